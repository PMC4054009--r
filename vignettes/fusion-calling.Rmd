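---
title: "Calling fusion transcripts from paired-end RNA-seq with fusejunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling fusion transcripts from paired-end RNA-seq with fusejunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusejunc)
```

## The problem and the evidence model

A fusion transcript joins the 5' part of one gene (the upstream gene) to
the 3' part of another (the downstream gene). In paired-end RNA-seq such a
transcript leaves two complementary footprints:

* **span-reads** — read pairs whose two ends map cleanly to the two
  different partner genes. They nominate the gene pair and, through the
  fragment-length geometry, bracket where the junction must lie, but they
  never touch the junction itself.
* **junc-reads** — reads that cross the junction. They cannot map to the
  genome or to any annotated transcript, but they pin the breakpoint down
  to single-base resolution once a candidate junction sequence exists to
  map them against.

`fusejunc` implements this two-evidence strategy as a nine-stage pipeline:
staged alignment (genome, then non-redundant transcripts, then a
small-indel rescue), optional iterative read trimming, span-read discovery
with orientation and candidate filters, junction-region localization from
half-reads and insert-size geometry, construction of a partial-exhaustion
junction sequence library, junc-read detection, and final filtering.

## Reference model

Each gene is represented by one **non-redundant transcript**: the interval
union of all annotated exons across its transcripts, concatenated (and
reverse-complemented as a whole for minus-strand genes) so transcript
coordinate 1 is the gene's 5' end. The union is our documented choice; it
is the only construction that guarantees every annotated exonic base is
representable, which the half-read mapping stage requires. Overlapping
exons merge into maximal blocks, introns are never included, and the block
table is a bijective map between transcript and genome coordinates — the
final calls are reported in genomic coordinates through this map. All
coordinates in the package are 1-based and inclusive; conversions to
0-based conventions happen only inside file readers and writers.

## Staged alignment

The internal aligner is a seed-and-verify, end-to-end, ungapped matcher:
exact k-mers (default `k = 21`, taken at both read termini and the middle)
anchor candidate placements which are then verified by Hamming distance
with at most `max_mismatch = 2` mismatches per end; `N` always counts as a
mismatch. Reads shorter than `3k` cannot carry three disjoint seeds, so
they are transparently re-routed to a lazily built `k = 10` index over the
same targets; this matters only for trimmed reads (minimum 30 nt) and
bisected half-reads. Multi-placement reads are reported up to
`max_hits = 5` with a truncation flag.

Pairs map first against the genome. A pair is properly mapped (`PE-S01`)
when some placement puts the two ends on one chromosome, head-to-head,
with an implied fragment below 10,000 bp; these pairs calibrate the
insert-size model and play no further role. Everything else contributes
single-end evidence (`SE-S01`) or moves on unmapped. Unmapped ends are
realigned against the non-redundant transcripts (stage `S02`), which
recovers reads spanning exon-exon boundaries. Ends that still fail are
offered a one-gap rescue — a single insertion or deletion of up to 5 nt,
anchored at terminal seeds — and reads that survive even that are the
**filtered-unmapped (FUM)** set, the only possible junction evidence.

### Insert-size estimation

`INS` and `SD` are the mean and sample standard deviation of the implied
fragment lengths (outer distance, inclusive) of properly mapped pairs. On
spliced transcripts measured in genome space a fragment whose two ends sit
in different exons appears inflated by the intervening introns, so the
pipeline uses a robust variant: fragments are restricted to a ±50 bp
window around the density mode before the moments are taken. This assumes
the unsplit-fragment mode dominates and `SD` is small relative to the
window; for libraries whose insert size approaches typical exon lengths
the estimate degrades, and `INS`/`SD` should then be supplied directly in
the configuration (both are honored per library — a sample may mix
libraries with different read lengths and insert sizes, and every library
is staged with its own statistics).

## Iterative trimming

Libraries with short inserts produce pairs whose 3' ends overlap; if the
overlap covers a junction, both ends fail to map and the pair is lost to
span-read discovery. The pipeline estimates the overlapped fraction as
`P(insert < 2 × read length)` under a Normal(`INS`, `SD`) model and trims
only when it exceeds 20% (or when forced by configuration). Trimming
removes 5 nt per cycle from the 3' end of each FUM read, realigning after
every cut and stopping at the first success; if the read is exhausted down
to 30 nt the full read is restored and the 5' end is trimmed the same way.
A read recoverable from both ends reports the 3'-phase result. Under the
default simulated conditions (`INS` 200, `SD` 20, 90-nt reads) the
overlapped fraction is about 16%, so trimming stays off unless forced.

## Candidate gene pairs

Span-reads are pairs whose two ends carry evidence on two different genes.
Untrimmed evidence must be a unique placement; trimmed reads may
contribute multiple placements (flagged). Genome-space hits are attributed
to a gene only when the read lies fully inside a single exon-union block,
so the placement is also a contiguous transcript placement; intronic hits
never create span evidence.

Orientation uses the head-to-head sequencing model: of the 16 combinations
of end serial number, mapped orientations and fragment-sense identity,
only 4 are rational, and in all of them the gene hit in the **plus**
orientation (relative to its own strand) is the upstream gene. Observed
`++` and `--` strand combinations are irrational and discarded.
Duplicated span-reads (identical placements on both sides) collapse to one
representative before support is counted, and three filters remove the
classic false-positive sources: gene pairs from the same family (shared
symbol prefix after stripping trailing digits, or an explicit family
table), span-reads inside exon regions shared by adjacent genes, and
span-reads whose surrounding 100-nt windows on the two genes are ≥90%
identical in either orientation.

## Locating the junction: two kinds of fused region

For each candidate pair the junction is localized twice, independently.

**Fused region 1 (narrow, from half-reads).** Every FUM read is bisected
into two isometric halves (the middle base of an odd-length read is
dropped). A genuine junc-read has one half clear of the junction; that
half maps to one partner gene and implies that the junction lies in the
adjacent window of one half-read length on the side of its unmapped
sibling. All placements of a multi-hit half are taken into account, and no
attempt is made to pre-filter spurious halves (reads unmapped merely for
excess mismatches): the credible-region intersection below is the defense.
FUM reads with at least one mapped half are the **useful unmapped (UUM)**
reads — the only reads later aligned to the junction library.

**Fused region 2 (wide, from insert-size geometry).** A span-read with end
1 at transcript position `MP1` on the upstream gene and end 2 at `MP2` on
the downstream gene confines the junction to

```
upstream:   [ MP1 + RL1 - FLB ,  MP1 + INS + 3·SD - RL2 + FLB - 1 ]
downstream: [ MP2 + RL2 - INS - 3·SD + RL1 - FLB ,  MP2 + FLB - 1 ]
```

where `RL1`/`RL2` are the end lengths and `FLB` (default 5 nt) allows for
the few junction-covering bases that mismatch-tolerant alignment can
absorb at a read's 3' end. `SD` is rounded up before use (a conservative
widening), intervals are clipped to the transcript, and the per-read
intervals are unioned across all supporting span-reads.

The overlap of region 2 with the union of region-1 windows is the
**credible region**; the remainder of region 2 is the **potential
region**. The two classes partition region 2 exactly, at base level.

## The partial-exhaustion junction library

Region 2 of each gene is tiled at one-nucleotide spacing; every upstream
tile `U_i` (last upstream base) is paired with every downstream tile `D_j`
(first downstream base), except connections whose two sites are **both**
potential — at least one site must be credible. Each kept connection is
materialized as a candidate junction sequence: the last `W` bases of the
upstream transcript through `U_i`, then `W` bases from `D_j` onward, with
`W` equal to the read length so any junc-read fits entirely, flanks
clipped at transcript ends and dropped below 30 nt. Identical sequences
arising from different connections collapse into one library entry that
retains all source coordinates.

UUM reads are matched against the library (ungapped, both orientations, at
most 2 mismatches) by indexing the reads and scanning each library
sequence, which avoids indexing the much larger library. A hit is a
junc-read only if it crosses the junction with at least 8 nt on both
sides; identical placements deduplicate.

## Calling, tie-breaking and canonicalization

Support counting uses **best-hit assignment**: a junc-read supports only
the junction sequences it matches with its minimal mismatch count.
Without this, a breakpoint candidate one or two bases away from the truth
— whose sequence differs by a single base — can accumulate comparable or
even larger support through mismatch-tolerant matching and shifted
overhang windows. Support is attributed to every source connection of a
matched sequence; the connection with maximal support wins, ties broken
toward exon-boundary sites and then the smallest coordinates.

The winning breakpoint is then **canonicalized within its microhomology
window**: when the bases moved across the junction agree between the two
genes, shifted breakpoints generate identical fused sequences and no read
evidence can distinguish them. Among these equivalents the one with the
best exon-boundary score is reported (ties to the smallest shift),
matching the convention that fusions arise at splice sites when the data
allow. A call is emitted when the pair has at least 2 deduplicated
span-reads and the winning site at least 2 deduplicated junc-reads —
thresholds motivated by the smallest support levels that validate in
practice — and two final guards remove read-through-like calls between
same-chromosome genes closer than 10 kb whose junction is not at exon
boundaries, and calls whose junction-adjacent windows on the two genes are
≥90% identical.

## The simulator, and what passing it does and does not show

`simulate_reference()` builds random chromosomes carrying non-overlapping
multi-exon genes on both strands (defaults: 4-8 exons of 150-400 nt,
introns 100-800 nt, intergenic gaps 2-5 kb — gene footprints of roughly
3-10 kb), each with a full-length transcript and, for half the genes, a
second isoform missing one internal exon so the exon union is genuinely
non-redundant. `select_fusion_pairs()` applies the same eligibility rules
the caller's filters assume (different families, partners separated by at
least 10 kb or on different chromosomes, no gene reused), and
`simulate_fusions()` places each junction either at exon-union block edges
or mid-exon, keeping at least 150 nt on both sides of the junction.
`simulate_reads()` samples fragments head-to-head with Normal(200, 20)
insert sizes, 90-nt ends, i.i.d. substitution errors at 0.5% and
background pairs from every unfused transcript at 5-fold coverage — the
conditions of the real libraries this design mirrors (90-bp reads, ~200-bp
inserts). Background replaces external stem-cell data with reads from the
toy reference's own unfused transcripts, preserving the role of
"non-fusion reads" while keeping the package self-contained.

Evaluation is strict: a simulated fusion counts as detected only if a call
names the same ordered gene pair with **both** genomic junction
coordinates strictly within 10 bp of the truth; the false-negative rate is
the undetected fraction, and the false-positive rate is the fraction of
calls matching no truth fusion.

The simulator does not model quality-score decay, indels or chimeric
library artifacts, GC or coverage bias, paralog families, or
alternative-splicing complexity beyond one skipped exon — so passing these
tests demonstrates the algorithmic machinery (staging, localization,
partial exhaustion, filtering) at realistic coverage and error rates, not
robustness to every artifact of real libraries.

Two residual error sources are inherent to the study conditions rather
than implementation defects. First, with 200-bp inserts and 2×90-nt ends
the unsequenced middle of a fragment is only ~20 bp, so a fusion expressed
at 30-fold yields on the order of four distinct span-reads; Poisson
fluctuation occasionally leaves fewer than the two required, which is
consistent with the ~5% false-negative floor reported for this class of
caller at 30-fold. Second, when a junction's microhomology window spans an
intron, transcript-identical breakpoints are genomically far apart and the
strict 10-bp rule can reject a perfectly supported call; no RNA-level
evidence can resolve that ambiguity.

## Worked example

```{r example, eval = FALSE}
library(fusejunc)

sim   <- simulate_reference(n_chrom = 2, n_genes = 20, seed = 7)
pairs <- select_fusion_pairs(sim$reference, 3, seed = 7)
fus   <- simulate_fusions(sim$reference, pairs, tiers = 100, seed = 7)
rd    <- simulate_reads(sim$reference, fus, error_rate = 0,
                        background_depth = 3, seed = 7)

res <- run_fusion_pipeline(rd$reads, sim$reference, fusion_config())
res
tidy(res)
glance(res)

ev <- evaluate_calls(res$calls, rd$truth)
ev
autoplot(ev)
```

Problem sizes used by the shipped checks: unit tests run on references of
8-24 genes; the end-to-end evaluation simulates 30-60 fusions over 80-150
genes across fold-coverage tiers from 5× to 200×, which completes in a few
minutes on a single core.

## Numerical and design choices

* Seed length 21 (10 for short reads), 2 mismatches per end, 5 placements
  maximum — SOAP-style short-read defaults; all configurable.
* Fragment length is the outer distance, inclusive, of a head-to-head
  placement; properly paired means fragment < 10,000 bp.
* `FLB = 5` nt: the flanking allowance matches the mismatch scale of the
  aligner (a span-read 3' end can cover the junction by about as many
  bases as the mismatch budget tolerates).
* Flank `W` = read length; minimum flank 30 nt, mirroring the minimum
  trimmed-read length.
* Half-reads use floor-half bisection (odd middle base dropped) with a
  minimum mappable half of 20 nt.
* Degenerate inputs: empty read sets, fusion-free datasets and header-only
  outputs are all exercised by the test suite; failure of trimming is a
  value, not an error, and an empty interval after clipping simply drops
  the region.
* Determinism: every stochastic step is seeded; rerunning a pipeline on
  the same inputs yields bit-identical TSV and FASTA outputs.

## Limitations

* The aligner is ungapped end-to-end (plus the one-gap rescue); junctions
  are localized only on annotated exonic sequence, so fusions involving
  unannotated exons or intronic breakpoints are out of reach.
* Genome-space insert estimation assumes the library's insert is small
  relative to exon lengths; otherwise supply `INS`/`SD` explicitly.
* Reads spanning three or more genes, paralog databases, expression
  quantification and reading-frame annotation are out of scope.
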