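#' Enumerate the sixteen span-read strand/serial combinations
#'
#' A span read is a pair of ends, read 'a' sequenced from the fragment
#' itself and read 'b' from its complementary strand, sequenced head-to-head.
#' Crossing the serial number of the end mapped to gene A, the mapped
#' orientations on genes A and B, and which serial number carries read 'a'
#' gives 16 combinations. A combination is rational only when the two ends
#' map in opposite orientations and the fragment-sense read ('a') is the
#' one mapping in the plus orientation; the gene aligned in the plus
#' orientation is then the upstream gene.
#'
#' @return Tibble with 16 rows: `end_on_A`, `strand_A`, `strand_B`,
#'   `read_a_end`, logical `rational`, and `upstream` (`"A"`, `"B"` or
#'   `NA` for irrational rows).
#' @export
enumerate_span_combinations <- function() {
  grid <- tidyr::expand_grid(end_on_A = c(1L, 2L),
                             strand_A = c("+", "-"),
                             strand_B = c("+", "-"),
                             read_a_end = c(1L, 2L))
  grid |>
    dplyr::mutate(
      strand_of_a = ifelse(.data$read_a_end == .data$end_on_A,
                           .data$strand_A, .data$strand_B),
      rational = .data$strand_A != .data$strand_B & .data$strand_of_a == "+",
      upstream = dplyr::case_when(
        !rational ~ NA_character_,
        strand_A == "+" ~ "A",
        TRUE ~ "B")) |>
    dplyr::select(-"strand_of_a")
}

#' Orient one span read into upstream and downstream genes
#'
#' The gene aligned by the read in the plus orientation is the upstream
#' gene; the mate must align to the other gene in the minus orientation.
#' Any other strand combination is irrational and the span read is
#' discarded.
#'
#' @param span List or one-row tibble with `gene_a`, `strand_a`, `gene_b`,
#'   `strand_b` (transcript-space hits, gene-strand orientation).
#' @return List with `upstream` and `downstream` gene ids, or `NULL` when
#'   the combination is irrational.
#' @export
orient_gene_pair <- function(span) {
  plus_a <- span$strand_a == "+"
  plus_b <- span$strand_b == "+"
  if (plus_a == plus_b) return(NULL)            # ++ or --: irrational
  if (plus_a) list(upstream = span$gene_a, downstream = span$gene_b)
  else        list(upstream = span$gene_b, downstream = span$gene_a)
}

#' Attribute genome-space hits to genes in transcript coordinates
#'
#' A genome hit contributes gene-level evidence only when the read lies
#' fully inside a single exon-union block of one gene (so the placement is
#' also a contiguous transcript-space placement); intronic or
#' block-straddling genome hits are dropped. The returned rows carry the
#' transcript-space leftmost coordinate and the hit orientation relative to
#' the gene strand.
#'
#' @param hits Genome-space hits tibble from [align_end()] with a
#'   `read_len` column.
#' @param ref A `fusion_reference`.
#' @return Evidence tibble with `read_id`, `gene_id`, `tpos`, `strand`,
#'   `mismatches`, `n_hits`, `read_len`.
#' @export
attribute_genome_hits <- function(hits, ref) {
  empty <- tibble::tibble(read_id = character(), gene_id = character(),
                          tpos = integer(), strand = character(),
                          mismatches = integer(), n_hits = integer(),
                          read_len = integer())
  if (nrow(hits) == 0) return(empty)
  blocks <- dplyr::bind_rows(lapply(ref$nrt, function(n) {
    tibble::tibble(gene_id = n$gene_id, chrom = n$chrom,
                   gstart = n$blocks$gstart, gend = n$blocks$gend)
  }))
  block_gr <- GenomicRanges::GRanges(blocks$chrom,
                                     IRanges::IRanges(blocks$gstart, blocks$gend))
  hit_gr <- GenomicRanges::GRanges(hits$target,
                                   IRanges::IRanges(hits$pos,
                                                    hits$pos + hits$read_len - 1))
  ov <- GenomicRanges::findOverlaps(hit_gr, block_gr, type = "within")
  if (length(ov) == 0) return(empty)
  hi <- S4Vectors::queryHits(ov)
  bi <- S4Vectors::subjectHits(ov)
  out <- hits[hi, ]
  out$gene_id <- blocks$gene_id[bi]
  gene_strand <- setNames(ref$genes$strand, ref$genes$gene_id)
  nrt_left <- mapply(function(g, p, len, st) {
    nrt <- ref$nrt[[g]]
    # leftmost transcript coordinate of the placement
    t1 <- map_genomic_coord(nrt, p)
    t2 <- map_genomic_coord(nrt, p + len - 1)
    min(t1, t2)
  }, out$gene_id, out$pos, out$read_len, out$strand)
  out$tpos <- as.integer(unname(nrt_left))
  out$strand <- unname(ifelse(out$strand == gene_strand[out$gene_id],
                              "+", "-"))
  dplyr::select(out, "read_id", "gene_id", "tpos", "strand", "mismatches",
                "n_hits", "read_len")
}

#' Find span reads in merged single-end evidence
#'
#' Pairs whose two ends carry evidence on two different genes become span
#' reads. Untrimmed evidence must be a unique placement; trimmed reads may
#' contribute up to their allowed multiplicity and the resulting span reads
#' are flagged `multi`. Each span read is oriented by
#' [orient_gene_pair()]; irrational combinations are discarded.
#'
#' @param evidence Evidence tibble: `pair_id`, `end`, `gene_id`, `tpos`,
#'   `strand`, `mismatches`, `n_hits`, `read_len`, `trim_cycles`.
#' @return Span-read tibble: `pair_id`, `up_gene`, `down_gene`, `mp_up`,
#'   `mp_down` (leftmost transcript coordinates of the plus- and
#'   minus-oriented ends), `rl_up`, `rl_down`, `multi`.
#' @export
find_span_reads <- function(evidence) {
  empty <- tibble::tibble(pair_id = character(), up_gene = character(),
                          down_gene = character(), mp_up = integer(),
                          mp_down = integer(), rl_up = integer(),
                          rl_down = integer(), multi = logical())
  if (nrow(evidence) == 0) return(empty)
  if (!"trim_cycles" %in% names(evidence)) evidence$trim_cycles <- 0L
  ev <- dplyr::filter(evidence,
                      .data$trim_cycles > 0 | .data$n_hits == 1)
  e1 <- dplyr::filter(ev, .data$end == 1L)
  e2 <- dplyr::filter(ev, .data$end == 2L)
  joined <- dplyr::inner_join(e1, e2, by = "pair_id",
                              suffix = c("_1", "_2"),
                              relationship = "many-to-many") |>
    dplyr::filter(.data$gene_id_1 != .data$gene_id_2,
                  .data$strand_1 != .data$strand_2)
  if (nrow(joined) == 0) return(empty)
  plus_is_1 <- joined$strand_1 == "+"
  tibble::tibble(
    pair_id = joined$pair_id,
    up_gene = ifelse(plus_is_1, joined$gene_id_1, joined$gene_id_2),
    down_gene = ifelse(plus_is_1, joined$gene_id_2, joined$gene_id_1),
    mp_up = as.integer(ifelse(plus_is_1, joined$tpos_1, joined$tpos_2)),
    mp_down = as.integer(ifelse(plus_is_1, joined$tpos_2, joined$tpos_1)),
    rl_up = as.integer(ifelse(plus_is_1, joined$read_len_1, joined$read_len_2)),
    rl_down = as.integer(ifelse(plus_is_1, joined$read_len_2, joined$read_len_1)),
    multi = joined$n_hits_1 > 1 | joined$n_hits_2 > 1)
}

#' Remove duplicated supporting reads
#'
#' Reads with identical placements (same targets, positions and strands on
#' both sides) collapse to a single representative before support is
#' counted. Idempotent.
#'
#' @param reads Tibble of span or junction reads.
#' @param keys Character vector of columns that define a placement.
#' @return Deduplicated tibble.
#' @export
dedup_reads <- function(reads,
                        keys = c("up_gene", "mp_up", "down_gene", "mp_down")) {
  dplyr::distinct(reads, dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE)
}

# gene family by shared symbol prefix after stripping trailing digits,
# plus an optional explicit family table (family_id, gene_id)
same_family <- function(symbol_a, symbol_b, gene_a = NULL, gene_b = NULL,
                        families = NULL) {
  if (!is.null(families) && !is.null(gene_a)) {
    fa <- families$family_id[match(gene_a, families$gene_id)]
    fb <- families$family_id[match(gene_b, families$gene_id)]
    if (!is.na(fa) && !is.na(fb) && fa == fb) return(TRUE)
  }
  pa <- sub("[0-9]+$", "", symbol_a)
  pb <- sub("[0-9]+$", "", symbol_b)
  nzchar(pa) && pa == pb
}

# identity of windows (width `window`) centered on two transcript hits,
# in either orientation
hit_window_identity <- function(seq_up, center_up, seq_down, center_down,
                                window = 100) {
  grab <- function(s, c) {
    half <- window %/% 2
    substr(s, max(1, c - half + 1), min(nchar(s), c + half))
  }
  wu <- grab(seq_up, center_up)
  wd <- grab(seq_down, center_down)
  n <- min(nchar(wu), nchar(wd))
  if (n < 20) return(0)
  wu <- substr(wu, 1, n); wd <- substr(wd, 1, n)
  max(seq_identity(wu, wd), seq_identity(wu, dna_revcomp(wd)))
}

#' Filter candidate gene pairs
#'
#' Three filters are applied to oriented, deduplicated span reads:
#' same-family gene pairs are removed outright; span reads whose hits fall
#' inside exon regions shared by the two genes (overlapping exon-union
#' blocks of adjacent genes) are excluded before counting; and span reads
#' whose surrounding sequence windows on the two genes are mutually
#' homologous (ungapped identity at or above `homology_identity` over a
#' `homology_window`-nt window, either orientation) are excluded. Pairs
#' left without support are dropped.
#'
#' @param span_reads Deduplicated span-read tibble from
#'   [find_span_reads()].
#' @param ref A `fusion_reference`.
#' @param homology_window,homology_identity Homology filter parameters.
#' @param families Optional tibble (`family_id`, `gene_id`).
#' @return List: `span_reads` (filtered), `pairs` (tibble `up_gene`,
#'   `down_gene`, `span_count`), `log` (per-pair removal reasons).
#' @export
filter_gene_pairs <- function(span_reads, ref, homology_window = 100,
                              homology_identity = 0.90, families = NULL) {
  log <- tibble::tibble(up_gene = character(), down_gene = character(),
                        reason = character())
  if (nrow(span_reads) == 0)
    return(list(span_reads = span_reads,
                pairs = tibble::tibble(up_gene = character(),
                                       down_gene = character(),
                                       span_count = integer()),
                log = log))
  symbols <- setNames(ref$genes$symbol, ref$genes$gene_id)

  keep <- rep(TRUE, nrow(span_reads))
  pairs <- dplyr::distinct(span_reads, .data$up_gene, .data$down_gene)
  for (i in seq_len(nrow(pairs))) {
    gu <- pairs$up_gene[i]; gd <- pairs$down_gene[i]
    rows <- which(span_reads$up_gene == gu & span_reads$down_gene == gd)
    if (same_family(symbols[[gu]], symbols[[gd]], gu, gd, families)) {
      keep[rows] <- FALSE
      log <- dplyr::add_row(log, up_gene = gu, down_gene = gd,
                            reason = "same_family")
      next
    }
    nu <- ref$nrt[[gu]]; nd <- ref$nrt[[gd]]
    # shared exon-union regions of adjacent genes, in genomic space
    if (nu$chrom == nd$chrom) {
      shared <- IRanges::intersect(
        IRanges::IRanges(nu$blocks$gstart, nu$blocks$gend),
        IRanges::IRanges(nd$blocks$gstart, nd$blocks$gend))
      if (length(shared) > 0) {
        for (r in rows) {
          gi_up <- range(map_transcript_coord(nu, c(span_reads$mp_up[r],
            min(span_reads$mp_up[r] + span_reads$rl_up[r] - 1, nchar(nu$sequence)))))
          gi_dn <- range(map_transcript_coord(nd, c(span_reads$mp_down[r],
            min(span_reads$mp_down[r] + span_reads$rl_down[r] - 1, nchar(nd$sequence)))))
          in_shared <- function(gi)
            length(IRanges::findOverlaps(IRanges::IRanges(gi[1], gi[2]), shared)) > 0
          if (in_shared(gi_up) || in_shared(gi_dn)) keep[r] <- FALSE
        }
        if (!any(keep[rows]))
          log <- dplyr::add_row(log, up_gene = gu, down_gene = gd,
                                reason = "shared_exons")
      }
    }
    # homologous read-bearing windows
    live <- rows[keep[rows]]
    for (r in live) {
      idt <- hit_window_identity(nu$sequence,
                                 span_reads$mp_up[r] + span_reads$rl_up[r] %/% 2,
                                 nd$sequence,
                                 span_reads$mp_down[r] + span_reads$rl_down[r] %/% 2,
                                 homology_window)
      if (idt >= homology_identity) keep[r] <- FALSE
    }
    if (any(keep[rows]) == FALSE && !any(log$up_gene == gu & log$down_gene == gd))
      log <- dplyr::add_row(log, up_gene = gu, down_gene = gd,
                            reason = "homologous_regions")
  }
  kept <- span_reads[keep, ]
  pairs <- kept |>
    dplyr::count(.data$up_gene, .data$down_gene, name = "span_count")
  list(span_reads = kept, pairs = pairs, log = log)
}
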