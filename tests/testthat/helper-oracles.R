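# Independent oracles used to freeze expected values; deliberately naive
# implementations that share no code with the package internals.

# all end-to-end ungapped placements of `read` on each target, both strands,
# with <= max_mm mismatches (N never matches), by exhaustive scan
brute_hamming_scan <- function(read, targets, max_mm = 2) {
  vset <- utf8ToInt("ACGT")
  out <- list()
  rv <- utf8ToInt(read); rinv <- !rv %in% vset
  cv <- utf8ToInt(dna_revcomp(read)); cinv <- !cv %in% vset
  L <- length(rv)
  for (tn in names(targets)) {
    tv <- utf8ToInt(targets[[tn]])
    tinv <- !tv %in% vset
    if (L > length(tv)) next
    for (p in seq_len(length(tv) - L + 1)) {
      seg <- tv[p:(p + L - 1)]; seginv <- tinv[p:(p + L - 1)]
      mm_f <- sum((rv != seg) | rinv | seginv)
      if (mm_f <= max_mm)
        out[[length(out) + 1]] <- tibble::tibble(
          target = tn, pos = p, strand = "+", mismatches = as.integer(mm_f))
      mm_r <- sum((cv != seg) | cinv | seginv)
      if (mm_r <= max_mm)
        out[[length(out) + 1]] <- tibble::tibble(
          target = tn, pos = p, strand = "-", mismatches = as.integer(mm_r))
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(target = character(), pos = integer(),
                          strand = character(), mismatches = integer()))
  dplyr::arrange(dplyr::bind_rows(out), .data$mismatches, .data$target,
                 .data$pos)
}

# can `read` be placed on `target` (forward strand) with exactly one gap of
# size 1..max_gap (insertion or deletion) and <= max_mm substitutions?
brute_gap_fit <- function(read, target, max_mm = 2, max_gap = 5) {
  rv <- utf8ToInt(read); tv <- utf8ToInt(target)
  L <- length(rv)
  for (g in seq_len(max_gap)) {
    # deletion from the read: target consumes L + g
    for (a in seq_len(max(0, length(tv) - (L + g) + 1))) {
      for (i in seq_len(L - 1)) {
        seg <- c(tv[a:(a + i - 1)], tv[(a + i + g):(a + L + g - 1)])
        if (sum(rv != seg) <= max_mm) return(TRUE)
      }
    }
    # insertion in the read: target consumes L - g
    if (L - g < 2) next
    for (a in seq_len(max(0, length(tv) - (L - g) + 1))) {
      for (i in seq_len(L - g - 1)) {
        rkeep <- c(rv[1:i], rv[(i + g + 1):L])
        if (sum(rkeep != tv[a:(a + L - g - 1)]) <= max_mm) return(TRUE)
      }
    }
  }
  FALSE
}

# base-level set of genomic positions covered by exon records
exon_base_set <- function(starts, ends) {
  v <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  sort(unique(as.integer(c(v, integer(0)))))
}

# per-base mismatch count between two equal-length DNA strings
str_mismatches <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

# deterministic tiny reference: two chromosomes, four genes (two per
# strand), hand-laid exons
tiny_reference <- function(seed = 42) {
  set.seed(seed)
  genome <- c(chrA = random_dna(6000), chrB = random_dna(6000))
  exons <- tibble::tibble(
    gene_id = c(rep("gA", 3), rep("gB", 3), rep("gC", 2), rep("gD", 3)),
    transcript_id = c(rep("gA.t1", 3), rep("gB.t1", 3), rep("gC.t1", 2),
                      rep("gD.t1", 3)),
    chrom = c(rep("chrA", 6), rep("chrB", 5)),
    strand = c(rep("+", 3), rep("-", 3), rep("+", 2), rep("-", 3)),
    start = c(101, 501, 901, 3001, 3401, 3801, 201, 701, 3001, 3501, 4001),
    end = c(300, 700, 1100, 3200, 3600, 4000, 500, 1000, 3300, 3800, 4300))
  new_reference(genome, exons)
}

# write a minimal FASTA/GTF fixture pair and return the paths
write_tiny_annotation <- function(dir, chrom_seq, exons) {
  fasta <- file.path(dir, "g.fa")
  gtf <- file.path(dir, "a.gtf")
  writeLines(c(">chr1", chrom_seq), fasta)
  rows <- sprintf(
    'chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$start, exons$end, exons$strand, exons$gene_id, exons$transcript_id)
  writeLines(rows, gtf)
  list(fasta = fasta, gtf = gtf)
}
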