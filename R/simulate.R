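#' Simulate a toy reference genome and annotation
#'
#' Random chromosomes carrying non-overlapping multi-exon genes on both
#' strands, each with one full-length transcript and (for a random half of
#' genes) a second transcript missing one internal exon, so the exon union
#' is genuinely non-redundant. Gene symbols are random letter strings
#' without trailing digits, so no two simulated genes share a family.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param n_genes Number of genes (default 40).
#' @param exons_per_gene Integer range `c(min, max)` (default `c(4, 8)`).
#' @param exon_length Range in nt (default `c(150, 400)`).
#' @param intron_length Range in nt (default `c(100, 800)`).
#' @param intergenic Range of gaps between genes in nt (default
#'   `c(2000, 5000)`).
#' @param seed Random seed; a fixed seed reproduces the files
#'   byte-identically.
#' @param dir Optional directory; when given, writes `genome.fa` and
#'   `annotation.gtf` there.
#' @return List with `reference` (a `fusion_reference`) and, when `dir` is
#'   given, `fasta` and `gtf` paths.
#' @export
simulate_reference <- function(n_chrom = 2, n_genes = 40,
                               exons_per_gene = c(4, 8),
                               exon_length = c(150, 400),
                               intron_length = c(100, 800),
                               intergenic = c(2000, 5000),
                               seed = 1, dir = NULL) {
  stopifnot(n_chrom >= 1, n_genes >= 1)
  set.seed(seed)
  rint <- function(rng, n = 1) sample(seq(rng[1], rng[2]), n, replace = TRUE)

  symbols <- character(0)
  while (length(unique(symbols)) < n_genes)
    symbols <- unique(c(symbols, paste0(
      replicate(n_genes, paste(sample(LETTERS, 5, replace = TRUE),
                               collapse = "")))))
  symbols <- symbols[seq_len(n_genes)]

  chrom_of <- rep(seq_len(n_chrom), length.out = n_genes)
  exon_rows <- list()
  cursor <- rep(1L, n_chrom)
  for (g in seq_len(n_genes)) {
    cr <- chrom_of[g]
    start <- cursor[cr] + rint(intergenic)
    n_ex <- rint(exons_per_gene)
    ex_len <- rint(exon_length, n_ex)
    in_len <- if (n_ex > 1) rint(intron_length, n_ex - 1) else integer(0)
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("SIMG%03d", g)
    rows <- tibble::tibble(gene_id = gid,
                           transcript_id = paste0(gid, ".t1"),
                           chrom = paste0("chr", cr), strand = strand,
                           start = ex_start, end = ex_end)
    if (n_ex >= 3 && runif(1) < 0.5) {          # isoform missing one internal exon
      drop <- sample(2:(n_ex - 1), 1)
      rows2 <- rows[-drop, ]
      rows2$transcript_id <- paste0(gid, ".t2")
      rows <- dplyr::bind_rows(rows, rows2)
    }
    exon_rows[[g]] <- rows
    cursor[cr] <- max(ex_end)
  }
  exons <- dplyr::bind_rows(exon_rows)

  chrom_len <- exons |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end) + rint(intergenic), .groups = "drop")
  genome <- setNames(vapply(chrom_len$len, random_dna, character(1)),
                     chrom_len$chrom)
  if (any(exons$end > nchar(genome)[exons$chrom]))
    stop("genes do not fit on the chromosome; increase intergenic or chromosome size",
         call. = FALSE)

  sym_map <- setNames(symbols, sprintf("SIMG%03d", seq_len(n_genes)))
  ref <- new_reference(genome, exons, symbols = sym_map)

  out <- list(reference = ref)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
    sym_of <- setNames(ref$genes$symbol, ref$genes$gene_id)
    gr <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start, exons$end),
      strand = exons$strand, type = "exon", source = "fusejunc",
      gene_id = exons$gene_id, transcript_id = exons$transcript_id,
      gene_name = unname(sym_of[exons$gene_id]))
    rtracklayer::export(gr, gtf, format = "gtf")
    out$fasta <- fasta
    out$gtf <- gtf
  }
  out
}

#' Select gene pairs eligible to be fused
#'
#' Random pairs constrained the way the candidate filters expect genuine
#' fusions to look: partners on different chromosomes or separated by at
#' least `min_distance`, from different gene families, with no gene reused
#' and both non-redundant transcripts at least `min_nrt_len` nt.
#'
#' @param ref A `fusion_reference`.
#' @param n_fusions Number of pairs requested.
#' @param min_distance Minimum genomic gap between same-chromosome partners
#'   (default 10,000 bp).
#' @param min_nrt_len Minimum non-redundant transcript length (default 600).
#' @param seed Random seed.
#' @return Tibble with `fusion_id`, `up_gene`, `down_gene`.
#' @export
select_fusion_pairs <- function(ref, n_fusions, min_distance = 10000,
                                min_nrt_len = 600, seed = 1) {
  set.seed(seed)
  lens <- vapply(ref$nrt, function(n) nchar(n$sequence), integer(1))
  eligible <- names(lens)[lens >= min_nrt_len]
  span_of <- function(g) {
    b <- ref$nrt[[g]]$blocks
    c(min(b$gstart), max(b$gend))
  }
  ok_pair <- function(a, b) {
    na <- ref$nrt[[a]]; nb <- ref$nrt[[b]]
    if (same_family(ref$genes$symbol[ref$genes$gene_id == a],
                    ref$genes$symbol[ref$genes$gene_id == b])) return(FALSE)
    if (na$chrom != nb$chrom) return(TRUE)
    sa <- span_of(a); sb <- span_of(b)
    gap <- max(sa[1], sb[1]) - min(sa[2], sb[2])
    gap >= min_distance
  }
  pool <- sample(eligible)
  ups <- character(0); downs <- character(0)
  while (length(ups) < n_fusions && length(pool) >= 2) {
    a <- pool[1]; pool <- pool[-1]
    j <- which(vapply(pool, ok_pair, logical(1), a = a))[1]
    if (is.na(j)) next
    ups <- c(ups, a); downs <- c(downs, pool[j]); pool <- pool[-j]
  }
  if (length(ups) < n_fusions)
    stop(sprintf(paste("only %d eligible fusion pairs (requested %d);",
                       "simulate more or longer genes, or relax min_distance"),
                 length(ups), n_fusions), call. = FALSE)
  tibble::tibble(fusion_id = sprintf("FUS%03d", seq_len(n_fusions)),
                 up_gene = ups, down_gene = downs)
}

#' Assign junction sites and expression folds to fusion pairs
#'
#' Each pair gets a junction either at exon edges (the upstream site at
#' the 3' boundary of an exon-union block and the downstream site at a
#' block's 5' boundary) or in the middle of exons, and an expression fold
#' drawn from `tiers`.
#'
#' @param ref A `fusion_reference`.
#' @param pairs Output of [select_fusion_pairs()].
#' @param tiers Numeric vector of fold-coverage levels; recycled over
#'   fusions in order (use a single value for one tier).
#' @param edge_fraction Fraction of fusions with exon-edge junctions
#'   (default 0.5).
#' @param margin Minimum length (nt) of the upstream part and of the
#'   retained downstream tail (default 150).
#' @param seed Random seed.
#' @return Truth tibble: `fusion_id`, `up_gene`, `down_gene`, `U`, `D`
#'   (transcript coords), `pos_5`, `pos_3` (genomic coords), `placement`,
#'   `fold`, `fused_length`.
#' @export
simulate_fusions <- function(ref, pairs, tiers = 50, edge_fraction = 0.5,
                             margin = 150, seed = 1) {
  set.seed(seed)
  n <- nrow(pairs)
  if (n == 0)
    return(tibble::tibble(fusion_id = character(), up_gene = character(),
                          down_gene = character(), up_symbol = character(),
                          down_symbol = character(), U = integer(),
                          D = integer(), pos_5 = integer(),
                          pos_3 = integer(), placement = character(),
                          fold = numeric(), fused_length = integer()))
  placement <- ifelse(runif(n) < edge_fraction, "exon_edge", "mid_exon")
  fold <- rep_len(tiers, n)
  U <- integer(n); D <- integer(n)
  for (i in seq_len(n)) {
    nu <- ref$nrt[[pairs$up_gene[i]]]; nd <- ref$nrt[[pairs$down_gene[i]]]
    lu <- nchar(nu$sequence); ld <- nchar(nd$sequence)
    u_rng <- c(margin, lu - 1)
    d_rng <- c(10, ld - margin)
    if (placement[i] == "exon_edge") {
      u_opts <- nu$blocks$tend[nu$blocks$tend >= u_rng[1] &
                                 nu$blocks$tend <= u_rng[2]]
      d_opts <- nd$blocks$tstart[nd$blocks$tstart >= d_rng[1] &
                                   nd$blocks$tstart <= d_rng[2]]
      if (length(u_opts) == 0 || length(d_opts) == 0) {
        placement[i] <- "mid_exon"
      } else {
        U[i] <- if (length(u_opts) == 1) u_opts else sample(u_opts, 1)
        D[i] <- if (length(d_opts) == 1) d_opts else sample(d_opts, 1)
      }
    }
    if (placement[i] == "mid_exon") {
      U[i] <- sample(seq(u_rng[1], u_rng[2]), 1)
      D[i] <- sample(seq(d_rng[1], d_rng[2]), 1)
    }
  }
  pos_5 <- mapply(function(g, u) map_transcript_coord(ref$nrt[[g]], u),
                  pairs$up_gene, U)
  pos_3 <- mapply(function(g, d) map_transcript_coord(ref$nrt[[g]], d),
                  pairs$down_gene, D)
  fused_length <- U + vapply(ref$nrt[pairs$down_gene],
                             function(x) nchar(x$sequence), integer(1)) - D + 1
  symbols <- setNames(ref$genes$symbol, ref$genes$gene_id)
  tibble::tibble(fusion_id = pairs$fusion_id, up_gene = pairs$up_gene,
                 down_gene = pairs$down_gene,
                 up_symbol = unname(symbols[pairs$up_gene]),
                 down_symbol = unname(symbols[pairs$down_gene]),
                 U = U, D = D,
                 pos_5 = as.integer(pos_5), pos_3 = as.integer(pos_3),
                 placement = placement, fold = fold,
                 fused_length = as.integer(fused_length))
}

# substitution errors i.i.d. per base at `rate`; substituted base is drawn
# from the three alternatives
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  n_err <- stats::rbinom(length(reads), L, rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(L[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  reads
}

# sample head-to-head read pairs from one template sequence
sample_pairs_from <- function(template, n_pairs, INS, SD, read_length,
                              id_prefix, junction_at = NA_integer_) {
  L <- nchar(template)
  if (n_pairs == 0 || L < read_length + 10)
    return(tibble::tibble(pair_id = character(), end1 = character(),
                          end2 = character(), crosses1 = logical(),
                          crosses2 = logical()))
  F <- pmin(pmax(round(rnorm(n_pairs, INS, SD)), read_length + 10), L)
  s <- vapply(F, function(f) sample.int(L - f + 1, 1), integer(1))
  e <- s + F - 1
  read_a <- substr(rep(template, n_pairs), s, s + read_length - 1)
  read_b <- dna_revcomp(substr(rep(template, n_pairs), e - read_length + 1, e))
  crosses_a <- !is.na(junction_at) & s <= junction_at & s + read_length - 1 >= junction_at + 1
  crosses_b <- !is.na(junction_at) & e - read_length + 1 <= junction_at & e >= junction_at + 1
  a_is_1 <- runif(n_pairs) < 0.5
  tibble::tibble(
    pair_id = sprintf("%s_%05d", id_prefix, seq_len(n_pairs)),
    end1 = ifelse(a_is_1, read_a, read_b),
    end2 = ifelse(a_is_1, read_b, read_a),
    crosses1 = ifelse(a_is_1, crosses_a, crosses_b),
    crosses2 = ifelse(a_is_1, crosses_b, crosses_a))
}

#' Simulate paired-end RNA-seq reads for fusions plus background
#'
#' Fragments are sampled from each fused transcript at the fusion's fold
#' coverage (fragment length Normal(INS, SD), paired-end reads sequenced
#' head-to-head from the fragment ends), with i.i.d. substitution errors.
#' Background read pairs are sampled the same way from the unfused
#' non-redundant transcripts of every gene at `background_depth`.
#'
#' @param ref A `fusion_reference`.
#' @param fusions Truth tibble from [simulate_fusions()] (may have zero
#'   rows for a background-only dataset).
#' @param INS,SD Fragment-length mean and standard deviation in bp
#'   (defaults 200 and 20).
#' @param read_length Read length per end in nt (default 90).
#' @param error_rate Per-base substitution rate in `[0, 0.05]`
#'   (default 0.005).
#' @param background_depth Fold coverage of unfused transcripts
#'   (default 5; 0 disables background).
#' @param seed Random seed.
#' @return List with `reads` (tibble `pair_id`, `end1`, `end2`, `origin`,
#'   `fusion_id`, `crosses1`, `crosses2`) and `truth` (the `fusions`
#'   tibble).
#' @export
simulate_reads <- function(ref, fusions, INS = 200, SD = 20,
                           read_length = 90, error_rate = 0.005,
                           background_depth = 5, seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(fusions))) {
    nu <- ref$nrt[[fusions$up_gene[i]]]; nd <- ref$nrt[[fusions$down_gene[i]]]
    template <- paste0(substr(nu$sequence, 1, fusions$U[i]),
                       substr(nd$sequence, fusions$D[i], nchar(nd$sequence)))
    n_pairs <- max(1, round(fusions$fold[i] * nchar(template) /
                              (2 * read_length)))
    tb <- sample_pairs_from(template, n_pairs, INS, SD, read_length,
                            id_prefix = fusions$fusion_id[i],
                            junction_at = fusions$U[i])
    tb$origin <- "fusion"
    tb$fusion_id <- fusions$fusion_id[i]
    out[[length(out) + 1]] <- tb
  }
  if (background_depth > 0) {
    for (g in names(ref$nrt)) {
      tpl <- ref$nrt[[g]]$sequence
      n_pairs <- round(background_depth * nchar(tpl) / (2 * read_length))
      tb <- sample_pairs_from(tpl, n_pairs, INS, SD, read_length,
                              id_prefix = paste0("BG_", g))
      if (nrow(tb) > 0) {
        tb$origin <- "background"
        tb$fusion_id <- NA_character_
        out[[length(out) + 1]] <- tb
      }
    }
  }
  reads <- if (length(out) == 0)
    tibble::tibble(pair_id = character(), end1 = character(),
                   end2 = character(), crosses1 = logical(),
                   crosses2 = logical(), origin = character(),
                   fusion_id = character())
  else dplyr::bind_rows(out)
  reads$end1 <- add_read_errors(reads$end1, error_rate)
  reads$end2 <- add_read_errors(reads$end2, error_rate)
  list(reads = reads, truth = fusions)
}

#' Write a simulated dataset to FASTQ and TSV files
#'
#' @param sim Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`fastq1`, `fastq2`, `truth`).
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq")
    path
  }
  paths <- list(
    fastq1 = fq(sim$reads$end1, paste0(sim$reads$pair_id, "/1"),
                file.path(dir, "reads_1.fastq")),
    fastq2 = fq(sim$reads$end2, paste0(sim$reads$pair_id, "/2"),
                file.path(dir, "reads_2.fastq")),
    truth = file.path(dir, "truth.tsv"))
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Score fusion calls against simulated truth
#'
#' A truth fusion is detected when some call names the same ordered gene
#' pair and both genomic junction coordinates are strictly within 10 bp
#' (`|call - truth| < max_dist`) of the true ones. FN rate = undetected /
#' total truth fusions; FP rate = calls matching no truth fusion / total
#' calls (an empty call set has FP rate 0; an empty truth set leaves the
#' FN rate `NA`).
#'
#' @param calls Fusion-call tibble.
#' @param truth Truth tibble from [simulate_fusions()].
#' @param max_dist Junction distance bound in bp; matching is strict
#'   (`< max_dist`, default 10).
#' @return A `fusion_evaluation` list: `per_fusion` (truth with `detected`
#'   flag and best distances), `fn_rate`, `fp_rate`, `n_truth`, `n_calls`.
#' @export
evaluate_calls <- function(calls, truth, max_dist = 10) {
  detected <- logical(nrow(truth))
  d5 <- rep(NA_integer_, nrow(truth)); d3 <- rep(NA_integer_, nrow(truth))
  call_matched <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    j <- which(calls$up_gene == truth$up_gene[i] &
                 calls$down_gene == truth$down_gene[i])
    if (length(j) == 0) next
    dist5 <- abs(calls$pos_5[j] - truth$pos_5[i])
    dist3 <- abs(calls$pos_3[j] - truth$pos_3[i])
    hit <- dist5 < max_dist & dist3 < max_dist
    if (any(hit)) {
      detected[i] <- TRUE
      call_matched[j[hit]] <- TRUE
      best <- which.min(dist5 + dist3)
      d5[i] <- dist5[best]; d3[i] <- dist3[best]
    }
  }
  per_fusion <- truth
  per_fusion$detected <- detected
  per_fusion$dist_5 <- d5
  per_fusion$dist_3 <- d3
  structure(list(
    per_fusion = per_fusion,
    fn_rate = if (nrow(truth) == 0) NA_real_ else mean(!detected),
    fp_rate = if (nrow(calls) == 0) 0 else mean(!call_matched),
    n_truth = nrow(truth), n_calls = nrow(calls)),
    class = "fusion_evaluation")
}

#' @export
print.fusion_evaluation <- function(x, ...) {
  cat(sprintf("<fusion_evaluation> %d truth fusion(s), %d call(s): FN %.1f%%, FP %.1f%%\n",
              x$n_truth, x$n_calls, 100 * x$fn_rate, 100 * x$fp_rate))
  invisible(x)
}
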