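# per-library staging: genome alignment, pair classification, insert-size
# estimation, transcript realignment, indel rescue, optional trimming.
stage_one_library <- function(reads_tbl, ref, genome_idx, tx_idx, cfg, lib) {
  n_pairs <- nrow(reads_tbl)
  if (n_pairs == 0) {
    return(list(evidence = tibble::tibble(), fum = character(0),
                ins = list(INS = cfg$INS %||% 0, SD = cfg$SD %||% 0,
                           n_used = 0L),
                rl = 0L, overlap = list(fraction = 0, trim = FALSE),
                counts = c(pairs = 0L, `PE-S01` = 0L, `SE-S01` = 0L,
                           `UM-S01` = 0L, `SE-S02` = 0L, `UM-S02` = 0L,
                           FUM = 0L, `SE-S03` = 0L),
                staging = tibble::tibble(pair_id = character(),
                                         fragment = numeric(),
                                         stage = character())))
  }
  rl1 <- nchar(reads_tbl$end1[1])
  rl2 <- nchar(reads_tbl$end2[1])

  ends1 <- setNames(reads_tbl$end1, reads_tbl$pair_id)
  ends2 <- setNames(reads_tbl$end2, reads_tbl$pair_id)
  hits1 <- align_end(ends1, genome_idx, cfg$max_mismatch, cfg$max_hits)
  hits2 <- align_end(ends2, genome_idx, cfg$max_mismatch, cfg$max_hits)
  staging <- classify_pairs(reads_tbl, hits1, hits2, cfg$max_insert)

  # insert-size statistics from properly paired fragments
  if (!is.null(cfg$INS) && !is.null(cfg$SD)) {
    ins <- list(INS = cfg$INS, SD = cfg$SD, n_used = 0L)
  } else {
    frags <- staging$fragment[staging$stage == "PE-S01"]
    ins <- estimate_insert_size(frags, robust = cfg$robust_insert,
                                peak_halfwidth = cfg$insert_peak_halfwidth)
  }

  # genome-space evidence from non-proper pairs, attributed to genes
  non_pe <- staging$pair_id[staging$stage != "PE-S01"]
  g_ev <- list()
  for (e in 1:2) {
    h <- if (e == 1) hits1 else hits2
    h <- h[h$read_id %in% non_pe, ]
    if (nrow(h) == 0) next
    h$read_len <- if (e == 1) rl1 else rl2
    att <- attribute_genome_hits(h, ref)
    if (nrow(att) == 0) next
    att$pair_id <- att$read_id
    att$end <- e
    g_ev[[e]] <- att
  }

  # transcript-space alignment of all unmapped ends
  um1 <- ends1[!reads_tbl$pair_id %in% unique(hits1$read_id)]
  um2 <- ends2[!reads_tbl$pair_id %in% unique(hits2$read_id)]
  um_reads <- c(setNames(unname(um1), paste0(names(um1), "/1")),
                setNames(unname(um2), paste0(names(um2), "/2")))
  tx <- align_to_transcripts(um_reads, tx_idx, cfg$max_mismatch, cfg$max_hits)
  tx_hits <- tx$hits
  t_ev <- NULL
  if (nrow(tx_hits) > 0) {
    t_ev <- tx_hits
    t_ev$pair_id <- sub("/[12]$", "", t_ev$read_id)
    t_ev$end <- as.integer(sub("^.*/", "", t_ev$read_id))
    t_ev$gene_id <- t_ev$target
    t_ev$tpos <- t_ev$pos
    t_ev$read_len <- nchar(um_reads[t_ev$read_id])
    t_ev <- dplyr::select(t_ev, "pair_id", "end", "gene_id", "tpos",
                          "strand", "mismatches", "n_hits", "read_len")
  }

  # pairs fully unmapped at S01 partition into SE-S02 / UM-S02
  um_s01 <- staging$pair_id[staging$stage == "UM-S01"]
  gained <- unique(sub("/[12]$", "", tx$mapped_reads))
  se_s02 <- intersect(um_s01, gained)
  um_s02 <- setdiff(um_s01, gained)

  # small-indel rescue; survivors are the FUM set
  still_um <- um_reads[!names(um_reads) %in% tx$mapped_reads]
  fum <- collect_fum(still_um, tx_idx, cfg$max_gap, cfg$max_mismatch)

  # 3'-overlap trimming decision and iterative trimming of FUM reads
  read_len <- max(rl1, rl2)
  ovl <- overlapped_end_fraction(ins, read_len, cfg$trim_threshold,
                                 cfg$force_trim)
  trim_ev <- NULL
  if (ovl$trim && length(fum) > 0) {
    tr <- trim_fum_batch(fum, tx_idx, cfg$trim_step, cfg$trim_min_len,
                         cfg$max_mismatch, cfg$max_hits)
    if (nrow(tr) > 0) {
      tr$pair_id <- sub("/[12]$", "", tr$read_id)
      tr$end <- as.integer(sub("^.*/", "", tr$read_id))
      tr$gene_id <- tr$target
      tr$tpos <- tr$pos
      trim_ev <- dplyr::select(tr, "pair_id", "end", "gene_id", "tpos",
                               "strand", "mismatches", "n_hits", "read_len",
                               "trim_side", "trim_cycles")
    }
  }

  evidence <- dplyr::bind_rows(c(g_ev, list(t_ev)))
  if (nrow(evidence) > 0) {
    evidence$trim_cycles <- 0L
    evidence$trim_side <- NA_character_
  }
  evidence <- merge_trimmed(trim_ev, evidence)
  if (nrow(evidence) > 0) evidence$lib <- lib

  counts <- c(pairs = n_pairs,
              `PE-S01` = sum(staging$stage == "PE-S01"),
              `SE-S01` = sum(staging$stage == "SE-S01"),
              `UM-S01` = length(um_s01),
              `SE-S02` = length(se_s02), `UM-S02` = length(um_s02),
              FUM = length(fum),
              `SE-S03` = if (is.null(trim_ev)) 0L else
                length(unique(trim_ev$pair_id)))
  list(evidence = evidence, fum = fum, ins = ins, rl = read_len,
       overlap = ovl, counts = counts, staging = staging)
}

#' Run the fusion-calling pipeline
#'
#' Executes the nine pipeline stages in order: genome alignment and pair
#' classification with insert-size estimation (S01), transcript
#' realignment of unmapped ends (S02), optional iterative trimming (S03),
#' evidence merging (S04), span-read search with deduplication,
#' orientation and candidate-pair filtering (S05), half-read bisection and
#' fused-region localization (S06, S07-a), partial-exhaustion junction
#' library construction and junc-read detection (S07-b), fusion calling
#' with support thresholds (S08), and final proximity/homology filtering
#' (S09).
#'
#' @param reads A read-pair tibble (`pair_id`, `end1`, `end2`), a list
#'   with `fastq1`/`fastq2` paths, or a named list of either form — one
#'   element per sequencing library, each staged with its own read length
#'   and insert-size statistics.
#' @param reference A `fusion_reference`, or a list with `fasta` and `gtf`
#'   paths.
#' @param config A [fusion_config()] list.
#' @return A `fusion_result`: list with `calls` (final fusion-call
#'   tibble), `prefilter_calls`, `report` (per-stage counts and
#'   parameters), `insert_stats` (per library), and `config`.
#' @export
run_fusion_pipeline <- function(reads, reference, config = fusion_config()) {
  cfg <- config
  if (!inherits(reference, "fusion_reference")) {
    stopifnot(is.list(reference), !is.null(reference$fasta),
              !is.null(reference$gtf))
    reference <- load_reference(reference$fasta, reference$gtf)
  }
  ref <- reference

  # normalize `reads` into a named list of read-pair tibbles
  as_lib <- function(x) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (is.list(x) && !is.null(x$fastq1))
      return(read_fastq_pairs(x$fastq1, x$fastq2))
    stop("unrecognized reads input", call. = FALSE)
  }
  libs <- if (is.data.frame(reads) || (is.list(reads) && !is.null(reads$fastq1)))
    list(lib1 = as_lib(reads))
  else lapply(reads, as_lib)
  if (is.null(names(libs)) || any(!nzchar(names(libs))))
    names(libs) <- paste0("lib", seq_along(libs))

  nrt_seqs <- vapply(ref$nrt, function(n) n$sequence, character(1))
  genome_idx <- build_seed_index(ref$genome,
                                 k = min(cfg$k, min(nchar(ref$genome))))
  tx_idx <- build_seed_index(nrt_seqs, k = min(cfg$k, min(nchar(nrt_seqs))))

  staged <- lapply(seq_along(libs), function(i) {
    stage_one_library(libs[[i]], ref, genome_idx, tx_idx, cfg, names(libs)[i])
  })
  names(staged) <- names(libs)

  evidence <- dplyr::bind_rows(lapply(staged, function(s) s$evidence))
  fum <- unlist(lapply(names(staged), function(nm) {
    f <- staged[[nm]]$fum
    if (length(f) > 0) names(f) <- paste0(nm, ":", names(f))
    f
  }))
  if (is.null(fum)) fum <- character(0)
  ins_tbl <- tibble::tibble(
    lib = names(staged),
    INS = unname(vapply(staged, function(s) s$ins$INS, numeric(1))),
    SD = unname(vapply(staged, function(s) s$ins$SD, numeric(1))),
    read_length = unname(vapply(staged, function(s) as.integer(s$rl),
                                integer(1))),
    overlap_fraction = unname(vapply(staged, function(s) s$overlap$fraction,
                                     numeric(1))),
    trimmed = unname(vapply(staged, function(s) s$overlap$trim, logical(1))))

  # S05: span reads, dedup, orientation, candidate filters
  span_raw <- find_span_reads(evidence)
  if (nrow(span_raw) > 0) {
    lib_of_pair <- dplyr::bind_rows(lapply(names(libs), function(nm)
      tibble::tibble(pair_id = libs[[nm]]$pair_id, lib = nm)))
    span_raw <- dplyr::left_join(span_raw, lib_of_pair, by = "pair_id")
  } else span_raw$lib <- character(0)
  span_dedup <- dedup_reads(span_raw)
  filt <- filter_gene_pairs(span_dedup, ref, cfg$homology_window,
                            cfg$homology_identity, cfg$families)
  pairs <- filt$pairs

  calls <- fusion_call_schema()
  n_uum <- 0L
  if (nrow(pairs) > 0 && length(fum) > 0) {
    cand_genes <- unique(c(pairs$up_gene, pairs$down_gene))
    cand_idx <- build_seed_index(nrt_seqs[cand_genes],
                                 k = min(cfg$hum_k,
                                         min(nchar(nrt_seqs[cand_genes]))))
    # S06: bisect FUM reads, align halves against candidate genes
    halves <- lapply(fum, bisect_read, min_half = cfg$hum_min_half)
    keep <- !vapply(halves, is.null, logical(1))
    fum <- fum[keep]; halves <- halves[keep]
    hum_seqs <- c(
      setNames(vapply(halves, `[[`, character(1), "left"),
               paste0(names(fum), "|L")),
      setNames(vapply(halves, `[[`, character(1), "right"),
               paste0(names(fum), "|R")))
    hum_len_of <- c(
      setNames(vapply(halves, `[[`, integer(1), "half_len"),
               paste0(names(fum), "|L")),
      setNames(vapply(halves, `[[`, integer(1), "half_len"),
               paste0(names(fum), "|R")))
    hum_hits <- align_end(hum_seqs, cand_idx, cfg$max_mismatch, cfg$max_hits)
    uum_parents <- unique(sub("\\|[LR]$", "", hum_hits$read_id))
    n_uum <- length(uum_parents)
    uum_seqs <- fum[uum_parents]

    per_pair <- lapply(seq_len(nrow(pairs)), function(i) {
      call_one_pair(pairs[i, ], filt$span_reads, hum_hits, hum_len_of,
                    uum_seqs, ref, ins_tbl, cfg)
    })
    calls <- dplyr::bind_rows(c(list(fusion_call_schema()), per_pair))
  }

  final <- final_filter_fusions(calls, ref, cfg$min_gene_distance,
                                cfg$homology_identity,
                                cfg$junction_flank_homology)
  ord <- order(sprintf("%s-%s", final$up_symbol, final$down_symbol),
               final$pos_5, final$pos_3)
  final <- final[ord, ]

  report <- list(
    libraries = ins_tbl,
    stage_counts = lapply(staged, function(s) s$counts),
    n_span_raw = nrow(span_raw),
    n_span_dedup = nrow(span_dedup),
    n_pairs_prefilter = nrow(dplyr::distinct(span_dedup, .data$up_gene,
                                             .data$down_gene)),
    n_pairs_postfilter = nrow(pairs),
    pair_filter_log = filt$log,
    n_uum = n_uum,
    n_calls_prefilter = nrow(calls),
    n_calls = nrow(final),
    final_filter_log = attr(final, "filter_log"))

  structure(list(calls = final, prefilter_calls = calls, report = report,
                 insert_stats = ins_tbl, config = cfg),
            class = "fusion_result")
}

# S06-S08 for a single candidate gene pair: fused regions from HUM halves
# and span geometry, credible/potential classification, partial-exhaustion
# junction library, junc-read detection and the per-pair call.
call_one_pair <- function(pair, span_reads, hum_hits, hum_len_of, uum_seqs,
                          ref, ins_tbl, cfg) {
  gu <- pair$up_gene; gd <- pair$down_gene
  nu <- ref$nrt[[gu]]; nd <- ref$nrt[[gd]]
  lu <- nchar(nu$sequence); ld <- nchar(nd$sequence)
  sp <- span_reads[span_reads$up_gene == gu & span_reads$down_gene == gd, ]
  if (!"lib" %in% names(sp) || any(is.na(sp$lib))) sp$lib <- ins_tbl$lib[1]

  # fused region 2 (span geometry), per supporting read's library stats
  r2u <- list(); r2d <- list()
  for (i in seq_len(nrow(sp))) {
    st <- ins_tbl[ins_tbl$lib == sp$lib[i], ]
    fr <- fused_region_from_span(
      list(MP1 = sp$mp_up[i], MP2 = sp$mp_down[i], RL1 = sp$rl_up[i],
           RL2 = sp$rl_down[i], INS = st$INS, SD = st$SD, FLB = cfg$FLB),
      up_len = lu, down_len = ld)
    r2u[[i]] <- fr$upstream; r2d[[i]] <- fr$downstream
  }
  r2u <- dplyr::bind_rows(r2u); r2d <- dplyr::bind_rows(r2d)
  if (nrow(r2u) == 0 || nrow(r2d) == 0) return(fusion_call_schema())

  # fused region 1 (mapped half-reads) on each gene of the pair
  hum_regions <- function(gene, tlen, role) {
    h <- hum_hits[hum_hits$target == gene, ]
    if (nrow(h) == 0)
      return(tibble::tibble(start = integer(), end = integer()))
    dplyr::bind_rows(lapply(seq_len(nrow(h)), function(j) {
      tag <- h$read_id[j]
      half <- if (endsWith(tag, "|L")) "left" else "right"
      fused_region_from_hum(list(pos = h$pos[j], strand = h$strand[j]),
                            hum_len_of[[tag]], half, role, tlen)
    }))
  }
  r1u <- hum_regions(gu, lu, "upstream")
  r1d <- hum_regions(gd, ld, "downstream")

  up_tiles <- enumerate_tiles(classify_subregions(r1u, r2u))
  down_tiles <- enumerate_tiles(classify_subregions(r1d, r2d))

  W <- cfg$W %||% max(ins_tbl$read_length)
  library <- build_junction_library(nu$sequence, nd$sequence, up_tiles,
                                    down_tiles, W, cfg$min_flank)
  if (nrow(library) == 0) return(fusion_call_schema())
  # only UUM reads with a mapped half on this gene pair can be junc-reads
  pair_parents <- unique(sub("\\|[LR]$", "",
                             hum_hits$read_id[hum_hits$target %in% c(gu, gd)]))
  junc <- detect_junc_reads(uum_seqs[intersect(names(uum_seqs), pair_parents)],
                            library, cfg$max_mismatch,
                            cfg$min_overhang, k = cfg$hum_k)
  call_fusions(list(up_gene = gu, down_gene = gd,
                    span_count = pair$span_count),
               library, junc, ref, cfg$min_span, cfg$min_junc,
               cfg$sample_id)
}

#' Write pipeline outputs (calls TSV and junction FASTA)
#'
#' @param result A `fusion_result`.
#' @param dir Output directory (created if needed).
#' @return Named list of paths (`calls`, `junctions`).
#' @export
write_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(calls = file.path(dir, "fusion_calls.tsv"),
                junctions = file.path(dir, "junction_sequences.fa"))
  write_fusion_calls(result$calls, paths$calls)
  write_junction_fasta(result$calls, paths$junctions)
  invisible(paths)
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d call(s) from %d candidate pair(s); %d span read(s) after dedup\n",
              nrow(x$calls), x$report$n_pairs_postfilter,
              x$report$n_span_dedup))
  if (nrow(x$calls) > 0)
    print(dplyr::select(x$calls, "up_symbol", "down_symbol", "pos_5",
                        "pos_3", "span_count", "junc_count"))
  invisible(x)
}
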