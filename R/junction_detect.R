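#' Map useful-unmapped reads against a junction library
#'
#' Each UUM read (a filtered-unmapped read with at least one mappable
#' half) is aligned end-to-end (ungapped, at most `max_mismatch`
#' mismatches, either orientation) against the junction sequences. A hit is
#' a junc-read only if it crosses the junction with at least `min_overhang`
#' bases on both sides. Identical placements (same library entry, position
#' and strand) are deduplicated.
#'
#' @param uum_reads Named character vector of UUM read sequences.
#' @param library Junction library tibble from
#'   [build_junction_library()] (columns `sequence`, `offset`).
#' @param max_mismatch Maximum mismatches (default 2).
#' @param min_overhang Minimum bases on each side of the junction
#'   (default 8).
#' @param k Seed length for the scan (default 15; reads shorter than `k`
#'   cannot be junc-reads).
#' @return Tibble with `lib_idx` (row of `library`), `read_id`, `pos`,
#'   `strand`, `mismatches`, `overhang_left`, `overhang_right`.
#' @export
detect_junc_reads <- function(uum_reads, library, max_mismatch = 2,
                              min_overhang = 8, k = 15) {
  empty <- tibble::tibble(lib_idx = integer(), read_id = character(),
                          pos = integer(), strand = character(),
                          mismatches = integer(), overhang_left = integer(),
                          overhang_right = integer())
  uum_reads <- uum_reads[nchar(uum_reads) >= k]
  if (length(uum_reads) == 0 || nrow(library) == 0) return(empty)
  ids <- names(uum_reads) %||% paste0("read", seq_along(uum_reads))
  both <- c(setNames(unname(uum_reads), paste0(ids, "+")),
            setNames(dna_revcomp(unname(uum_reads)), paste0(ids, "-")))
  idx <- build_seed_index(both, k = k)
  res <- fa_scan_refs(idx$ptr, library$sequence, as.integer(max_mismatch))
  if (length(res$ref) == 0) return(empty)
  tag <- idx$names[res$target]
  nt <- nchar(tag)
  read_len <- unname(nchar(both)[res$target])
  offset <- library$offset[res$ref]
  out <- tibble::tibble(
    lib_idx = res$ref,
    read_id = substr(tag, 1, nt - 1),
    pos = res$pos,
    strand = substr(tag, nt, nt),
    mismatches = res$mismatches,
    overhang_left = offset - res$pos + 1L,
    overhang_right = res$pos + read_len - 1L - offset) |>
    dplyr::filter(.data$overhang_left >= min_overhang,
                  .data$overhang_right >= min_overhang) |>
    dedup_reads(keys = c("lib_idx", "pos", "strand"))
  out
}

# exon-boundary preference used to break junc-support ties: 2 when both
# sites sit on block boundaries, 1 when one does, 0 otherwise
boundary_score <- function(nrt_up, nrt_down, U, D) {
  (U %in% nrt_up$blocks$tend) + (D %in% nrt_down$blocks$tstart)
}

# Microhomology at a junction makes breakpoints ambiguous: shifting the
# junction by d bases keeps the fused sequence identical whenever the bases
# moved across the junction agree between the two genes. Read evidence
# cannot distinguish such breakpoints, so the reported one is canonicalized
# to the equivalent breakpoint with the best exon-boundary score (ties to
# the smallest shift), mirroring the convention that fusions arise at
# splice sites when the data allow it.
canonicalize_breakpoint <- function(nrt_up, nrt_down, U, D, max_shift = 20) {
  up <- nrt_up$sequence; down <- nrt_down$sequence
  cands <- tibble::tibble(d = 0L, U = U, D = D)
  u <- U; dd <- D
  for (d in seq_len(max_shift)) {       # shift right: move a down base up
    if (u + 1 > nchar(up) || dd > nchar(down)) break
    if (substr(up, u + 1, u + 1) != substr(down, dd, dd)) break
    u <- u + 1L; dd <- dd + 1L
    cands <- dplyr::add_row(cands, d = d, U = u, D = dd)
  }
  u <- U; dd <- D
  for (d in seq_len(max_shift)) {       # shift left: move an up base down
    if (u < 1 || dd - 1 < 1) break
    if (substr(up, u, u) != substr(down, dd - 1, dd - 1)) break
    u <- u - 1L; dd <- dd - 1L
    cands <- dplyr::add_row(cands, d = -d, U = u, D = dd)
  }
  cands$bscore <- mapply(boundary_score, U = cands$U, D = cands$D,
                         MoreArgs = list(nrt_up = nrt_up, nrt_down = nrt_down))
  cands <- cands[order(-cands$bscore, abs(cands$d), cands$d), ]
  list(U = cands$U[1], D = cands$D[1])
}

#' Call fusions from span and junction evidence of one gene pair
#'
#' Each junc-read is first assigned to the junction sequence(s) it matches
#' with the fewest mismatches (best-hit assignment). Support is then
#' attributed to every source `(U, D)` connection of a matched library
#' sequence; the connection with maximal deduplicated junc-read support
#' wins, ties broken toward sites at exon boundaries and then by smallest
#' `(U, D)`, and the winning breakpoint is canonicalized within its
#' microhomology window. A call is emitted only when the pair has at least
#' `min_span` span reads and the winning site at least `min_junc` junc
#' reads.
#'
#' @param pair List with `up_gene`, `down_gene`, `span_count`.
#' @param library Junction library tibble for the pair.
#' @param junc Junc-read tibble from [detect_junc_reads()].
#' @param ref A `fusion_reference`.
#' @param min_span,min_junc Support thresholds (default 2 and 2).
#' @param sample_id Sample label for the output row.
#' @return One-row fusion-call tibble, or a zero-row tibble when the pair
#'   does not reach the thresholds.
#' @export
call_fusions <- function(pair, library, junc, ref, min_span = 2,
                         min_junc = 2, sample_id = "sample") {
  empty <- fusion_call_schema()
  if (pair$span_count < min_span || nrow(junc) == 0) return(empty)
  # best-hit assignment: a junc-read supports only the junction sequences
  # it matches with the fewest mismatches, so support does not smear onto
  # nearby candidates that the read fits one extra mismatch worse
  junc <- junc |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$mismatches == min(.data$mismatches)) |>
    dplyr::ungroup()
  support <- junc |> dplyr::count(.data$lib_idx, name = "junc_count")
  # expand support onto every source (U, D) connection of each matched
  # library sequence; ambiguous support is attributed to all sources
  n_src <- vapply(library$src_U[support$lib_idx], length, integer(1))
  cand <- tibble::tibble(
    lib_idx = rep(support$lib_idx, n_src),
    junc_count = rep(support$junc_count, n_src),
    U = unlist(library$src_U[support$lib_idx], use.names = FALSE),
    D = unlist(library$src_D[support$lib_idx], use.names = FALSE),
    sequence = rep(library$sequence[support$lib_idx], n_src),
    offset = rep(library$offset[support$lib_idx], n_src))
  nu <- ref$nrt[[pair$up_gene]]; nd <- ref$nrt[[pair$down_gene]]
  cand$bscore <- mapply(boundary_score, U = cand$U, D = cand$D,
                        MoreArgs = list(nrt_up = nu, nrt_down = nd))
  cand <- dplyr::arrange(cand, dplyr::desc(.data$junc_count),
                         dplyr::desc(.data$bscore), .data$U, .data$D)
  best <- cand[1, ]
  if (best$junc_count < min_junc) return(empty)
  canon <- canonicalize_breakpoint(nu, nd, best$U, best$D)
  symbols <- setNames(ref$genes$symbol, ref$genes$gene_id)
  tibble::tibble(
    sample_id = sample_id,
    up_gene = pair$up_gene, down_gene = pair$down_gene,
    up_symbol = unname(symbols[pair$up_gene]),
    down_symbol = unname(symbols[pair$down_gene]),
    chrom_5 = nu$chrom, chrom_3 = nd$chrom,
    U = canon$U, D = canon$D,
    pos_5 = map_transcript_coord(nu, canon$U),
    pos_3 = map_transcript_coord(nd, canon$D),
    span_count = pair$span_count,
    junc_count = best$junc_count,
    junction_seq = best$sequence,
    junction_offset = best$offset)
}

fusion_call_schema <- function() {
  tibble::tibble(
    sample_id = character(), up_gene = character(), down_gene = character(),
    up_symbol = character(), down_symbol = character(),
    chrom_5 = character(), chrom_3 = character(),
    U = integer(), D = integer(), pos_5 = integer(), pos_3 = integer(),
    span_count = integer(), junc_count = integer(),
    junction_seq = character(), junction_offset = integer())
}

#' Final filtering of fusion calls
#'
#' Two guards against recurrent false positives: calls between genes whose
#' genomic spans lie within `min_gene_distance` on the same chromosome are
#' removed unless both junction sites sit at exon boundaries
#' (read-through/proximity guard); and calls whose junction-adjacent
#' sequence windows are mutually homologous (ungapped identity at or above
#' `homology_identity` over the flank width, either orientation, comparing
#' what follows the upstream site on its own gene against the downstream
#' flank and vice versa) are removed as alignment artifacts.
#'
#' @param calls Fusion-call tibble from [call_fusions()].
#' @param ref A `fusion_reference`.
#' @param min_gene_distance Proximity threshold in bp (default 10,000).
#' @param homology_identity Identity threshold (default 0.90).
#' @param flank Window width in nt used for the homology comparison
#'   (default 60).
#' @return Filtered calls tibble; removed calls are recorded in the
#'   `filter_log` attribute.
#' @export
final_filter_fusions <- function(calls, ref, min_gene_distance = 10000,
                                 homology_identity = 0.90, flank = 60) {
  if (nrow(calls) == 0) {
    attr(calls, "filter_log") <- tibble::tibble(up_gene = character(),
                                                down_gene = character(),
                                                reason = character())
    return(calls)
  }
  keep <- rep(TRUE, nrow(calls))
  reasons <- character(0); rg_up <- character(0); rg_dn <- character(0)
  for (i in seq_len(nrow(calls))) {
    nu <- ref$nrt[[calls$up_gene[i]]]; nd <- ref$nrt[[calls$down_gene[i]]]
    # proximity / read-through guard
    if (nu$chrom == nd$chrom) {
      gap <- max(min(nu$blocks$gstart), min(nd$blocks$gstart)) -
        min(max(nu$blocks$gend), max(nd$blocks$gend))
      at_boundaries <- boundary_score(nu, nd, calls$U[i], calls$D[i]) == 2
      if (gap < min_gene_distance && !at_boundaries) {
        keep[i] <- FALSE
        reasons <- c(reasons, "proximity"); rg_up <- c(rg_up, calls$up_gene[i])
        rg_dn <- c(rg_dn, calls$down_gene[i])
        next
      }
    }
    # junction-flank homology: the upstream gene's own continuation past U
    # vs the fused downstream flank, and the downstream gene's own sequence
    # before D vs the fused upstream flank
    U <- calls$U[i]; D <- calls$D[i]
    up_cont <- substr(nu$sequence, U + 1, min(nchar(nu$sequence), U + flank))
    down_flank <- substr(nd$sequence, D, min(nchar(nd$sequence), D + flank - 1))
    down_cont <- substr(nd$sequence, max(1, D - flank), D - 1)
    up_flank <- substr(nu$sequence, max(1, U - flank + 1), U)
    idt <- function(a, b, anchor) {
      n <- min(nchar(a), nchar(b))
      if (n < 20) return(0)
      if (anchor == "left") {            # both windows run rightward
        a <- substr(a, 1, n); b <- substr(b, 1, n)
      } else {                           # both end at the junction
        a <- substr(a, nchar(a) - n + 1, nchar(a))
        b <- substr(b, nchar(b) - n + 1, nchar(b))
      }
      max(seq_identity(a, b), seq_identity(a, dna_revcomp(b)))
    }
    if (idt(up_cont, down_flank, "left") >= homology_identity ||
        idt(up_flank, down_cont, "right") >= homology_identity) {
      keep[i] <- FALSE
      reasons <- c(reasons, "junction_homology")
      rg_up <- c(rg_up, calls$up_gene[i]); rg_dn <- c(rg_dn, calls$down_gene[i])
    }
  }
  out <- calls[keep, ]
  attr(out, "filter_log") <- tibble::tibble(up_gene = rg_up, down_gene = rg_dn,
                                            reason = reasons)
  out
}
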