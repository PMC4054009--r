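#' Build an exact k-mer seed index over target sequences
#'
#' Forward-strand postings are stored; [seed_lookup()] answers queries for
#' both strands by also probing the reverse complement of the query k-mer.
#'
#' @param targets Named character vector of uppercase target sequences
#'   (chromosomes or non-redundant transcripts).
#' @param k Seed length in nt (default 21; must be at least 8 and no longer
#'   than the shortest target).
#' @return A `seed_index` object (external pointer plus metadata).
#' @export
build_seed_index <- function(targets, k = 21, fallback_k = 10) {
  stopifnot(k >= 8)
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("targets must be named", call. = FALSE)
  check_dna_alphabet(targets, "target")
  ptr <- fa_build_index(names(targets), unname(targets), as.integer(k))
  env <- new.env(parent = emptyenv())
  env$fallback <- NULL
  structure(list(ptr = ptr, k = as.integer(k), names = names(targets),
                 lengths = setNames(nchar(targets), names(targets)),
                 targets = targets, fallback_k = as.integer(fallback_k),
                 env = env),
            class = "seed_index")
}

# reads shorter than 3k cannot carry three disjoint seeds, so two
# mismatches may evade every seed; they are re-routed to a lazily built
# small-k index over the same targets
fallback_index <- function(index) {
  if (is.null(index$env$fallback)) {
    fk <- max(8L, min(index$fallback_k, min(index$lengths)))
    index$env$fallback <- structure(
      list(ptr = fa_build_index(index$names, unname(index$targets), fk),
           k = fk, names = index$names, lengths = index$lengths,
           targets = index$targets, fallback_k = fk,
           env = new.env(parent = emptyenv())),
      class = "seed_index")
  }
  index$env$fallback
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d over %d target(s), %d nt total\n",
              x$k, length(x$names), sum(x$lengths)))
  invisible(x)
}

#' Look up one k-mer in a seed index
#'
#' @param index A `seed_index`.
#' @param kmer A single DNA string of length `k`.
#' @return Tibble with `target`, `pos` (1-based leftmost base of the
#'   matching window on the target's forward strand) and `strand` (`+` when
#'   the k-mer matches the forward strand, `-` when its reverse complement
#'   does).
#' @export
seed_lookup <- function(index, kmer) {
  res <- fa_lookup(index$ptr, kmer)
  tibble::tibble(target = index$names[res$target], pos = res$pos,
                 strand = res$strand) |>
    dplyr::arrange(.data$target, .data$pos, .data$strand)
}

#' Align read ends end-to-end against an index
#'
#' Seed-and-verify ungapped alignment: every full-length placement of each
#' read (either strand) with at most `max_mismatch` mismatches is reported,
#' ranked by mismatch count then (target, position), and truncated to
#' `max_hits` placements with a truncation flag. `N` bases always count as
#' mismatches. An absent read id in the result means the read is unmapped.
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids), or an unnamed vector (ids default to `read1`, `read2`, ...).
#' @param index A `seed_index`.
#' @param max_mismatch Maximum mismatches per placement (default 2).
#' @param max_hits Maximum placements reported per read (default 5).
#' @return Tibble with `read_id`, `target`, `pos`, `strand`, `mismatches`,
#'   `n_hits` (total placements found for the read) and `truncated`.
#' @export
align_end <- function(reads, index, max_mismatch = 2, max_hits = 5) {
  if (length(reads) == 0)
    return(tibble::tibble(read_id = character(), target = character(),
                          pos = integer(), strand = character(),
                          mismatches = integer(), n_hits = integer(),
                          truncated = logical()))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  names(reads) <- ids
  lens <- nchar(reads)
  # reads long enough for three disjoint seeds use the primary index;
  # shorter reads (but >= k) fall back to a small-k index
  short <- lens < 3 * index$k & lens >= index$k
  run <- function(rd, idx) {
    if (length(rd) == 0)
      return(NULL)
    res <- fa_align(idx$ptr, unname(rd), as.integer(max_mismatch),
                    as.integer(max_hits))
    tibble::tibble(read_id = names(rd)[res$read],
                   target = idx$names[res$target],
                   pos = res$pos, strand = res$strand,
                   mismatches = res$mismatches,
                   n_hits = res$n_hits[res$read],
                   truncated = res$truncated[res$read])
  }
  out <- dplyr::bind_rows(
    run(reads[!short], index),
    run(reads[short], fallback_index(index)))
  if (is.null(out) || nrow(out) == 0)
    return(tibble::tibble(read_id = character(), target = character(),
                          pos = integer(), strand = character(),
                          mismatches = integer(), n_hits = integer(),
                          truncated = logical()))
  out[order(match(out$read_id, ids)), ]
}

#' Classify read pairs by their genome alignments
#'
#' Stage `PE-S01`: some combination of end hits lies on the same
#' chromosome, head-to-head (the plus-strand end leftmost, the minus-strand
#' end rightmost), with an implied fragment shorter than
#' `max_insert` (10,000 bp by default). Stage `SE-S01`: exactly one end has
#' hits, or both ends map but every combination violates the orientation or
#' insert constraint. Stage `UM-S01`: neither end maps.
#'
#' @param pairs Tibble with columns `pair_id`, `end1`, `end2` (sequences).
#' @param hits1,hits2 Alignment hits for ends 1 and 2 (from [align_end()],
#'   read ids equal to `pair_id`).
#' @param max_insert Maximum proper fragment length in bp.
#' @return Tibble `pair_id`, `stage`, and for PE pairs `fragment` (outer
#'   distance of the best proper placement, in bp).
#' @export
classify_pairs <- function(pairs, hits1, hits2, max_insert = 10000) {
  # fragment = outer distance, inclusive: rightmost mapped base of the
  # downstream (minus-strand) end minus leftmost base of the plus end + 1
  rl1 <- setNames(nchar(pairs$end1), pairs$pair_id)
  rl2 <- setNames(nchar(pairs$end2), pairs$pair_id)
  proper <- dplyr::inner_join(hits1, hits2, by = c("read_id", "target"),
                              suffix = c("1", "2"), relationship = "many-to-many") |>
    dplyr::filter(.data$strand1 != .data$strand2) |>
    dplyr::mutate(
      left_pos = ifelse(.data$strand1 == "+", .data$pos1, .data$pos2),
      right_pos = ifelse(.data$strand1 == "+", .data$pos2, .data$pos1),
      minus_len = ifelse(.data$strand1 == "+", rl2[.data$read_id], rl1[.data$read_id]),
      fragment = .data$right_pos + .data$minus_len - 1 - .data$left_pos + 1) |>
    dplyr::filter(.data$left_pos <= .data$right_pos,
                  .data$fragment > 0, .data$fragment < max_insert) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(fragment = .data$fragment[which.min(.data$mismatches1 + .data$mismatches2)],
                     .groups = "drop")

  mapped1 <- unique(hits1$read_id)
  mapped2 <- unique(hits2$read_id)
  tibble::tibble(pair_id = pairs$pair_id) |>
    dplyr::left_join(proper, by = c(pair_id = "read_id")) |>
    dplyr::mutate(stage = dplyr::case_when(
      !is.na(fragment) ~ "PE-S01",
      pair_id %in% mapped1 | pair_id %in% mapped2 ~ "SE-S01",
      TRUE ~ "UM-S01"))
}

#' Estimate insert-size statistics from properly paired reads
#'
#' `INS` is the mean and `SD` the sample standard deviation of the implied
#' fragment lengths (outer distance, inclusive) of `PE-S01` pairs. With
#' `robust = TRUE` the estimate is restricted to fragments near the density
#' peak before averaging, which guards against fragment lengths inflated by
#' introns when pairs are measured in genome space on spliced transcripts.
#'
#' @param fragments Numeric vector of implied fragment lengths (bp), e.g.
#'   the `fragment` column of [classify_pairs()] output for PE pairs.
#' @param robust Restrict to the peak window before computing moments.
#' @param peak_halfwidth Half-width (bp) of the window around the density
#'   mode used when `robust = TRUE`.
#' @return A list with `INS` and `SD` (both in bp) and `n_used`.
#' @export
estimate_insert_size <- function(fragments, robust = FALSE, peak_halfwidth = 50) {
  fragments <- fragments[!is.na(fragments)]
  if (length(fragments) < 2)
    stop(paste("fewer than 2 properly paired fragments; supply INS/SD",
               "explicitly in the configuration"), call. = FALSE)
  used <- fragments
  if (robust && length(fragments) >= 10) {
    d <- density(fragments)
    mode_est <- d$x[which.max(d$y)]
    for (i in 1:2) {
      keep <- abs(fragments - mode_est) <= peak_halfwidth
      if (sum(keep) >= 2) mode_est <- mean(fragments[keep])
    }
    used <- fragments[abs(fragments - mode_est) <= peak_halfwidth]
    if (length(used) < 2) used <- fragments
  }
  list(INS = mean(used), SD = sd(used), n_used = length(used))
}

#' Align unmapped ends to non-redundant transcripts
#'
#' Realigns the unmapped read ends of `UM-S01` (and the unmapped mates of
#' `SE-S01` pairs) against the non-redundant transcript index. Pairs that
#' were fully unmapped and gain at least one transcript hit move to stage
#' `SE-S02`; the remainder stay `UM-S02`.
#'
#' @param um_reads Named character vector of unmapped read sequences, names
#'   of the form `<pair_id>/<end>`.
#' @param transcript_index A `seed_index` over non-redundant transcripts.
#' @param max_mismatch,max_hits As in [align_end()].
#' @return List with `hits` (transcript-space hits tibble) and
#'   `mapped_reads` (character vector of read names that gained a hit).
#' @export
align_to_transcripts <- function(um_reads, transcript_index,
                                 max_mismatch = 2, max_hits = 5) {
  hits <- align_end(um_reads, transcript_index, max_mismatch, max_hits)
  list(hits = hits, mapped_reads = unique(hits$read_id))
}

#' Filter small-indel artifacts out of the unmapped set
#'
#' Reads placeable end-to-end on a transcript with exactly one insertion or
#' deletion of at most `max_gap` bases (plus at most `max_mismatch`
#' substitutions) are treated as small-indel artifacts and removed; the
#' survivors form the filtered-unmapped (FUM) set, the candidate junction
#' evidence.
#'
#' @param um_reads Named character vector of reads unmapped to genome and
#'   transcripts.
#' @param transcript_index A `seed_index` over non-redundant transcripts.
#' @param max_gap Maximum indel size in nt (default 5).
#' @param max_mismatch Maximum substitutions alongside the gap.
#' @return Named character vector: the FUM reads.
#' @export
collect_fum <- function(um_reads, transcript_index, max_gap = 5,
                        max_mismatch = 2) {
  if (length(um_reads) == 0) return(um_reads)
  rescued <- fa_gap_rescue(transcript_index$ptr, unname(um_reads),
                           as.integer(max_mismatch), as.integer(max_gap))
  um_reads[!rescued]
}
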