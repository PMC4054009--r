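#' Bisect an unmapped read into two isometric halves
#'
#' Both halves get length `floor(length / 2)`; for odd read lengths the
#' middle base is dropped so the halves stay isometric.
#'
#' @param fum_read A single DNA string.
#' @param min_half Minimum mappable half length; shorter reads are skipped
#'   (returns `NULL`).
#' @return List with `left`, `right` (strings) and `half_len`, or `NULL`.
#' @export
bisect_read <- function(fum_read, min_half = 20) {
  L <- nchar(fum_read)
  half <- as.integer(L %/% 2)
  if (half < min_half) return(NULL)
  list(left = substr(fum_read, 1, half),
       right = substr(fum_read, L - half + 1, L),
       half_len = half)
}

#' Fused region implied by a mapped half-read
#'
#' A half-read (HUM read) that maps cleanly to one gene of a candidate pair
#' localizes the junction inside the adjacent one-half-read-length window
#' on the side where its unmapped sibling half lies. For a plus-orientation
#' hit, a mapped left half at position `p` gives the region
#' `[p + hum_len, p + 2 * hum_len - 1]` and a mapped right half gives
#' `[p - hum_len, p - 1]`; minus-orientation hits mirror the side. Regions
#' are clipped to the transcript bounds.
#'
#' @param hum_hit One-row tibble or list with `pos` (1-based leftmost
#'   transcript coordinate) and `strand`.
#' @param hum_len Half-read length in nt.
#' @param which_half `"left"` or `"right"` (in read orientation).
#' @param gene_role `"upstream"` or `"downstream"` (metadata only).
#' @param transcript_len Length of the gene's non-redundant transcript,
#'   used for clipping.
#' @return Tibble with `start`, `end`, `source = "HUM"`, `gene_role`; zero
#'   rows when the region is clipped away entirely.
#' @export
fused_region_from_hum <- function(hum_hit, hum_len, which_half,
                                  gene_role = NA_character_,
                                  transcript_len = Inf) {
  stopifnot(which_half %in% c("left", "right"))
  p <- hum_hit$pos
  unmapped_right <- xor(which_half == "left", hum_hit$strand == "-")
  if (unmapped_right) {
    start <- p + hum_len; end <- p + 2 * hum_len - 1
  } else {
    start <- p - hum_len; end <- p - 1
  }
  start <- max(1, start); end <- min(transcript_len, end)
  if (start > end)
    return(tibble::tibble(start = integer(), end = integer(),
                          source = character(), gene_role = character()))
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 source = "HUM", gene_role = gene_role)
}

#' Fused regions implied by a span read's insert-size geometry
#'
#' With end 1 of a span read mapped at transcript position `MP1` on the
#' upstream gene and end 2 at `MP2` on the downstream gene, read lengths
#' `RL1`/`RL2`, insert-size statistics `INS`/`SD` and a flanking allowance
#' `FLB`, the junction site must lie in
#' `[MP1 + RL1 - FLB, MP1 + INS + 3 SD - RL2 + FLB - 1]` on the upstream
#' gene and in `[MP2 + RL2 - INS - 3 SD + RL1 - FLB, MP2 + FLB - 1]` on the
#' downstream gene. `SD` is rounded up to an integer before use, and each
#' interval is clipped to its transcript's bounds.
#'
#' @param p List with `MP1`, `MP2`, `RL1`, `RL2`, `INS`, `SD`, `FLB`.
#' @param up_len,down_len Transcript lengths for clipping (default
#'   unbounded).
#' @return List of two tibbles, `upstream` and `downstream`, each with
#'   `start`, `end`, `source = "SPAN"`; a tibble has zero rows when its
#'   interval is empty after clipping.
#' @export
fused_region_from_span <- function(p, up_len = Inf, down_len = Inf) {
  sd3 <- 3 * ceiling(p$SD)
  ins <- round(p$INS)
  up <- c(p$MP1 + p$RL1 - p$FLB,
          p$MP1 + ins + sd3 - p$RL2 + p$FLB - 1)
  dn <- c(p$MP2 + p$RL2 - ins - sd3 + p$RL1 - p$FLB,
          p$MP2 + p$FLB - 1)
  clip <- function(iv, len) {
    s <- max(1, iv[1]); e <- min(len, iv[2])
    if (s > e) tibble::tibble(start = integer(), end = integer(),
                              source = character())
    else tibble::tibble(start = as.integer(s), end = as.integer(e),
                        source = "SPAN")
  }
  list(upstream = clip(up, up_len), downstream = clip(dn, down_len))
}

#' Split a span-derived fused region into credible and potential parts
#'
#' The credible part of fused region 2 is its overlap with the union of
#' the half-read-derived regions (fused region 1); everything else in
#' region 2 is potential. The output intervals are disjoint and cover
#' region 2 exactly.
#'
#' @param region1_set Tibble of HUM-derived intervals (`start`, `end`);
#'   may have zero rows.
#' @param region2 Tibble of span-derived intervals (`start`, `end`).
#' @return Tibble with `start`, `end`, `class` (`"credible"` or
#'   `"potential"`), sorted by `start`.
#' @export
classify_subregions <- function(region1_set, region2) {
  r2 <- IRanges::reduce(IRanges::IRanges(region2$start, region2$end))
  r1 <- if (is.null(region1_set) || nrow(region1_set) == 0)
    IRanges::IRanges() else
    IRanges::reduce(IRanges::IRanges(region1_set$start, region1_set$end))
  credible <- IRanges::intersect(r2, r1)
  potential <- IRanges::setdiff(r2, credible)
  out <- dplyr::bind_rows(
    tibble::tibble(start = IRanges::start(credible),
                   end = IRanges::end(credible), class = "credible"),
    tibble::tibble(start = IRanges::start(potential),
                   end = IRanges::end(potential), class = "potential"))
  dplyr::arrange(out, .data$start)
}
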