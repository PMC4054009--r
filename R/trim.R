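#' Estimate the fraction of fragments with overlapping 3' ends
#'
#' Library protocols can produce fragments shorter than the summed read
#' lengths, so the two 3' ends overlap; reads whose overlap covers a fusion
#' junction cannot map and would be lost. Under a Normal(INS, SD) fragment
#' model the overlapped fraction is `P(insert < 2 * read_length)`. Trimming
#' is triggered when this fraction exceeds `threshold` (20% by default) or
#' when forced by configuration.
#'
#' @param stats List with `INS` and `SD` (bp), as from
#'   [estimate_insert_size()].
#' @param read_length Read length in nt (per end).
#' @param threshold Trigger fraction (default 0.20).
#' @param force Trim regardless of the estimate.
#' @return List with `fraction` and logical `trim`.
#' @export
overlapped_end_fraction <- function(stats, read_length, threshold = 0.20,
                                    force = FALSE) {
  fraction <- if (stats$SD <= 0) as.numeric(2 * read_length > stats$INS)
              else pnorm(2 * read_length, mean = stats$INS, sd = stats$SD)
  list(fraction = fraction, trim = force || fraction > threshold)
}

#' Iteratively trim and realign one unmapped read
#'
#' Phase 1 removes `step` nt from the 3' end and realigns after each cut,
#' stopping at the first successful alignment; if the read is exhausted
#' down to `min_len` without a hit, phase 2 restores the full read and
#' trims from the 5' end the same way. The trimmed length never drops below
#' `min_len` (30 nt by default). Failure is a value, not an error.
#'
#' @param fum_read A single DNA string (an unmapped read).
#' @param transcript_index A `seed_index` over non-redundant transcripts.
#' @param step Bases removed per cycle (default 5).
#' @param min_len Minimum trimmed read length (default 30).
#' @param max_mismatch,max_hits Alignment parameters, as [align_end()].
#' @return List with `mapped` (logical), `trimmed_read`, `hits` (tibble),
#'   `side` (`"3p"`, `"5p"` or `NA`), `cycles_3prime`, `cycles_5prime`.
#' @export
trim_and_realign <- function(fum_read, transcript_index, step = 5,
                             min_len = 30, max_mismatch = 2, max_hits = 5) {
  L <- nchar(fum_read)
  fail <- list(mapped = FALSE, trimmed_read = NA_character_,
               hits = NULL, side = NA_character_,
               cycles_3prime = 0L, cycles_5prime = 0L)
  if (L < min_len + step) return(fail)
  max_cycles <- (L - min_len) %/% step
  c3 <- 0L; c5 <- 0L
  for (cycle in seq_len(max_cycles)) {       # phase 1: trim the 3' end
    c3 <- cycle
    trimmed <- substr(fum_read, 1, L - step * cycle)
    hits <- align_end(c(trimmed = trimmed), transcript_index,
                      max_mismatch, max_hits)
    if (nrow(hits) > 0)
      return(list(mapped = TRUE, trimmed_read = trimmed, hits = hits,
                  side = "3p", cycles_3prime = c3, cycles_5prime = 0L))
  }
  for (cycle in seq_len(max_cycles)) {       # phase 2: restore, trim the 5' end
    c5 <- cycle
    trimmed <- substr(fum_read, step * cycle + 1, L)
    hits <- align_end(c(trimmed = trimmed), transcript_index,
                      max_mismatch, max_hits)
    if (nrow(hits) > 0)
      return(list(mapped = TRUE, trimmed_read = trimmed, hits = hits,
                  side = "5p", cycles_3prime = c3, cycles_5prime = c5))
  }
  fail$cycles_3prime <- c3
  fail$cycles_5prime <- c5
  fail
}

# batch trimming used by the pipeline: all reads are cut together and the
# still-unmapped ones carried to the next cycle, which keeps alignment calls
# vectorized. Returns a tibble of transcript-space evidence rows.
trim_fum_batch <- function(fum_reads, transcript_index, step = 5,
                           min_len = 30, max_mismatch = 2, max_hits = 5) {
  empty <- tibble::tibble(read_id = character(), target = character(),
                          pos = integer(), strand = character(),
                          mismatches = integer(), n_hits = integer(),
                          truncated = logical(), read_len = integer(),
                          trim_side = character(), trim_cycles = integer())
  if (length(fum_reads) == 0) return(empty)
  out <- list()
  for (side in c("3p", "5p")) {
    pending <- fum_reads
    lens <- nchar(pending)
    max_cycles <- pmax((lens - min_len) %/% step, 0L)
    cycle <- 0L
    while (length(pending) > 0) {
      cycle <- cycle + 1L
      lens <- nchar(fum_reads[names(pending)])
      keep <- (lens - min_len) %/% step >= cycle
      pending <- pending[keep]
      if (length(pending) == 0) break
      full <- fum_reads[names(pending)]
      trimmed <- if (side == "3p") substr(unname(full), 1, nchar(full) - step * cycle)
                 else substr(unname(full), step * cycle + 1, nchar(full))
      trimmed <- setNames(trimmed, names(full))
      hits <- align_end(trimmed, transcript_index, max_mismatch, max_hits)
      if (nrow(hits) > 0) {
        hits$read_len <- unname(nchar(trimmed)[match(hits$read_id,
                                                     names(trimmed))])
        hits$trim_side <- side
        hits$trim_cycles <- cycle
        out[[length(out) + 1]] <- hits
        pending <- pending[!names(pending) %in% hits$read_id]
      }
    }
    # a read recovered in the 3' phase is not retried from the 5' end
    recovered <- unique(unlist(lapply(out, function(h) h$read_id)))
    fum_reads <- fum_reads[!names(fum_reads) %in% recovered]
    if (length(fum_reads) == 0) break
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Merge trimmed-read evidence with prior single-end evidence
#'
#' Union of the single-end transcript-space evidence gathered across the
#' alignment stages, with trim provenance on every row (which side was
#' trimmed and how many cycles; `NA`/0 for untrimmed evidence). Conflicting
#' duplicate evidence for the same (read, end) is kept and flagged via
#' `n_hits`.
#'
#' @param se_s03 Evidence tibble for mapped trimmed reads (may have 0 rows).
#' @param prior Evidence tibble of untrimmed single-end transcript hits.
#' @return Combined evidence tibble.
#' @export
merge_trimmed <- function(se_s03, prior) {
  cols <- c("trim_side", "trim_cycles")
  for (cc in cols) {
    if (!cc %in% names(prior))
      prior[[cc]] <- if (cc == "trim_cycles") 0L else NA_character_
  }
  if (is.null(se_s03) || nrow(se_s03) == 0) return(prior)
  dplyr::bind_rows(prior, se_s03)
}
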