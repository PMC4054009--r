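#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA
#'
#' Uniform i.i.d. bases; used by the simulator for chromosome backbones.
#'
#' @param n Sequence length in nt.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# validate a DNA alphabet; returns invisibly or errors
check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                 what, names(x)[bad][1] %||% which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ungapped identity between two equal-length windows, in [0, 1]
seq_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  n <- nchar(a)
  if (n == 0) return(0)
  1 - fa_hamming(a, b) / n
}
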