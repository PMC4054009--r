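Package: fusejunc
Title: Fusion Transcript Discovery from Paired-End RNA-Seq via Span and
    Junction Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fusion transcripts from paired-end RNA-seq read pairs
    and an annotated reference. Discordant read pairs whose two ends map to
    different genes (span-reads) nominate candidate fusion gene pairs; the
    junction site is then localized at single-base resolution by building a
    partial-exhaustion library of candidate junction sequences, constrained
    by half-read mapping evidence, and mapping the remaining unmapped reads
    against it (junc-reads). Includes an internal seed-and-verify read
    aligner, a paired-end RNA-seq read simulator with fusion truth tables,
    and false-negative/false-positive evaluation of calls against simulated
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
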