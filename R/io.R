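#' Read a pair of FASTQ files into a read-pair tibble
#'
#' Files are read in lockstep; read names may carry `/1` and `/2` suffixes
#' (stripped to form the pair id) or be bare and positionally paired.
#' Quality scores are parsed by the FASTQ reader but not used by the
#' caller.
#'
#' @param fastq1,fastq2 Paths to the two mate files.
#' @return Tibble with `pair_id`, `end1`, `end2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2))
    stop(sprintf("mate files differ in read count (%d vs %d)",
                 length(r1), length(r2)), call. = FALSE)
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  tibble::tibble(pair_id = ids,
                 end1 = unname(toupper(as.character(r1))),
                 end2 = unname(toupper(as.character(r2))))
}

#' Write fusion calls as a TSV
#'
#' One row per call with columns `sample_id`, `fusion_genes_5_3`,
#' `chrom_5`, `chrom_3`, `pos_5`, `pos_3`, `span_count`, `junc_count`,
#' `junction_seq`, in deterministic order (gene symbols, then
#' coordinates). A call set of size zero yields a header-only file.
#'
#' @param calls Fusion-call tibble.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  out <- tibble::tibble(
    sample_id = calls$sample_id,
    fusion_genes_5_3 = sprintf("%s-%s", calls$up_symbol, calls$down_symbol),
    chrom_5 = calls$chrom_5, chrom_3 = calls$chrom_3,
    pos_5 = calls$pos_5, pos_3 = calls$pos_3,
    span_count = calls$span_count, junc_count = calls$junc_count,
    junction_seq = calls$junction_seq)
  out <- out[order(out$fusion_genes_5_3, out$pos_5, out$pos_3), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a fusion-call TSV
#'
#' @param path TSV written by [write_fusion_calls()].
#' @return Tibble in the on-disk column schema.
#' @export
read_fusion_calls <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t",
                               colClasses = c(
                                 sample_id = "character",
                                 fusion_genes_5_3 = "character",
                                 chrom_5 = "character",
                                 chrom_3 = "character",
                                 pos_5 = "integer", pos_3 = "integer",
                                 span_count = "integer",
                                 junc_count = "integer",
                                 junction_seq = "character")))
}

#' Write predicted junction sequences as FASTA
#'
#' Headers encode `geneU:geneD:pos5:pos3` (gene symbols and genomic
#' junction coordinates), supporting downstream primer design.
#'
#' @param calls Fusion-call tibble.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_junction_fasta <- function(calls, path) {
  ord <- order(sprintf("%s-%s", calls$up_symbol, calls$down_symbol),
               calls$pos_5, calls$pos_3)
  calls <- calls[ord, ]
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(calls$junction_seq)
  names(x) <- sprintf("%s:%s:%d:%d", calls$up_symbol, calls$down_symbol,
                      calls$pos_5, calls$pos_3)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
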