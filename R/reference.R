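#' Load a genome and gene annotation into an annotated reference
#'
#' Reads a FASTA genome and a GTF annotation (exon records carrying
#' `gene_id` and `transcript_id` attributes), validates them against each
#' other, and builds one non-redundant transcript per gene: the interval
#' union of all annotated exons, in gene-strand orientation, with a
#' bidirectional map between transcript and genome coordinates.
#'
#' All coordinates are 1-based and inclusive throughout the package;
#' conversions to other conventions happen only at file-format boundaries.
#'
#' @param genome_fasta Path to a FASTA file of chromosome sequences.
#' @param annotation Path to a GTF file. Feature types other than `exon`
#'   are ignored (with a message).
#' @return A `fusion_reference` object: a list with `genome` (named
#'   character vector of uppercase chromosome sequences), `genes` (tibble:
#'   `gene_id`, `symbol`, `chrom`, `strand`), `exons` (tibble of exon
#'   records), and `nrt` (named list of non-redundant transcripts, see
#'   [build_nonredundant_transcript()]).
#' @export
load_reference <- function(genome_fasta, annotation) {
  genome_set <- tryCatch(
    Biostrings::readDNAStringSet(genome_fasta),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", genome_fasta,
                                     conditionMessage(e)), call. = FALSE))
  genome <- toupper(as.character(genome_set))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in FASTA", call. = FALSE)
  check_dna_alphabet(genome, "genome")

  gr <- tryCatch(
    rtracklayer::import(annotation, format = "gtf"),
    error = function(e) stop(sprintf("malformed GTF '%s': %s", annotation,
                                     conditionMessage(e)), call. = FALSE))
  types <- as.character(gr$type)
  ignored <- setdiff(unique(types), c("exon", "gene", "transcript", "mRNA", "CDS"))
  if (length(ignored) > 0)
    message("ignoring annotation feature types: ", paste(ignored, collapse = ", "))
  ex <- gr[types == "exon"]
  if (length(ex) == 0) stop("annotation contains no exon records", call. = FALSE)
  exons <- tibble::tibble(
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex))
  symbols <- NULL
  if (!is.null(ex$gene_name))
    symbols <- setNames(as.character(ex$gene_name), exons$gene_id)
  new_reference(genome, exons, symbols)
}

#' Construct an annotated reference from in-memory pieces
#'
#' Backbone behind [load_reference()]; exposed so that programmatically
#' built toy references (and tests) need not round-trip through files.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param exons Tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @param symbols Optional named character vector mapping `gene_id` to a
#'   display symbol; defaults to the `gene_id` itself.
#' @return A `fusion_reference` object.
#' @export
new_reference <- function(genome, exons, symbols = NULL) {
  genome <- toupper(genome)
  check_dna_alphabet(genome, "genome")
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
                %in% names(exons)))
  exons <- tibble::as_tibble(exons)
  if (!all(exons$strand %in% c("+", "-")))
    stop("exon strand must be '+' or '-'", call. = FALSE)

  bad_chrom <- !exons$chrom %in% names(genome)
  if (any(bad_chrom))
    stop(sprintf("exon of gene '%s' on unknown chromosome '%s'",
                 exons$gene_id[bad_chrom][1], exons$chrom[bad_chrom][1]),
         call. = FALSE)
  chrom_len <- nchar(genome)[exons$chrom]
  oob <- exons$start < 1 | exons$end > chrom_len | exons$start > exons$end
  if (any(oob))
    stop(sprintf(
      "exon [%d, %d] of gene '%s' outside chromosome '%s' bounds (1..%d)",
      exons$start[oob][1], exons$end[oob][1], exons$gene_id[oob][1],
      exons$chrom[oob][1], chrom_len[oob][1]), call. = FALSE)

  # one chrom/strand per gene; exons sorted and non-overlapping per transcript
  per_gene <- dplyr::distinct(exons, .data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(per_gene$gene_id))
    stop("gene with exons on multiple chromosomes or strands", call. = FALSE)
  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id, .data$start)
  ovl <- exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(bad = any(.data$start[-1] <= .data$end[-length(.data$end)]),
                     .groups = "drop")
  if (any(ovl$bad))
    stop(sprintf("overlapping exons within transcript '%s'",
                 ovl$transcript_id[ovl$bad][1]), call. = FALSE)

  genes <- per_gene |>
    dplyr::mutate(symbol = if (is.null(symbols)) .data$gene_id
                  else unname(symbols[.data$gene_id])) |>
    dplyr::select("gene_id", "symbol", "chrom", "strand") |>
    dplyr::arrange(.data$gene_id)

  ref <- structure(list(genome = genome, genes = genes, exons = exons,
                        nrt = NULL),
                   class = "fusion_reference")
  ref$nrt <- setNames(
    lapply(genes$gene_id, function(g) {
      build_nonredundant_transcript(gene_model(ref, g), genome)
    }),
    genes$gene_id)
  ref
}

#' Extract one gene model from a reference
#'
#' @param ref A `fusion_reference`.
#' @param gene_id Gene identifier.
#' @return A list with `gene_id`, `symbol`, `chrom`, `strand` and an
#'   `exons` tibble (one row per exon record, grouped by transcript).
#' @export
gene_model <- function(ref, gene_id) {
  row <- ref$genes[ref$genes$gene_id == gene_id, ]
  if (nrow(row) == 0) stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  list(gene_id = gene_id, symbol = row$symbol, chrom = row$chrom,
       strand = row$strand,
       exons = ref$exons[ref$exons$gene_id == gene_id, ])
}

#' Build the non-redundant transcript of a gene
#'
#' The non-redundant transcript is the interval union of all exon intervals
#' across all transcripts of the gene: overlapping exons are merged into
#' maximal blocks, introns are never included, and the block sequences are
#' concatenated (then reverse-complemented as a whole for minus-strand
#' genes) so transcript coordinate 1 is the gene's 5' end.
#'
#' @param gene A gene model as returned by [gene_model()] (fields
#'   `gene_id`, `chrom`, `strand`, `exons`).
#' @param genome Named character vector of chromosome sequences.
#' @return A `nonredundant_transcript`: list with `gene_id`, `chrom`,
#'   `strand`, `sequence` (gene-strand orientation) and `blocks`, a tibble
#'   in transcript order with genomic (`gstart`, `gend`) and transcript
#'   (`tstart`, `tend`) interval columns.
#' @export
build_nonredundant_transcript <- function(gene, genome) {
  stopifnot(nrow(gene$exons) >= 1)
  merged <- IRanges::reduce(IRanges::IRanges(gene$exons$start, gene$exons$end))
  gstart <- IRanges::start(merged)
  gend <- IRanges::end(merged)
  chrom_seq <- genome[[gene$chrom]]
  block_seqs <- substring(chrom_seq, gstart, gend)
  seq_plus <- paste(block_seqs, collapse = "")
  widths <- gend - gstart + 1

  if (gene$strand == "+") {
    ord <- order(gstart)
    sequence <- seq_plus
  } else {
    ord <- order(gstart, decreasing = TRUE)
    sequence <- dna_revcomp(seq_plus)
  }
  gstart <- gstart[ord]; gend <- gend[ord]; widths <- widths[ord]
  tend <- cumsum(widths)
  tstart <- tend - widths + 1

  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, sequence = sequence,
                 blocks = tibble::tibble(gstart = gstart, gend = gend,
                                         tstart = tstart, tend = tend)),
            class = "nonredundant_transcript")
}

#' Map transcript coordinates to genomic coordinates
#'
#' Inverse of the non-redundant transcript's block map. For minus-strand
#' genes transcript position 1 maps to the highest genomic coordinate of
#' the blocks.
#'
#' @param nrt A `nonredundant_transcript`.
#' @param pos Integer vector of transcript coordinates (1-based).
#' @return Integer vector of genomic coordinates.
#' @export
map_transcript_coord <- function(nrt, pos) {
  len <- nchar(nrt$sequence)
  if (any(pos < 1 | pos > len))
    stop(sprintf("transcript coordinate out of range 1..%d", len), call. = FALSE)
  b <- findInterval(pos, nrt$blocks$tstart)
  off <- pos - nrt$blocks$tstart[b]
  if (nrt$strand == "+") nrt$blocks$gstart[b] + off
  else nrt$blocks$gend[b] - off
}

#' Map genomic coordinates to transcript coordinates
#'
#' @param nrt A `nonredundant_transcript`.
#' @param gpos Integer vector of genomic coordinates; every position must
#'   fall inside one of the gene's exon-union blocks.
#' @return Integer vector of transcript coordinates.
#' @export
map_genomic_coord <- function(nrt, gpos) {
  blk <- nrt$blocks[order(nrt$blocks$gstart), ]
  b <- findInterval(gpos, blk$gstart)
  bad <- b == 0 | gpos > blk$gend[pmax(b, 1)]
  if (any(bad))
    stop(sprintf("genomic position %d not covered by gene '%s'",
                 gpos[bad][1], nrt$gene_id), call. = FALSE)
  if (nrt$strand == "+") blk$tstart[b] + (gpos - blk$gstart[b])
  else blk$tstart[b] + (blk$gend[b] - gpos)
}

#' @export
print.fusion_reference <- function(x, ...) {
  cat(sprintf("<fusion_reference> %d chromosome(s), %d gene(s), %d exon record(s)\n",
              length(x$genome), nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' @export
print.nonredundant_transcript <- function(x, ...) {
  cat(sprintf("<nonredundant_transcript> %s (%s%s): %d nt in %d block(s)\n",
              x$gene_id, x$chrom, x$strand, nchar(x$sequence), nrow(x$blocks)))
  invisible(x)
}
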