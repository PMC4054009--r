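#' Enumerate one-nucleotide tiles over a fused region
#'
#' Every transcript coordinate in the span-derived fused region becomes a
#' candidate junction site, labelled credible or potential from
#' [classify_subregions()].
#'
#' @param subregions Classified sub-region tibble (`start`, `end`,
#'   `class`), one gene.
#' @return Tibble with `pos` (one row per base) and `class`.
#' @export
enumerate_tiles <- function(subregions) {
  if (nrow(subregions) == 0)
    return(tibble::tibble(pos = integer(), class = character()))
  out <- dplyr::reframe(subregions, pos = seq(.data$start, .data$end),
                        class = .data$class,
                        .by = c("start", "end")) |>
    dplyr::select("pos", "class") |>
    dplyr::arrange(.data$pos)
  out
}

#' Materialize one candidate junction sequence
#'
#' The candidate fused transcript around a putative junction: the last `W`
#' bases of the upstream gene up to and including site `U`, concatenated
#' with `W` bases of the downstream gene starting at site `D`. Flanks are
#' clipped at transcript ends; a flank shorter than `min_flank` drops the
#' candidate (returns `NULL`).
#'
#' @param up_seq,down_seq Non-redundant transcript sequences.
#' @param U,D Junction sites: `U` is the last upstream base, `D` the first
#'   downstream base (transcript coordinates).
#' @param W Flank length in nt (defaults to the read length at call sites).
#' @param min_flank Minimum clipped flank length (default 30).
#' @return List with `sequence`, `offset` (length of the upstream flank:
#'   the junction lies between `offset` and `offset + 1`), `U`, `D`; or
#'   `NULL` when a flank is too short.
#' @export
junction_sequence <- function(up_seq, down_seq, U, D, W, min_flank = 30) {
  u_start <- max(1, U - W + 1)
  d_end <- min(nchar(down_seq), D + W - 1)
  up_flank <- substr(up_seq, u_start, U)
  down_flank <- substr(down_seq, D, d_end)
  if (nchar(up_flank) < min_flank || nchar(down_flank) < min_flank)
    return(NULL)
  list(sequence = paste0(up_flank, down_flank),
       offset = nchar(up_flank), U = U, D = D)
}

#' Build the partial-exhaustion junction sequence library for one gene pair
#'
#' All pairwise connections between upstream tiles `U_i` and downstream
#' tiles `D_j` are enumerated, except pairs whose two sites are both in
#' potential regions: at least one site must be credible. The kept pairs
#' are materialized as junction sequences; identical sequences arising from
#' different `(U, D)` connections collapse to one library entry that
#' retains all source coordinates.
#'
#' @param up_seq,down_seq Non-redundant transcript sequences of the
#'   upstream and downstream genes.
#' @param up_sites,down_sites Tile tibbles (`pos`, `class`) from
#'   [enumerate_tiles()].
#' @param W Flank length in nt.
#' @param min_flank Minimum clipped flank length.
#' @return Tibble with one row per distinct junction sequence: `U`, `D`,
#'   `class_U`, `class_D`, `sequence`, `offset`, and `src_U`/`src_D` (list
#'   columns holding all contributing `(U, D)` connections).
#' @export
build_junction_library <- function(up_seq, down_seq, up_sites, down_sites,
                                   W, min_flank = 30) {
  empty <- tibble::tibble(U = integer(), D = integer(),
                          class_U = character(), class_D = character(),
                          sequence = character(), offset = integer(),
                          src_U = list(), src_D = list())
  if (nrow(up_sites) == 0 || nrow(down_sites) == 0) return(empty)
  grid <- tidyr::expand_grid(
    ui = seq_len(nrow(up_sites)), dj = seq_len(nrow(down_sites))) |>
    dplyr::mutate(U = up_sites$pos[.data$ui], D = down_sites$pos[.data$dj],
                  class_U = up_sites$class[.data$ui],
                  class_D = down_sites$class[.data$dj]) |>
    dplyr::filter(!(.data$class_U == "potential" &
                      .data$class_D == "potential"))
  if (nrow(grid) == 0) return(empty)

  u_start <- pmax(1L, grid$U - W + 1L)
  d_end <- pmin(nchar(down_seq), grid$D + W - 1L)
  up_flank <- substr(rep(up_seq, nrow(grid)), u_start, grid$U)
  down_flank <- substr(rep(down_seq, nrow(grid)), grid$D, d_end)
  ok <- nchar(up_flank) >= min_flank & nchar(down_flank) >= min_flank
  grid <- grid[ok, ]
  if (nrow(grid) == 0) return(empty)
  grid$sequence <- paste0(up_flank[ok], down_flank[ok])
  grid$offset <- nchar(up_flank[ok])

  grid <- dplyr::arrange(grid, .data$U, .data$D)
  f <- factor(grid$sequence, levels = unique(grid$sequence))
  idx <- split(seq_len(nrow(grid)), f)
  first <- vapply(idx, function(i) i[1], integer(1))
  out <- tibble::tibble(
    U = grid$U[first], D = grid$D[first],
    class_U = grid$class_U[first], class_D = grid$class_D[first],
    sequence = grid$sequence[first], offset = grid$offset[first],
    src_U = unname(split(grid$U, f)), src_D = unname(split(grid$D, f)))
  dplyr::arrange(out, .data$U, .data$D)
}

#' Write a junction library as FASTA
#'
#' Headers encode the source coordinates as
#' `geneU:geneD:U:D`.
#'
#' @param library Library tibble from [build_junction_library()].
#' @param up_gene,down_gene Gene ids for the header.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_junction_library <- function(library, up_gene, down_gene, path) {
  seqs <- Biostrings::DNAStringSet(library$sequence)
  names(seqs) <- sprintf("%s:%s:%d:%d", up_gene, down_gene, library$U,
                         library$D)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
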