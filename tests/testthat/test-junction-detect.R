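make_junction_fixture <- function(seed = 101) {
  set.seed(seed)
  up <- random_dna(400)
  down <- random_dna(400)
  U <- 200L; D <- 150L
  lib <- build_junction_library(
    up, down,
    tibble::tibble(pos = c(U - 1L, U, U + 1L), class = "credible"),
    tibble::tibble(pos = D, class = "credible"),
    W = 90, min_flank = 30)
  fused <- paste0(substr(up, 1, U), substr(down, D, 400))
  list(up = up, down = down, U = U, D = D, lib = lib, fused = fused)
}

test_that("junc-reads must cross the junction with both overhangs", {
  fx <- make_junction_fixture()
  center <- substr(fx$fused, fx$U - 44, fx$U + 45)   # 45/45 around junction
  ending <- substr(fx$fused, fx$U - 89, fx$U)        # ends at the junction
  short_ov <- substr(fx$fused, fx$U - 84, fx$U + 5)  # 5-base right overhang
  res <- detect_junc_reads(c(a = center, b = ending, c = short_ov), fx$lib,
                           min_overhang = 8)
  hit <- res[res$read_id == "a", ]
  true_row <- which(fx$lib$U == fx$U & fx$lib$D == fx$D)
  expect_true(true_row %in% hit$lib_idx)
  expect_equal(hit$overhang_left[hit$lib_idx == true_row], 45L)
  expect_equal(hit$overhang_right[hit$lib_idx == true_row], 45L)
  expect_false("b" %in% res$read_id)
  expect_false("c" %in% res$read_id)

  # reverse-complement junc-reads are found on the minus strand
  res_rc <- detect_junc_reads(c(a = dna_revcomp(center)), fx$lib)
  expect_equal(res_rc$strand[res_rc$lib_idx == true_row], "-")

  # identical placements deduplicate
  res_dup <- detect_junc_reads(c(a = center, a2 = center), fx$lib)
  expect_equal(sum(res_dup$lib_idx == true_row), 1)
})

test_that("fusion calls need both span and junction support", {
  fx <- make_junction_fixture()
  genome <- c(chr1 = paste0(fx$up, fx$down, random_dna(30200)))
  exons <- tibble::tibble(
    gene_id = c("gU", "gD"), transcript_id = c("gU.t1", "gD.t1"),
    chrom = "chr1", strand = "+", start = c(1L, 30401L),
    end = c(400L, 30800L))
  ref <- new_reference(genome, exons)
  ref$nrt$gU$sequence <- fx$up
  ref$nrt$gD$sequence <- fx$down

  reads <- setNames(
    vapply(c(-30, -10, 10, 25), function(o)
      substr(fx$fused, fx$U - 44 + o, fx$U + 45 + o), character(1)),
    paste0("j", 1:4))
  junc <- detect_junc_reads(reads, fx$lib)
  call <- call_fusions(list(up_gene = "gU", down_gene = "gD",
                            span_count = 2L),
                       fx$lib, junc, ref, min_span = 2, min_junc = 2)
  expect_equal(nrow(call), 1)
  expect_equal(call$U, fx$U)
  expect_equal(call$D, fx$D)
  expect_equal(call$junc_count, 4L)
  expect_equal(call$pos_5, 200)
  expect_equal(call$pos_3, 30401 + 150 - 1)

  # junction support below threshold, or no junc evidence: no call
  expect_equal(nrow(call_fusions(list(up_gene = "gU", down_gene = "gD",
                                      span_count = 5L),
                                 fx$lib, junc[0, ], ref)), 0)
  expect_equal(nrow(call_fusions(list(up_gene = "gU", down_gene = "gD",
                                      span_count = 1L),
                                 fx$lib, junc, ref, min_span = 2)), 0)

  # the junction site with maximal junc support wins
  shifted <- setNames(
    vapply(c(-20, 0), function(o)
      substr(fx$fused, fx$U - 44 + o, fx$U + 45 + o), character(1)),
    c("k1", "k2"))
  junc_all <- detect_junc_reads(c(reads, shifted), fx$lib)
  support <- dplyr::count(junc_all, lib_idx)
  best_row <- support$lib_idx[which.max(support$n)]
  call2 <- call_fusions(list(up_gene = "gU", down_gene = "gD",
                             span_count = 2L), fx$lib, junc_all, ref)
  expect_equal(call2$junc_count, max(support$n))
  expect_equal(call2$U, fx$lib$U[best_row])
})

test_that("final filters drop read-through-like and homologous junctions", {
  set.seed(111)
  genome <- c(chr1 = random_dna(40000))
  # gP and gQ are adjacent (3 kb apart); gR and gS are far apart; gT's
  # continuation past the junction is nearly identical to gV's flank
  exons <- tibble::tibble(
    gene_id = c("gP", "gQ", "gR", "gS", "gT", "gV"),
    transcript_id = paste0(c("gP", "gQ", "gR", "gS", "gT", "gV"), ".t1"),
    chrom = "chr1", strand = "+",
    start = c(1001L, 5001L, 9001L, 29001L, 15001L, 33001L),
    end = c(2000L, 6000L, 10000L, 30000L, 16000L, 34000L))
  ref <- new_reference(genome, exons)
  template <- function(gene, U, D, down_gene) {
    tibble::tibble(
      sample_id = "s", up_gene = gene, down_gene = down_gene,
      up_symbol = gene, down_symbol = down_gene,
      chrom_5 = "chr1", chrom_3 = "chr1",
      U = U, D = D,
      pos_5 = map_transcript_coord(ref$nrt[[gene]], U),
      pos_3 = map_transcript_coord(ref$nrt[[down_gene]], D),
      span_count = 5L, junc_count = 5L,
      junction_seq = "ACGT", junction_offset = 2L)
  }
  calls <- dplyr::bind_rows(
    template("gP", 500L, 400L, "gQ"),     # adjacent, mid-exon junction
    template("gR", 500L, 400L, "gS"))     # distant, dissimilar flanks
  kept <- final_filter_fusions(calls, ref)
  expect_equal(kept$up_gene, "gR")
  expect_equal(attr(kept, "filter_log")$reason, "proximity")

  # homologous junction flanks: copy gT's post-junction sequence into gV
  g <- genome
  seg <- substr(g[["chr1"]], 15501, 15560)                 # gT tpos 501-560
  seg_mut <- seg
  substr(seg_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(seg, 10, 10))[1]
  s <- g[["chr1"]]
  substr(s, 33401, 33460) <- seg_mut                       # gV tpos 401-460
  g[["chr1"]] <- s
  ref2 <- new_reference(g, exons)
  call_h <- template("gT", 500L, 401L, "gV")
  call_h$pos_3 <- map_transcript_coord(ref2$nrt[["gV"]], 401L)
  kept2 <- final_filter_fusions(call_h, ref2)
  expect_equal(nrow(kept2), 0)
  expect_equal(attr(kept2, "filter_log")$reason, "junction_homology")
})
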