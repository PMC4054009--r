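test_that("the sixteen span-read combinations contain four rational ones", {
  tab <- enumerate_span_combinations()
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$rational), 4)
  # rational rows split two orientation classes, 2 and 2
  expect_equal(as.vector(table(tab$upstream[tab$rational])), c(2L, 2L))
  # all rational rows have opposite strands and a plus-oriented read 'a'
  rat <- tab[tab$rational, ]
  expect_true(all(rat$strand_A != rat$strand_B))
})

test_that("orientation of a span read agrees with the combination table", {
  # read 'a' (end 1) plus on gene A: A is upstream
  expect_equal(orient_gene_pair(list(gene_a = "A", strand_a = "+",
                                     gene_b = "B", strand_b = "-")),
               list(upstream = "A", downstream = "B"))
  # read 'b' (end 2) plus on gene B: B is upstream
  expect_equal(orient_gene_pair(list(gene_a = "A", strand_a = "-",
                                     gene_b = "B", strand_b = "+")),
               list(upstream = "B", downstream = "A"))
  # both plus: irrational, discarded
  expect_null(orient_gene_pair(list(gene_a = "A", strand_a = "+",
                                    gene_b = "B", strand_b = "+")))
  expect_null(orient_gene_pair(list(gene_a = "A", strand_a = "-",
                                    gene_b = "B", strand_b = "-")))

  # exhaustive agreement with the enumeration on strand combinations
  tab <- enumerate_span_combinations()
  for (i in seq_len(nrow(tab))) {
    o <- orient_gene_pair(list(gene_a = "A", strand_a = tab$strand_A[i],
                               gene_b = "B", strand_b = tab$strand_B[i]))
    if (tab$rational[i]) {
      expect_equal(o$upstream, tab$upstream[i])
    } else if (tab$strand_A[i] == tab$strand_B[i]) {
      expect_null(o)
    }
  }
})

test_that("duplicated placements collapse to one representative", {
  reads <- tibble::tibble(
    pair_id = c("p1", "p2", "p3", "p4", "p5"),
    up_gene = "A", down_gene = "B",
    mp_up = c(100L, 100L, 100L, 101L, 100L),
    mp_down = c(50L, 50L, 50L, 50L, 51L))
  d1 <- dedup_reads(reads)
  expect_equal(nrow(d1), 3)               # three identical -> one retained
  expect_equal(dedup_reads(d1), d1)       # idempotent
})

test_that("span reads pair ends hitting two different genes", {
  ev <- tibble::tibble(
    pair_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p3"),
    end = c(1L, 2L, 1L, 2L, 1L, 2L, 2L),
    gene_id = c("A", "B", "A", "A", "A", "B", "C"),
    tpos = c(10L, 20L, 10L, 90L, 30L, 40L, 50L),
    strand = c("+", "-", "+", "-", "+", "-", "-"),
    mismatches = 0L,
    n_hits = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    read_len = 90L,
    trim_cycles = c(0L, 0L, 0L, 0L, 0L, 1L, 1L))
  sp <- find_span_reads(ev)
  # p1: span A->B; p2: both ends one gene; p3: trimmed multi-hit end gives
  # two candidate span reads flagged multi
  expect_equal(sp$up_gene[sp$pair_id == "p1"], "A")
  expect_equal(sp$mp_up[sp$pair_id == "p1"], 10L)
  expect_false("p2" %in% sp$pair_id)
  expect_equal(nrow(sp[sp$pair_id == "p3", ]), 2)
  expect_true(all(sp$multi[sp$pair_id == "p3"]))

  # untrimmed multi-hit evidence is not used
  ev2 <- ev
  ev2$trim_cycles <- 0L
  sp2 <- find_span_reads(ev2)
  expect_false("p3" %in% sp2$pair_id)

  # irrational strand combinations are discarded
  ev3 <- tibble::tibble(pair_id = "p9", end = c(1L, 2L),
                        gene_id = c("A", "B"), tpos = c(1L, 2L),
                        strand = c("+", "+"), mismatches = 0L, n_hits = 1L,
                        read_len = 90L, trim_cycles = 0L)
  expect_equal(nrow(find_span_reads(ev3)), 0)
})

test_that("genome hits are attributed only when inside one exon block", {
  ref <- tiny_reference()
  hits <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    target = "chrA",
    pos = c(110L, 290L, 1500L),   # inside gA exon1 / straddling / intergenic
    strand = "+", mismatches = 0L, n_hits = 1L, truncated = FALSE,
    read_len = 90L)
  att <- attribute_genome_hits(hits, ref)
  expect_equal(att$read_id, "r1")
  expect_equal(att$gene_id, "gA")
  expect_equal(att$tpos, 10L)      # 110 - 101 + 1
  expect_equal(att$strand, "+")

  # a minus-strand gene flips the hit orientation and coordinates
  hits_b <- tibble::tibble(read_id = "r4", target = "chrA", pos = 3051L,
                           strand = "+", mismatches = 0L, n_hits = 1L,
                           truncated = FALSE, read_len = 90L)
  att_b <- attribute_genome_hits(hits_b, ref)
  expect_equal(att_b$gene_id, "gB")
  expect_equal(att_b$strand, "-")  # plus-genome hit on a minus gene
  # leftmost transcript coordinate corresponds to the hit's rightmost base
  nrtB <- ref$nrt[["gB"]]
  expect_equal(att_b$tpos, map_genomic_coord(nrtB, 3051 + 89))
})

test_that("candidate-pair filters remove families, shared exons, homology", {
  set.seed(61)
  genome <- c(chr1 = random_dna(20000))
  # HOXA1/HOXA2: same family; gC/gD share two exons; gE/gF distant clean;
  # gG/gH carry an identical (homologous) 300-nt block
  hom <- random_dna(300)
  base <- function(start, n_ex = 3, len = 200, gap = 100) {
    s <- start + (seq_len(n_ex) - 1) * (len + gap)
    tibble::tibble(start = s, end = s + len - 1)
  }
  ex <- dplyr::bind_rows(
    dplyr::mutate(base(101), gene_id = "g1", symbol = "HOXA1"),
    dplyr::mutate(base(2101), gene_id = "g2", symbol = "HOXA2"),
    dplyr::mutate(base(4101), gene_id = "g3", symbol = "AL"),
    dplyr::mutate(base(4401), gene_id = "g4", symbol = "BE"),  # overlaps g3
    dplyr::mutate(base(8101), gene_id = "g5", symbol = "CE"),
    dplyr::mutate(base(11101), gene_id = "g6", symbol = "DE"),
    dplyr::mutate(base(14101), gene_id = "g7", symbol = "EF"),
    dplyr::mutate(base(17101), gene_id = "g8", symbol = "FG"))
  ex$transcript_id <- paste0(ex$gene_id, ".t1")
  ex$chrom <- "chr1"; ex$strand <- "+"
  # plant the homologous block inside g7 exon2 and g8 exon2
  s <- genome[["chr1"]]
  substr(s, 14401, 14700) <- hom
  substr(s, 17401, 17700) <- hom
  genome[["chr1"]] <- s
  first <- !duplicated(ex$gene_id)
  ref <- new_reference(genome, ex,
                       symbols = setNames(ex$symbol[first],
                                          ex$gene_id[first]))

  span <- tibble::tibble(
    pair_id = paste0("p", 1:4),
    up_gene = c("g1", "g3", "g5", "g7"),
    down_gene = c("g2", "g4", "g6", "g8"),
    mp_up = c(100L, 350L, 100L, 255L),
    mp_down = c(100L, 50L, 100L, 255L),
    rl_up = 90L, rl_down = 90L, multi = FALSE)
  filt <- filter_gene_pairs(span, ref)
  expect_false(any(filt$pairs$up_gene == "g1"))     # family
  expect_false(any(filt$pairs$up_gene == "g3"))     # shared exons
  expect_true(any(filt$pairs$up_gene == "g5"))      # clean pair retained
  expect_false(any(filt$pairs$up_gene == "g7"))     # homologous windows
  expect_setequal(filt$log$reason[filt$log$up_gene == "g1"], "same_family")

  # a pair keeps support if at least one span read escapes the masks
  span2 <- dplyr::bind_rows(
    span[span$up_gene == "g3", ],
    tibble::tibble(pair_id = "p5", up_gene = "g3", down_gene = "g4",
                   mp_up = 10L, mp_down = 550L, rl_up = 90L, rl_down = 90L,
                   multi = FALSE))
  filt2 <- filter_gene_pairs(span2, ref)
  expect_true(any(filt2$pairs$up_gene == "g3"))
  expect_equal(filt2$pairs$span_count[filt2$pairs$up_gene == "g3"], 1L)
})
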