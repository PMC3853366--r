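test_that("upstream windows and mismatch counts follow the motif rule", {
  #            0123456789...
  g <- c(chr1 = paste0("AAAA", "TATAGGG", "CATGCATGCATGCATGCATG"))
  # + tag at five_prime 11: upstream window = positions 4..10 = TATAGGG
  aln <- alignment_table("r1", "chr1", 11L, 25L, "+")
  call <- flag_strand_invasion(aln, g)
  expect_equal(call$upstream_window, "TATAGGG")
  expect_equal(call$mismatches, 0L)
  expect_true(call$si_flagged)

  # exactly at the two-mismatch threshold: still flagged
  g2 <- c(chr1 = paste0("AAAA", "TATAGTT", "CATGCATGCATGCATGCATG"))
  call <- flag_strand_invasion(alignment_table("r1", "chr1", 11L, 25L, "+"),
                               g2)
  expect_equal(call$mismatches, 2L)
  expect_true(call$si_flagged)

  # three mismatches: kept
  g3 <- c(chr1 = paste0("AAAA", "CCCAGGG", "CATGCATGCATGCATGCATG"))
  call <- flag_strand_invasion(alignment_table("r1", "chr1", 11L, 25L, "+"),
                               g3)
  expect_equal(call$mismatches, 3L)
  expect_false(call$si_flagged)

  # minus-strand tag: window is the reverse complement downstream
  gm <- c(chr1 = paste0(strrep("C", 12), revcomp_chr("TATAGGG"), "AAAA"))
  # five_prime at 11, window = revcomp(genome[12..18]) = TATAGGG
  aln <- alignment_table("r2", "chr1", 0L, 12L, "-")
  call <- flag_strand_invasion(aln, gm)
  expect_equal(call$upstream_window, "TATAGGG")
  expect_true(call$si_flagged)
})

test_that("contig edges are never flagged and are counted", {
  g <- c(chr1 = strrep("ACGT", 20))
  aln <- alignment_table(c("r1", "r2"), "chr1", c(3L, 40L), c(34L, 71L),
                         c("+", "+"))
  call <- flag_strand_invasion(aln, g)
  expect_true(is.na(call$mismatches[1]))
  expect_false(call$si_flagged[1])
  expect_equal(attr(call, "edge"), 1L)
})

test_that("flagged set grows monotonically with the threshold", {
  set.seed(81)
  g <- c(chr1 = random_dna(50000))
  pos <- sample(20:49950, 2000)
  str <- sample(c("+", "-"), 2000, replace = TRUE)
  aln <- alignment_table(paste0("r", 1:2000), "chr1",
                         ifelse(str == "+", pos, pos - 30L),
                         ifelse(str == "+", pos + 31L, pos + 1L), str)
  prev <- rep(FALSE, 2000)
  for (k in 0:4) {
    cur <- flag_strand_invasion(aln, g, max_mismatch = k)$si_flagged
    expect_true(all(cur[prev]), info = paste("k =", k))
    prev <- cur
  }
})

test_that("filtering is strand-symmetric", {
  set.seed(82)
  L <- 20000L
  g <- c(chr1 = random_dna(L))
  pos <- sample(50:(L - 50), 800)
  str <- sample(c("+", "-"), 800, replace = TRUE)
  aln <- alignment_table(paste0("r", 1:800), "chr1",
                         ifelse(str == "+", pos, pos - 30L),
                         ifelse(str == "+", pos + 31L, pos + 1L), str)
  f1 <- flag_strand_invasion(aln, g)$si_flagged

  # reverse-complement the genome, flip strands and mirror coordinates
  grc <- c(chr1 = revcomp_chr(g[[1]]))
  pos2 <- L - 1L - pos
  str2 <- ifelse(str == "+", "-", "+")
  aln2 <- alignment_table(paste0("r", 1:800), "chr1",
                          ifelse(str2 == "+", pos2, pos2 - 30L),
                          ifelse(str2 == "+", pos2 + 31L, pos2 + 1L), str2)
  f2 <- flag_strand_invasion(aln2, grc)$si_flagged
  expect_equal(f1, f2)
})

test_that("planted invasion sites are all recovered, edges aside", {
  ref <- tiny_reference(seed = 83, n_sites = 60)
  lib <- simulate_library(ref, "D3_1", n_reads = 600, seed = 84,
                          error_rate = 0,
                          class_rates = c(tss = 0, internal = 0,
                                          invasion = 1, rrna = 0,
                                          artifact = 0))
  aln <- alignments_from_truth(lib$truth, ref)
  call <- flag_strand_invasion(aln, ref$genome)
  expect_equal(mean(call$si_flagged), 1.0)
})

test_that("invasion_rate reports per-sample binomial summaries", {
  calls <- alignment_table(paste0("r", 1:1000), "chr1",
                           seq(100L, by = 40L, length.out = 1000),
                           seq(131L, by = 40L, length.out = 1000), "+",
                           sample_id = "S1")
  calls$si_flagged <- c(rep(TRUE, 91), rep(FALSE, 909))
  r <- invasion_rate(calls)
  expect_equal(r$rate, 0.091)
  expect_equal(r$flagged, 91L)
  expect_equal(r$se, sqrt(0.091 * 0.909 / 1000))
  expect_error(invasion_rate(calls[0, ]), "no invasion calls")
})

test_that("cluster-level removal drops only all-flagged clusters", {
  # two clusters: one fully flagged, one mixed
  g <- c(chr1 = paste0("AAAA", "TATAGGG", strrep("CATG", 30)))
  aln <- alignment_table(c("a1", "a2", "b1"), "chr1",
                         c(11L, 11L, 60L), c(42L, 42L, 91L), "+")
  call <- flag_strand_invasion(aln, g)
  sp <- split_strand_invasion(call)
  expect_equal(sort(sp$kept$read_id), "b1")
  expect_equal(sort(sp$flagged$read_id), c("a1", "a2"))
  expect_equal(sp$stats$flagged, 2L)
})
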