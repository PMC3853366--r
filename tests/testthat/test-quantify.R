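test_that("gene_counts pools same-strand clusters per gene", {
  cl <- data.frame(
    cluster_id = c("TC1", "TC2", "TC3", "TC4"),
    chrom = "chr1", start = 1L, end = 2L, strand = "+", peak_pos = 1L,
    count = c(10L, 5L, 7L, 3L),
    count.S1 = c(10L, 5L, 7L, 3L),
    basket = c("promoter", "exon", "other", "intron"),
    gene_id = c("geneA", "geneA", NA, "geneB"),
    stringsAsFactors = FALSE)
  m <- gene_counts(cl)
  expect_equal(m["geneA", "S1"], 15L)
  expect_equal(m["geneB", "S1"], 3L)
  expect_equal(nrow(m), 2L)  # the "other" cluster contributes nowhere
})

test_that("pairwise correlations are symmetric, unit-diagonal, scale-free", {
  set.seed(111)
  mu <- rexp(200, 1 / 50)
  a <- rpois(200, mu)
  mat <- cbind(A = a, B = a * 2L, C = rpois(200, mu))
  r <- pairwise_pearson(mat)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))
  # TPM normalisation makes a scaled copy correlate perfectly
  expect_equal(r["A", "B"], 1)
  expect_true(r["A", "C"] < 1 && r["A", "C"] > 0.5)
  rl <- pairwise_pearson(mat, log_scale = TRUE)
  expect_equal(rl["A", "B"], 1)

  expect_warning(pairwise_pearson(cbind(A = c(1L, 1L), B = c(1L, 2L))),
                 "zero-variance")
})

test_that("correlation of NB replicates matches a Monte-Carlo oracle", {
  # two libraries drawn from one gene-mean vector with gamma-Poisson noise
  set.seed(112)
  n_genes <- 300L
  mu <- 50 * (1:n_genes)^-1
  mu <- mu / sum(mu) * 3e4
  size <- 1 / 0.2  # dispersion 0.2
  draw_r <- function() {
    x <- rnbinom(n_genes, mu = mu, size = size)
    y <- rnbinom(n_genes, mu = mu, size = size)
    suppressWarnings(pairwise_pearson(cbind(a = x, b = y))["a", "b"])
  }
  reps <- vapply(1:200, function(i) draw_r(), numeric(1))
  oracle_mean <- mean(reps)
  oracle_se <- sd(reps)
  set.seed(998)
  x <- rnbinom(n_genes, mu = mu, size = size)
  y <- rnbinom(n_genes, mu = mu, size = size)
  r <- pairwise_pearson(cbind(a = x, b = y))["a", "b"]
  expect_lt(abs(r - oracle_mean), 3 * oracle_se)
})

test_that("rarefy draws exactly n tags without replacement", {
  set.seed(113)
  counts <- setNames(rpois(100, 40) + 1L, paste0("g", 1:100))
  sub <- rarefy(counts, 1000L, seed = 5)
  expect_equal(sum(sub), 1000L)
  expect_true(all(sub <= counts))
  expect_equal(names(sub), names(counts))
  # identity at full depth, zero vector at depth 0
  expect_equal(rarefy(counts, sum(counts), seed = 5), counts)
  expect_equal(sum(rarefy(counts, 0L)), 0L)
  expect_error(rarefy(counts, sum(counts) + 1L), "short by 1")
  # reproducible under seed
  expect_equal(rarefy(counts, 500L, seed = 9), rarefy(counts, 500L, seed = 9))
})

test_that("rarefied share of a gene follows the hypergeometric law", {
  set.seed(114)
  total <- 300000L
  gene_share <- 0.10
  counts <- c(big = as.integer(total * gene_share),
              setNames(rep(as.integer(total * 0.9 / 500), 500),
                       paste0("g", 1:500)))
  n <- 30000L
  draws <- vapply(1:30, function(i) rarefy(counts, n, seed = i)[["big"]],
                  numeric(1))
  p <- gene_share
  se_hyper <- sqrt(n * p * (1 - p) * (sum(counts) - n) / (sum(counts) - 1))
  expect_true(all(abs(draws - n * p) < 3 * se_hyper + 1e-9))
})

test_that("detected loci counts and rarefaction monotonicity", {
  expect_equal(detected_loci(c(0, 0, 0)), 0L)
  expect_equal(detected_loci(c(1, 0, 3, 2)), 3L)
  set.seed(115)
  counts <- setNames(as.integer(rexp(400, 1 / 30)) + 0L, paste0("g", 1:400))
  counts <- counts[counts >= 0]
  shallow <- vapply(1:50, function(i) {
    detected_loci(rarefy(counts, 500L, seed = i))
  }, numeric(1))
  deep <- vapply(1:50, function(i) {
    detected_loci(rarefy(counts, 3000L, seed = 1000 + i))
  }, numeric(1))
  expect_lt(mean(shallow), mean(deep))
})

test_that("common loci and the resampling null behave as designed", {
  expect_equal(common_loci(list(c("a", "b"), c("a", "b"))), 2L)
  expect_equal(common_loci(list(c("a", "b"), c("c"))), 0L)
  expect_equal(common_loci(list(character(0), c("a"))), 0L)

  # scale-free truth: three equal-depth samplings of one pool miss low-count
  # loci, so the null intersection sits below each pool's detected count
  set.seed(116)
  n_genes <- 1000L
  p <- (1:n_genes)^-1
  p <- p / sum(p)
  ref_counts <- setNames(as.integer(rmultinom(1, 60000, p)), paste0("g", 1:n_genes))
  null <- resampling_null(ref_counts, sizes = c(20000L, 20000L), seed = 7)
  expect_lt(null$common, null$reference_detected)
  expect_true(all(null$common < null$detected + 1L))
  # and resampled pools of one library overlap more than pools with
  # chemistry-specific noise at matched depth
  noisy <- lapply(1:2, function(i) {
    q <- p * rlnorm(n_genes, 0, 1)
    names(which(rmultinom(1, 20000, q / sum(q))[, 1] >= 1))
  })
  ref_set <- names(ref_counts)[ref_counts >= 1]
  indep <- common_loci(c(list(ref_set), noisy))
  expect_gt(null$common, indep)
})
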