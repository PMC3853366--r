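test_that("reference simulation is deterministic and well-formed", {
  cfg <- simulation_config(seed = 121, genome_length = 80000,
                           n_genes = 20, n_invasion_sites = 50)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$invasion_sites, r2$invasion_sites)
  expect_equal(nrow(r1$genes), 20L)
  expect_equal(nrow(r1$invasion_sites), 50L)
  expect_equal(nchar(r1$genome[[1]]), 80000L)
  expect_equal(nchar(r1$contaminant[[1]]), 2000L)
  # genes do not overlap
  o <- order(r1$genes$span_start)
  expect_true(all(diff(r1$genes$span_start[o]) > 0))
  expect_true(all(r1$genes$span_end[o][-20] <= r1$genes$span_start[o][-1]))

  # zero genes is allowed
  r0 <- simulate_reference(simulation_config(
    seed = 1, genome_length = 30000, n_genes = 0, n_invasion_sites = 10,
    class_rates = c(tss = 0, internal = 0, invasion = 0.5, rrna = 0.25,
                    artifact = 0.25)))
  expect_equal(length(r0$models), 0L)
  # too many genes for the genome errors with advice
  expect_error(simulate_reference(simulation_config(
    seed = 1, genome_length = 20000, n_genes = 100)), "genome_length")
})

test_that("genome base composition is uniform", {
  ref <- simulate_reference(simulation_config(
    seed = 122, genome_length = 100000, n_genes = 0,
    n_invasion_sites = 0,
    class_rates = c(tss = 0, internal = 0, invasion = 0, rrna = 1,
                    artifact = 0)))
  g <- strsplit(ref$genome[[1]], "")[[1]]
  gc <- mean(g %in% c("G", "C"))
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("library simulation is deterministic and follows class rates", {
  ref <- tiny_reference(seed = 123)
  l1 <- simulate_library(ref, "L1_1", n_reads = 2000, seed = 5)
  l2 <- simulate_library(ref, "L1_1", n_reads = 2000, seed = 5)
  expect_identical(l1, l2)
  fq1 <- tempfile(); fq2 <- tempfile()
  write_library_fastq(l1, fq1); write_library_fastq(l2, fq2)
  expect_identical(readLines(fq1), readLines(fq2))

  rates <- ref$config$class_rates
  obs <- table(factor(l1$truth$true_class, levels = names(rates))) / 2000
  se <- sqrt(rates * (1 - rates) / 2000)
  expect_true(all(abs(obs - rates) <= 3 * se + 1e-12))
})

test_that("degenerate class mixes behave by construction", {
  ref <- tiny_reference(seed = 124)
  # all TSS: every insert starts at an annotated transcript start
  lib <- simulate_library(ref, "R3_1", n_reads = 200, seed = 6,
                          error_rate = 0,
                          class_rates = c(tss = 1, internal = 0,
                                          invasion = 0, rrna = 0,
                                          artifact = 0))
  expect_true(all(lib$truth$pos %in% ref$genes$tss))
  # all invasion, no errors: the filter flags 100%
  lib <- simulate_library(ref, "D3_1", n_reads = 200, seed = 7,
                          error_rate = 0,
                          class_rates = c(tss = 0, internal = 0,
                                          invasion = 1, rrna = 0,
                                          artifact = 0))
  aln <- alignments_from_truth(lib$truth, ref)
  expect_equal(mean(flag_strand_invasion(aln, ref$genome)$si_flagged), 1)
})

test_that("chemistry presets encode the published invasion rates", {
  for (chem in c("R3", "D3", "L1", "L2", "L3")) {
    r <- chemistry_preset(chem)
    expect_equal(sum(r), 1)
  }
  expect_equal(chemistry_preset("R3")[["invasion"]], 0.091)
  expect_equal(chemistry_preset("L3")[["invasion"]], 0.359)
  expect_equal(chemistry_preset("D3")[["invasion"]], 0.736)
  # R3 is TSS-dominated, the others internal-dominated
  expect_gt(chemistry_preset("R3")[["tss"]],
            chemistry_preset("R3")[["internal"]])
  expect_lt(chemistry_preset("D3")[["tss"]],
            chemistry_preset("D3")[["internal"]])
})

test_that("ground truth aligns with read content for genomic classes", {
  ref <- tiny_reference(seed = 125)
  lib <- simulate_library(ref, "L2_1", n_reads = 300, seed = 8,
                          error_rate = 0)
  pp <- nanocager:::.parse_reads_vec(lib$reads$sequence, lib$reads$quality,
                                     lib$reads$read_id,
                                     default_sample_sheet(),
                                     preprocess_config())
  m <- merge(pp, lib$truth, by = "read_id")
  gen <- m[m$true_class %in% c("tss", "internal", "invasion"), ]
  g <- ref$genome[[1]]
  ok <- vapply(seq_len(nrow(gen)), function(i) {
    len <- nchar(gen$insert[i])
    want <- if (gen$strand[i] == "+") {
      substr(g, gen$pos[i] + 1L, gen$pos[i] + len)
    } else {
      revcomp_chr(substr(g, gen$pos[i] - len + 2L, gen$pos[i] + 1L))
    }
    identical(want, gen$insert[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(class_rates = c(tss = 0.5, internal = 0.6)),
               "sum to 1")
  expect_error(simulation_config(class_rates = c(bogus = 1)), "named")
  ref <- tiny_reference(seed = 126)
  expect_error(simulate_library(ref, "nope"), "unknown sample")
})
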