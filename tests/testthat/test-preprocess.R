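test_that("parse_read extracts barcode, UMI and trimmed insert", {
  insert40 <- "AACGTTGCAGGTTACGATCGTACGGATTACCAGTCAATGC"
  read <- paste0("CACTGA", "AACCGGTT", "TATA", "GGG", insert40)
  pr <- parse_read(read)
  expect_equal(pr$status, "assigned")
  expect_equal(pr$sample_id, "R3_1")  # CACTGA is the first R3 barcode
  expect_equal(pr$umi, "AACCGGTT")
  expect_equal(pr$insert, substr(insert40, 1, 31))

  # insert exactly at trim length stays unchanged (L3 barcode TATAGC)
  ins31 <- substr(insert40, 1, 31)
  pr <- parse_read(paste0("TATAGC", "GGGGGGGG", "TATAGGG", ins31))
  expect_equal(pr$sample_id, "L3_3")  # TATAGC is the third L3 barcode
  expect_equal(pr$insert, ins31)

  # unknown barcode -> unassigned, still parsed downstream
  pr <- parse_read(paste0("NNNNNN", "AACCGGTT", "TATAGGG", ins31))
  expect_equal(pr$status, "unassigned")

  # too short for barcode+UMI+linker -> artifact
  pr <- parse_read("CACTGAAACC")
  expect_equal(pr$status, "artifact")
})

test_that("linker stripping removes the full G run", {
  ins <- "ATCGATCGATCGATCGATCGATCGATCGATC"  # starts with A on purpose
  for (extra in 0:3) {
    read <- paste0("GCTCTC", "ACGTACGT", "TATA", strrep("G", 3 + extra), ins)
    pr <- parse_read(read)
    expect_equal(pr$insert, ins, info = paste("extra G:", extra))
  }
  # fewer than 3 G's is not a valid linker
  pr <- parse_read(paste0("GCTCTC", "ACGTACGT", "TATA", "GG", ins))
  expect_equal(pr$status, "artifact")
})

test_that("barcode matching at distance 1 assigns uniquely or not at all", {
  ins <- "ATCGATCGATCGATCGATCGATCGATCGATC"
  mutated <- "CACTGT"  # CACTGA with one substitution
  read <- paste0(mutated, "ACGTACGT", "TATAGGG", ins)
  pr0 <- parse_read(read)
  expect_equal(pr0$status, "unassigned")
  pr1 <- parse_read(read, config = preprocess_config(barcode_max_mismatch = 1))
  expect_equal(pr1$sample_id, "R3_1")
})

test_that("demultiplexing partitions every read", {
  ref <- tiny_reference()
  lib <- simulate_library(ref, "D3_2", n_reads = 300, seed = 21,
                          class_rates = c(tss = 0.4, internal = 0.2,
                                          invasion = 0.1, rrna = 0.15,
                                          artifact = 0.15))
  pp <- nanocager:::.parse_reads_vec(lib$reads$sequence, lib$reads$quality,
                                     lib$reads$read_id,
                                     default_sample_sheet(),
                                     preprocess_config())
  pp <- artifact_filter(pp)
  expect_equal(nrow(pp), 300L)
  expect_true(all(pp$status %in% c("assigned", "unassigned", "artifact")))
  expect_true(all(nchar(pp$insert[pp$status == "assigned"]) <= 31L))
})

test_that("error-free reads round-trip sample and UMI exactly", {
  ref <- tiny_reference()
  lib <- simulate_library(ref, "L2_3", n_reads = 400, seed = 33,
                          error_rate = 0)
  pp <- nanocager:::.parse_reads_vec(lib$reads$sequence, lib$reads$quality,
                                     lib$reads$read_id,
                                     default_sample_sheet(),
                                     preprocess_config())
  merged <- merge(pp, lib$truth, by = "read_id")
  genuine <- merged[merged$true_class != "artifact", ]
  expect_true(all(genuine$status == "assigned"))
  expect_true(all(genuine$sample_id.x == genuine$sample_id.y))
  expect_true(all(genuine$umi.x == genuine$umi.y))
})

test_that("artifact coverage criterion flags concatemers, spares cDNA", {
  lib <- default_artifact_library()
  mk <- function(ins) structure(list(read_id = "r", sample_id = "s",
                                     umi = "ACGTACGT", insert = ins,
                                     insert_qualities = NA_character_,
                                     status = "assigned"),
                                class = "ParsedRead")
  # linker concatemer: fully covered
  out <- artifact_filter(mk(substr(strrep("TATAGGG", 6), 2, 32)))
  expect_equal(out$status, "artifact")
  # random insert: no shared content
  set.seed(5)
  out <- artifact_filter(mk(random_dna(31)))
  expect_equal(out$status, "assigned")
  # roughly half oligo, half random: coverage ~16/31 below 0.8
  half <- paste0(substr(lib[2], 3, 18), random_dna(15))
  out <- artifact_filter(mk(half))
  expect_equal(out$status, "assigned")
  # empty library is a no-op with a warning
  expect_warning(out <- artifact_filter(mk("TATAGGGTATAGGG"), character(0)))
  expect_equal(out$status, "assigned")
})

test_that("FASTQ round trip through preprocess_fastq", {
  ref <- tiny_reference()
  lib <- simulate_library(ref, "R3_2", n_reads = 150, seed = 44,
                          error_rate = 0)
  fq <- tempfile(fileext = ".fastq")
  write_library_fastq(lib, fq)
  res <- preprocess_fastq(fq)
  expect_equal(res$summary$input, 150L)
  expect_equal(res$summary$input,
               sum(unlist(res$summary$assigned)) + res$summary$unassigned +
                 res$summary$artifact)
  expect_gt(res$summary$assigned$R3_2, 0L)

  dir <- tempfile()
  paths <- write_demux_fastq(res$reads, dir)
  expect_true(file.exists(file.path(dir, "R3_2.fastq")))
  back <- Biostrings::readDNAStringSet(file.path(dir, "R3_2.fastq"),
                                       format = "fastq")
  expect_equal(length(back), res$summary$assigned$R3_2)
})
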