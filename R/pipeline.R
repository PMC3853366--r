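#' Run the full nanoCAGE analysis on simulated or provided inputs
#'
#' Orchestrates the fixed stage order — preprocess (barcode/UMI/linker
#' parsing, artifact screen), rRNA screen, alignment, strand-invasion
#' post-filter, CTSS clustering, basket annotation, digital-expression
#' statistics — and returns a per-sample report. With `simulate = TRUE`
#' the inputs come from the synthetic-data generator under the given
#' presets; otherwise supply `fastq`, `genome`, `annotation` and
#' `contaminants` paths.
#'
#' Basket summaries are reported both before and after strand-invasion
#' filtering: the pre-filter summary describes the raw library content
#' (how the chemistries differ), the post-filter one the cleaned signal.
#'
#' @param config List of settings; see Details. Key entries:
#'   `simulate` (logical), `sim_config` (a [simulation_config()]),
#'   `samples` (named list sample_id -> class-rate vector, e.g. from
#'   [chemistry_preset()]), `reads_per_sample`, `seed`;
#'   or `fastq`/`genome`/`annotation`/`contaminants` paths plus `sheet`.
#'   Stage parameters: `trim_length`, `max_errors`, `rrna_k`,
#'   `invasion_motif`, `invasion_max_mm` (set to `NA` to disable the
#'   invasion filter), `cluster_gap`, `promoter_flank`, `rarefy_n`.
#' @return A report list: `parameters`, per-sample `stage_counts`
#'   (non-increasing along extracted / post_artifact / post_rrna / mapped /
#'   post_invasion), `invasion` (rate table), `baskets_prefilter`,
#'   `baskets_postfilter`, `quantify` (detected loci raw/rarefied, common
#'   loci, pairwise correlations), and (simulations only) `truth_summary`.
#' @export
run_pipeline <- function(config = list()) {
  p <- .pipeline_defaults(config)
  report <- list(schema = "nanocager-report-1",
                 parameters = p[setdiff(names(p), c("sim_config"))])

  if (isTRUE(p$simulate)) {
    ref <- simulate_reference(p$sim_config)
    sheet <- p$sim_config$sheet
    libs <- list()
    for (i in seq_along(p$samples)) {
      sid <- names(p$samples)[i]
      libs[[sid]] <- simulate_library(
        ref, sid, n_reads = p$reads_per_sample,
        class_rates = p$samples[[i]], seed = p$seed + i)
    }
    reads <- do.call(rbind, lapply(libs, `[[`, "reads"))
    truth <- do.call(rbind, lapply(libs, `[[`, "truth"))
    rownames(reads) <- rownames(truth) <- NULL
    genome <- ref$genome
    models <- read_gene_models(ref$models,
                               promoter_flank = p$promoter_flank)
    contaminants <- ref$contaminant
    report$truth_summary <- as.list(table(truth$sample_id,
                                          truth$true_class))
    parsed <- .parse_reads_vec(toupper(reads$sequence), reads$quality,
                               reads$read_id, sheet,
                               preprocess_config(trim_length =
                                                   p$trim_length))
    parsed <- artifact_filter(parsed, default_artifact_library(),
                              preprocess_config(trim_length =
                                                  p$trim_length))
  } else {
    for (need in c("fastq", "genome", "annotation", "contaminants")) {
      if (is.null(p[[need]])) stop("config$", need, " is required")
      if (!file.exists(p[[need]])) stop("missing input: ", p[[need]])
    }
    sheet <- p$sheet
    pp <- preprocess_fastq(p$fastq, sheet,
                           preprocess_config(trim_length = p$trim_length))
    parsed <- pp$reads
    genome <- .genome_seqs(p$genome)
    models <- read_gene_models(p$annotation,
                               promoter_flank = p$promoter_flank)
    contaminants <- .contaminant_seqs(p$contaminants)
    truth <- NULL
  }

  assigned <- parsed[parsed$status == "assigned", , drop = FALSE]
  # demultiplexed reads per sample (before the artifact screen; reads whose
  # linker failed to parse were never demultiplexed and count in no sample)
  n_extracted <- table(factor(parsed$sample_id, levels = sheet$sample_id))
  n_assigned <- table(factor(assigned$sample_id, levels = sheet$sample_id))

  # rRNA screen on assigned inserts
  rr <- rrna_flag_many(assigned$insert, contaminants, k = p$rrna_k)
  clean <- assigned[!rr$flagged, , drop = FALSE]
  n_rrna <- table(factor(clean$sample_id, levels = sheet$sample_id))

  # alignment
  inserts <- setNames(clean$insert, clean$read_id)
  al <- align_inserts(inserts, genome, max_errors = p$max_errors,
                      sample_id = clean$sample_id)
  aln <- al$alignments
  n_mapped <- table(factor(aln$sample_id, levels = sheet$sample_id))

  # strand-invasion post-filter
  calls <- flag_strand_invasion(aln, genome, oligo_end = p$invasion_motif,
                                max_mismatch =
                                  if (is.na(p$invasion_max_mm)) -1L
                                  else p$invasion_max_mm)
  inv <- invasion_rate(calls)
  si <- split_strand_invasion(calls)
  kept <- si$kept
  n_kept <- table(factor(kept$sample_id, levels = sheet$sample_id))

  report$stage_counts <- lapply(sheet$sample_id, function(s) {
    list(sample_id = s,
         extracted = as.integer(n_extracted[s]),
         post_artifact = as.integer(n_assigned[s]),
         post_rrna = as.integer(n_rrna[s]),
         mapped = as.integer(n_mapped[s]),
         post_invasion = as.integer(n_kept[s]))
  })
  names(report$stage_counts) <- sheet$sample_id
  report$invasion <- inv

  # clustering + annotation, before and after invasion filtering
  report$baskets_prefilter <- .baskets_of(aln, models, p$cluster_gap)
  report$baskets_postfilter <- .baskets_of(kept, models, p$cluster_gap)

  # quantification on the filtered tags
  ctss <- alignments_to_ctss(kept)
  clusters <- cluster_ctss(ctss, max_gap = p$cluster_gap)
  classified <- classify_clusters(clusters, models)
  gm <- gene_counts(classified)
  q <- list(detected_loci = apply(gm, 2L, detected_loci))
  if (ncol(gm) >= 2L) {
    q$pearson <- pairwise_pearson(gm)
    q$pearson_log <- pairwise_pearson(gm, log_scale = TRUE)
    pools <- lapply(colnames(gm), function(s) rownames(gm)[gm[, s] >= 1])
    q$common_loci <- common_loci(pools)
  }
  totals <- colSums(gm)
  if (all(totals >= p$rarefy_n) && length(totals) > 0L) {
    q$detected_rarefied <- vapply(seq_len(ncol(gm)), function(j) {
      detected_loci(rarefy(gm[, j], p$rarefy_n, seed = p$seed + 1000L + j))
    }, numeric(1))
    names(q$detected_rarefied) <- colnames(gm)
  }
  report$quantify <- q
  report$n_clusters <- nrow(clusters)
  report
}

.baskets_of <- function(aln, models, cluster_gap) {
  ctss <- alignments_to_ctss(aln)
  cl <- cluster_ctss(ctss, max_gap = cluster_gap)
  basket_summary(classify_clusters(cl, models))
}

.pipeline_defaults <- function(config) {
  d <- list(
    simulate = TRUE,
    sim_config = simulation_config(),
    samples = list(R3_1 = chemistry_preset("R3")),
    reads_per_sample = 5000L,
    seed = 1L,
    sheet = default_sample_sheet(),
    trim_length = 31L,
    max_errors = 3L,
    rrna_k = NULL,
    invasion_motif = "TATAGGG",
    invasion_max_mm = 2L,
    cluster_gap = 20L,
    promoter_flank = 100L,
    rarefy_n = 30000L
  )
  d[names(config)] <- config
  d
}

#' Write a pipeline report as JSON
#'
#' @param report List from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
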