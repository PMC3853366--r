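#' Gene-level count matrix from classified clusters
#'
#' Sums tag counts of same-strand clusters assigned to each gene (promoter,
#' exon and intron baskets); clusters without a gene ("other") are excluded.
#'
#' @param classified Output of [classify_clusters()].
#' @return Integer matrix, genes x samples.
#' @export
gene_counts <- function(classified) {
  count_cols <- grep("^count\\.", names(classified), value = TRUE)
  if (length(count_cols) == 0L) count_cols <- "count"
  keep <- !is.na(classified$gene_id)
  sub <- classified[keep, , drop = FALSE]
  genes <- sort(unique(sub$gene_id))
  mat <- matrix(0L, nrow = length(genes), ncol = length(count_cols),
                dimnames = list(genes, sub("^count\\.?", "", count_cols)))
  if (length(count_cols) == 1L && count_cols == "count") {
    colnames(mat) <- "all"
  }
  for (j in seq_along(count_cols)) {
    agg <- tapply(sub[[count_cols[j]]], sub$gene_id, sum)
    mat[names(agg), j] <- as.integer(agg)
  }
  mat
}

#' Pairwise gene-wise Pearson correlations between libraries
#'
#' Correlations are computed on TPM-normalised gene counts (each column
#' scaled to tags per million of its own total), optionally on
#' `log10(TPM + pseudocount)`.
#'
#' @param mat Gene x sample count matrix.
#' @param log_scale Correlate on log10(TPM + pseudocount) when TRUE.
#' @param pseudocount Added before the log (default 1).
#' @return Symmetric sample x sample correlation matrix with unit diagonal;
#'   columns with zero variance give NA (with a warning).
#' @export
pairwise_pearson <- function(mat, log_scale = FALSE, pseudocount = 1) {
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    warning("column(s) with zero total: ",
            paste(colnames(mat)[totals <= 0], collapse = ", "))
    totals[totals <= 0] <- NA_real_
  }
  tpm <- sweep(mat, 2L, totals, "/") * 1e6
  x <- if (log_scale) log10(tpm + pseudocount) else tpm
  vars <- apply(x, 2L, stats::var)
  if (any(!is.na(vars) & vars == 0)) {
    warning("zero-variance column(s): ",
            paste(colnames(mat)[!is.na(vars) & vars == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[!is.na(vars) & vars == 0, ] <- NA_real_
  r[, !is.na(vars) & vars == 0] <- NA_real_
  diag(r)[!is.na(diag(r))] <- 1
  r
}

#' Rarefy a count vector to fixed depth
#'
#' Draws exactly `n` tags without replacement (multivariate hypergeometric)
#' so that libraries of different depth can be compared on detected genes.
#' Delegates the draw to `vegan::rrarefy`.
#'
#' @param counts Named integer vector of per-gene counts.
#' @param n Target depth (default 30000).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of the same length and names, summing to `n`.
#' @export
rarefy <- function(counts, n = 30000L, seed = NULL) {
  n <- as.integer(n)
  total <- sum(counts)
  if (total < n) {
    stop("cannot rarefy to ", n, " tags: only ", total,
         " available (short by ", n - total, ")")
  }
  if (n == 0L) return(setNames(integer(length(counts)), names(counts)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  # rrarefy warns when the smallest nonzero count exceeds 1 (a heuristic
  # for spotting non-count data); gene-level tag counts trip it legitimately
  out <- as.integer(suppressWarnings(
    vegan::rrarefy(matrix(counts, nrow = 1L), n)))
  names(out) <- names(counts)
  out
}

#' Number of detected loci
#'
#' @param counts Count vector (optionally rarefied first).
#' @return Number of genes with at least one tag.
#' @export
detected_loci <- function(counts) {
  sum(counts >= 1)
}

#' Loci common to all pools
#'
#' @param pools List of character vectors of detected gene ids.
#' @return Size of the intersection.
#' @export
common_loci <- function(pools) {
  if (length(pools) == 0L || any(lengths(pools) == 0L)) return(0L)
  length(Reduce(intersect, pools))
}

#' Resampling null for the common-loci count
#'
#' How many loci would be common if the compared pools were random
#' subsamples of one reference library? The reference's tags are subsampled
#' without replacement at the comparison libraries' depths; the detected
#' gene sets of the subsamples are intersected with the reference's own
#' detected set. Because digital expression is scale-free, low-count loci
#' are missed even between samples identical by construction, so this null
#' exceeds chance overlap yet stays below the reference's detected count.
#'
#' @param reference Named count vector of the reference pool.
#' @param sizes Integer vector of subsample depths (one per emulated pool).
#' @param seed Optional integer seed.
#' @return List: `common` (null intersection size), `detected` (detected
#'   loci per subsample), `reference_detected`.
#' @export
resampling_null <- function(reference, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ref_set <- names(reference)[reference >= 1]
  sets <- lapply(sizes, function(sz) {
    sub <- rarefy(reference, sz)
    names(sub)[sub >= 1]
  })
  list(common = common_loci(c(list(ref_set), sets)),
       detected = vapply(sets, length, integer(1)),
       reference_detected = length(ref_set))
}
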