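#' Collapse alignment 5' ends into CTSS counts
#'
#' A CTSS (CAGE transcription start site) is one genomic position and
#' strand carrying the number of tag 5' ends observed there, per sample.
#'
#' @param aln Alignment table (filtered: artifacts, rRNA and strand
#'   invasion already removed).
#' @return data.frame `chrom`, `pos` (0-based), `strand`, `sample_id`,
#'   `count`, sorted by (chrom, strand, pos).
#' @export
alignments_to_ctss <- function(aln) {
  if (nrow(aln) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), sample_id = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  sample <- ifelse(is.na(aln$sample_id), "all", aln$sample_id)
  key <- paste(aln$chrom, aln$five_prime_pos, aln$strand, sample,
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    sample_id = vapply(parts, `[`, "", 4L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$strand, out$pos), , drop = FALSE]
}

#' Single-linkage clustering of CTSS into tag clusters
#'
#' Adjacent CTSS on the same chromosome and strand join one cluster when
#' their gap is at most `max_gap` nt; no expression threshold is applied.
#' Counts from all samples at one position contribute to the same cluster.
#'
#' @param ctss CTSS table from [alignments_to_ctss()].
#' @param max_gap Maximum distance between consecutive member CTSS
#'   (default 20 nt).
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`
#'   (0-based half-open hull), `strand`, `peak_pos` (CTSS with maximal
#'   summed count; smallest coordinate on ties), `count` (total tags),
#'   plus one `count.<sample>` column per sample.
#' @export
cluster_ctss <- function(ctss, max_gap = 20L) {
  if (nrow(ctss) == 0L) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), peak_pos = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  max_gap <- max(0L, as.numeric(max_gap))
  # collapse samples to unique positions first
  poskey <- paste(ctss$chrom, ctss$strand, ctss$pos, sep = "\r")
  o <- order(ctss$chrom, ctss$strand, ctss$pos)
  ctss <- ctss[o, , drop = FALSE]
  poskey <- poskey[o]
  upos <- !duplicated(poskey)
  uc <- ctss[upos, c("chrom", "strand", "pos"), drop = FALSE]
  same_run <- c(FALSE, uc$chrom[-1] == uc$chrom[-nrow(uc)] &
                  uc$strand[-1] == uc$strand[-nrow(uc)])
  gap <- c(NA_integer_, diff(uc$pos))
  new_cluster <- !same_run | gap > max_gap
  cl_of_upos <- cumsum(new_cluster)
  cl <- cl_of_upos[match(poskey, poskey[upos])]

  total_at_pos <- tapply(ctss$count, poskey, sum)[poskey[upos]]
  samples <- sort(unique(ctss$sample_id))
  out <- data.frame(
    cluster_id = paste0("TC", seq_len(max(cl_of_upos))),
    chrom = tapply(uc$chrom, cl_of_upos, `[`, 1L),
    start = as.integer(tapply(uc$pos, cl_of_upos, min)),
    end = as.integer(tapply(uc$pos, cl_of_upos, max)) + 1L,
    strand = tapply(uc$strand, cl_of_upos, `[`, 1L),
    peak_pos = as.integer(tapply(seq_len(nrow(uc)), cl_of_upos, function(i) {
      uc$pos[i][which.max(total_at_pos[i])]
    })),
    count = as.integer(tapply(ctss$count, cl, sum)),
    stringsAsFactors = FALSE
  )
  for (s in samples) {
    cnt <- integer(nrow(out))
    sel <- ctss$sample_id == s
    agg <- tapply(ctss$count[sel], cl[sel], sum)
    cnt[as.integer(names(agg))] <- as.integer(agg)
    out[[paste0("count.", s)]] <- cnt
  }
  rownames(out) <- NULL
  out
}

#' Tags-per-million normalisation
#'
#' @param counts Numeric vector of tag counts.
#' @param library_total_mapped Total mapped, filtered tags in the library.
#' @return `counts * 1e6 / library_total_mapped`.
#' @export
tpm_normalize <- function(counts, library_total_mapped) {
  if (length(library_total_mapped) != 1L || is.na(library_total_mapped) ||
      library_total_mapped <= 0) {
    stop("library_total_mapped must be a single positive number")
  }
  counts * 1e6 / library_total_mapped
}

#' Write CTSS as BED6 (score = count)
#'
#' One line per (position, strand, sample is pooled); useful for genome
#' browsers.
#'
#' @param ctss CTSS table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ctss_bed <- function(ctss, path) {
  key <- paste(ctss$chrom, ctss$pos, ctss$strand, sep = "\r")
  agg <- tapply(ctss$count, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  strand <- vapply(parts, `[`, "", 3L)
  o <- order(chrom, strand, pos)
  out <- data.frame(chrom[o], pos[o], pos[o] + 1L,
                    paste0("ctss_", seq_along(agg)),
                    as.integer(agg)[o], strand[o])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-strand bedGraph export of CTSS counts
#'
#' @param ctss CTSS table (samples pooled).
#' @param prefix Output path prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @return Invisibly, the two paths.
#' @export
write_ctss_bedgraph <- function(ctss, prefix) {
  paths <- character(0)
  for (sgn in c("+", "-")) {
    sub <- ctss[ctss$strand == sgn, , drop = FALSE]
    key <- paste(sub$chrom, sub$pos, sep = "\r")
    agg <- tapply(sub$count, key, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- as.integer(vapply(parts, `[`, "", 2L))
    o <- order(chrom, pos)
    path <- paste0(prefix, if (sgn == "+") ".plus" else ".minus",
                   ".bedGraph")
    val <- as.integer(agg)[o]
    if (sgn == "-") val <- -val
    utils::write.table(
      data.frame(chrom[o], pos[o], pos[o] + 1L, val),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
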