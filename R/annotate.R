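#' Build gene models for basket annotation
#'
#' Reads gene models from GTF/GFF (exon records grouped by transcript) or
#' BED12 (blocks as exons) and derives the three same-strand feature sets
#' used for classification: promoters (+/- `promoter_flank` nt around every
#' transcript start, merged per gene), merged exons, and gene spans (used
#' for the intron basket).
#'
#' @param annotation Path to a GTF/GFF or BED12 file, or a GRanges of exons
#'   carrying `gene_id` and `transcript_id` metadata columns.
#' @param promoter_flank Half-width of the promoter window (default 100 nt;
#'   the window is `2 * flank + 1` wide, centred on the transcript start).
#' @return A `GeneModels` list of GRanges: `promoters`, `exons`, `genes`,
#'   each with a `gene_id` column; plus `promoter_flank`.
#' @export
read_gene_models <- function(annotation, promoter_flank = 100L) {
  exons <- .exon_granges(annotation)
  if (length(exons) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(structure(list(promoters = empty, exons = empty, genes = empty,
                          promoter_flank = as.integer(promoter_flank)),
                     class = "GeneModels"))
  }
  # flat per-exon vectors; hulls computed by plain aggregation
  ex_tx <- S4Vectors::mcols(exons)$transcript_id
  ex_gene <- S4Vectors::mcols(exons)$gene_id
  ex_chr <- as.character(GenomicRanges::seqnames(exons))
  ex_str <- as.character(BiocGenerics::strand(exons))
  ex_start <- BiocGenerics::start(exons)
  ex_end <- BiocGenerics::end(exons)

  # transcript starts: 5'-most exon base per transcript
  tx_ids <- unique(ex_tx)
  ord <- match(tx_ids, ex_tx)
  tx_str <- ex_str[ord]
  tx_chr <- ex_chr[ord]
  tx_gene <- ex_gene[ord]
  tx_min <- tapply(ex_start, ex_tx, min)[tx_ids]
  tx_max <- tapply(ex_end, ex_tx, max)[tx_ids]
  tss <- ifelse(tx_str == "+", tx_min, tx_max)

  fl <- as.integer(promoter_flank)
  promoters <- GenomicRanges::GRanges(
    seqnames = tx_chr,
    ranges = IRanges::IRanges(pmax(1L, as.integer(tss - fl)),
                              as.integer(tss + fl)),
    strand = tx_str)
  S4Vectors::mcols(promoters)$gene_id <- tx_gene
  promoters <- .merge_by_gene(promoters)

  ex <- exons
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(gene_id = ex_gene)
  ex <- .merge_by_gene(ex)

  g_ids <- unique(ex_gene)
  g_ord <- match(g_ids, ex_gene)
  gene_rng <- GenomicRanges::GRanges(
    seqnames = ex_chr[g_ord],
    ranges = IRanges::IRanges(
      as.integer(tapply(ex_start, ex_gene, min)[g_ids]),
      as.integer(tapply(ex_end, ex_gene, max)[g_ids])),
    strand = ex_str[g_ord])
  S4Vectors::mcols(gene_rng)$gene_id <- g_ids

  structure(list(promoters = promoters, exons = ex, genes = gene_rng,
                 promoter_flank = fl),
            class = "GeneModels")
}

.exon_granges <- function(annotation) {
  if (methods::is(annotation, "GRanges")) return(annotation)
  ext <- tolower(tools::file_ext(annotation))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(annotation, format = ext)
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    return(gr)
  }
  if (ext == "bed") {
    bed <- rtracklayer::import(annotation, format = "bed")
    blocks <- S4Vectors::mcols(bed)$blocks
    if (is.null(blocks)) {  # plain BED: one exon per record
      gr <- bed
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = bed$name, transcript_id = bed$name)
      return(gr)
    }
    gr <- rtracklayer::blocks(bed)
    out <- unlist(gr)
    nm <- rep(bed$name, S4Vectors::elementNROWS(gr))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(gene_id = nm,
                                                  transcript_id = nm)
    strand_rep <- rep(as.character(BiocGenerics::strand(bed)),
                      S4Vectors::elementNROWS(gr))
    BiocGenerics::strand(out) <- strand_rep
    names(out) <- NULL
    return(out)
  }
  stop("unsupported annotation format: ", annotation)
}

.merge_by_gene <- function(gr) {
  gid <- S4Vectors::mcols(gr)$gene_id
  pieces <- lapply(unique(gid), function(g) {
    r <- GenomicRanges::reduce(gr[gid == g])
    S4Vectors::mcols(r)$gene_id <- g
    r
  })
  out <- do.call(c, pieces)
  names(out) <- NULL
  out
}

#' Classify tag clusters into genomic baskets
#'
#' Each cluster is assigned to one of four baskets with precedence
#' promoter > exon > intron > other, testing same-strand overlap of the
#' cluster's peak CTSS (a single base) against the feature sets — or of the
#' whole cluster hull with `by = "hull"`. `stranded = FALSE` ignores strand,
#' for antisense-signal exploration.
#'
#' @param clusters Cluster table from [cluster_ctss()].
#' @param models `GeneModels` from [read_gene_models()].
#' @param by `"peak"` (default) or `"hull"`.
#' @param stranded Same-strand overlap only (default TRUE).
#' @return `clusters` with added `basket` and `gene_id` columns (gene of
#'   the winning feature; ties broken by lexicographic gene id).
#' @export
classify_clusters <- function(clusters, models, by = c("peak", "hull"),
                              stranded = TRUE) {
  by <- match.arg(by)
  n <- nrow(clusters)
  basket <- rep("other", n)
  gene <- rep(NA_character_, n)
  if (n > 0L) {
    q <- if (by == "peak") {
      GenomicRanges::GRanges(clusters$chrom,
                             IRanges::IRanges(clusters$peak_pos + 1L,
                                              width = 1L),
                             strand = clusters$strand)
    } else {
      GenomicRanges::GRanges(clusters$chrom,
                             IRanges::IRanges(clusters$start + 1L,
                                              clusters$end),
                             strand = clusters$strand)
    }
    for (level in c("intron", "exon", "promoter")) {
      subject <- switch(level, promoter = models$promoters,
                        exon = models$exons, intron = models$genes)
      if (length(subject) == 0L) next
      ov <- GenomicRanges::findOverlaps(q, subject,
                                        ignore.strand = !stranded)
      if (length(ov) == 0L) next
      qh <- S4Vectors::queryHits(ov)
      gid <- S4Vectors::mcols(subject)$gene_id[S4Vectors::subjectHits(ov)]
      first <- tapply(gid, qh, function(g) sort(g)[1L])
      idx <- as.integer(names(first))
      basket[idx] <- level
      gene[idx] <- as.character(first)
    }
  }
  clusters$basket <- basket
  clusters$gene_id <- gene
  clusters
}

#' Basket fractions and promoter/exon ratio
#'
#' Tag-weighted fractions of the four baskets per sample, and the
#' promoter/exon tag-count ratio that summarises cap specificity: capped
#' reads start at transcription start sites (promoter basket), while
#' internally primed or strand-invasion reads scatter over gene bodies.
#'
#' @param classified Output of [classify_clusters()].
#' @return A `BasketSummary` data.frame: one row per sample with columns
#'   `sample_id`, `n_tags`, counts and fractions per basket, and
#'   `promoter_exon_ratio` (`Inf` when promoter tags exist but exon tags
#'   are zero; `NaN` when both are zero).
#' @export
basket_summary <- function(classified) {
  count_cols <- grep("^count\\.", names(classified), value = TRUE)
  if (length(count_cols) == 0L) count_cols <- "count"
  baskets <- c("promoter", "exon", "intron", "other")
  rows <- lapply(count_cols, function(cc) {
    sid <- if (cc == "count") "all" else sub("^count\\.", "", cc)
    cnt <- vapply(baskets, function(b) {
      sum(classified[[cc]][classified$basket == b])
    }, numeric(1))
    tot <- sum(cnt)
    frac <- if (tot > 0) cnt / tot else rep(NA_real_, 4L)
    out <- data.frame(sample_id = sid, n_tags = tot,
                      stringsAsFactors = FALSE)
    for (b in baskets) {
      out[[paste0(b, "_count")]] <- cnt[[b]]
      out[[paste0(b, "_fraction")]] <- frac[[b]]
    }
    out$promoter_exon_ratio <- cnt[["promoter"]] / cnt[["exon"]]
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("BasketSummary", "data.frame")
  res
}
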