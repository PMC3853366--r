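#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator: a toy genome with
#' annotated genes, a contaminant record, planted strand-invasion sites,
#' and barcoded libraries mixing five read classes — capped TSS reads,
#' internally primed (uncapped) reads, strand-invasion reads, rRNA
#' carry-over, and oligonucleotide artifacts.
#'
#' Defaults: 1 Mb genome, 200 genes, 64-nt reads, Zipf(1) expression (the
#' distribution of digital expression levels is scale-free), per-base
#' substitution error 0.001, 50,000 reads per sample, the fifteen published
#' barcodes. The default class mix (55% TSS, 25% internal, 10% invasion,
#' 5% rRNA, 5% artifact) represents a reasonably clean library;
#' chemistry-specific mixes come from [chemistry_preset()].
#'
#' @param seed Integer seed driving all reference randomness.
#' @param genome_length Genome size in nt.
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param read_length Sequenced read length in nt.
#' @param class_rates Named numeric vector over
#'   `c("tss","internal","invasion","rrna","artifact")`, summing to 1.
#' @param zipf_exponent Exponent of the rank-frequency expression law.
#' @param error_rate Per-base substitution error rate.
#' @param reads_per_sample Reads emitted per library.
#' @param n_invasion_sites Strand-invasion sites planted in the genome.
#' @param contaminant_length Length of the synthetic rRNA record.
#' @param invasion_site_max_mismatch Planted site motifs carry 0 to this
#'   many mismatches from the oligo end (all within the filter threshold).
#' @param sheet Sample sheet mapping barcodes to samples.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, genome_length = 1e6, n_genes = 200L,
                              exons_per_gene = c(1L, 5L), read_length = 64L,
                              class_rates = c(tss = 0.55, internal = 0.25,
                                              invasion = 0.10, rrna = 0.05,
                                              artifact = 0.05),
                              zipf_exponent = 1.0, error_rate = 0.001,
                              reads_per_sample = 50000L,
                              n_invasion_sites = 300L,
                              contaminant_length = 2000L,
                              invasion_site_max_mismatch = 2L,
                              sheet = default_sample_sheet()) {
  rates <- .check_rates(class_rates)
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    read_length = as.integer(read_length), class_rates = rates,
    zipf_exponent = zipf_exponent, error_rate = error_rate,
    reads_per_sample = as.integer(reads_per_sample),
    n_invasion_sites = as.integer(n_invasion_sites),
    contaminant_length = as.integer(contaminant_length),
    invasion_site_max_mismatch = as.integer(invasion_site_max_mismatch),
    sheet = validate_sample_sheet(sheet)
  ), class = "SimulationConfig")
}

.check_rates <- function(rates) {
  cls <- c("tss", "internal", "invasion", "rrna", "artifact")
  if (is.null(names(rates)) || !all(names(rates) %in% cls)) {
    stop("class_rates must be named with: ", paste(cls, collapse = ", "))
  }
  full <- setNames(numeric(5), cls)
  full[names(rates)] <- rates
  if (any(full < 0) || any(full > 1) || abs(sum(full) - 1) > 1e-8) {
    stop("class_rates must lie in [0,1] and sum to 1")
  }
  full
}

#' Chemistry-specific class mixes
#'
#' Emulated template-switching chemistries, calibrated to the published
#' strand-invasion rates of the real libraries: 9.1% (R3, RNA bases),
#' 48.6% (L1), 38.6% (L2), 35.9% (L3, locked nucleic acid) and 73.6% (D3,
#' all-DNA). The remaining mass is split between capped TSS reads and
#' internally primed reads at 2:1 for the cap-specific R3 chemistry and
#' 1:2 otherwise, reflecting the loss of cap specificity away from RNA
#' bases. rRNA and artifact classes are 0 so that the invasion rate among
#' aligned tags equals the preset.
#'
#' @param chemistry One of `"R3"`, `"D3"`, `"L1"`, `"L2"`, `"L3"`.
#' @return Named class-rate vector for [simulation_config()].
#' @export
chemistry_preset <- function(chemistry = c("R3", "D3", "L1", "L2", "L3")) {
  chemistry <- match.arg(chemistry)
  p_inv <- c(R3 = 0.091, D3 = 0.736, L1 = 0.486, L2 = 0.386,
             L3 = 0.359)[[chemistry]]
  tss_share <- if (chemistry == "R3") 2 / 3 else 1 / 3
  rest <- 1 - p_inv
  c(tss = rest * tss_share, internal = rest * (1 - tss_share),
    invasion = p_inv, rrna = 0, artifact = 0)
}

#' Simulate the reference: genome, gene models, contaminant, planted sites
#'
#' Generates an i.i.d. uniform A/C/G/T genome (one contig, `chr1`), places
#' non-overlapping multi-exon genes on both strands, plants strand-invasion
#' sites in intergenic space (the flank sequence, not the read sequence,
#' carries the artifact signal, matching the genomic test the filter
#' applies), and draws a separate contaminant record. The genomic base at
#' every read start (transcript starts and post-motif site bases) is forced
#' to a non-G so that linker G-run stripping never consumes genomic
#' sequence — template-switching start positions are otherwise ambiguous
#' by one base whenever a transcript starts with G.
#'
#' @param config A `SimulationConfig`.
#' @return A `SimulatedReference` list: `genome` (named character),
#'   `models` (GRanges of exons with gene/transcript ids), `genes`
#'   (data.frame with `gene_id`, `strand`, `tss`, `span_start`, `span_end`),
#'   `expression` (per-gene sampling probabilities), `invasion_sites`
#'   (data.frame `chrom`, `five_prime`, `strand`, `mismatches`),
#'   `contaminant` (named character), `config`.
#' @export
simulate_reference <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, L, replace = TRUE), collapse = "")

  n <- config$n_genes
  genes <- NULL
  exon_list <- list()
  if (n > 0L) {
    cursor <- 500L
    gene_id <- sprintf("G%04d", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- integer(n); span_s <- integer(n); span_e <- integer(n)
    for (g in seq_len(n)) {
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(60:400, n_ex - 1L, replace = TRUE)
                else integer(0)
      gap <- sample(200:1500, 1L)
      start <- cursor + gap
      span <- sum(ex_len) + sum(in_len)
      if (start + span > L - 600L) {
        stop("could not place ", n, " genes in a ", L,
             " nt genome; increase genome_length")
      }
      s <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
      e <- s + ex_len
      exon_list[[g]] <- cbind(s, e)
      span_s[g] <- start; span_e[g] <- start + span
      tss[g] <- if (strand[g] == "+") start else start + span - 1L
      cursor <- start + span
    }
    genes <- data.frame(gene_id = gene_id, strand = strand, tss = tss,
                        span_start = span_s, span_end = span_e,
                        stringsAsFactors = FALSE)
    # force non-G read-start base at every TSS (strand-aware)
    genome <- .force_non_g(genome, tss, strand)
  }

  sites <- .plant_invasion_sites(genome, genes, config)
  genome <- sites$genome
  if (!is.null(genes)) {
    # a capped read whose genomic flank happens to resemble the oligo end
    # is indistinguishable from strand invasion, so its class label would
    # be wrong by definition; push such TSS flanks out of the filter ball
    genome <- .scrub_motif_flank(genome, genes$tss, genes$strand,
                                 ts_oligo_spec()$linker,
                                 config$invasion_site_max_mismatch)
  }

  contaminant <- paste(sample(bases, config$contaminant_length,
                              replace = TRUE), collapse = "")

  ranks <- sample(max(n, 1L))
  expr <- ranks^(-config$zipf_exponent)
  expr <- expr / sum(expr)
  if (n > 0L) names(expr) <- genes$gene_id

  models <- if (n > 0L) {
    ex <- do.call(rbind, lapply(seq_len(n), function(g) {
      m <- exon_list[[g]]
      data.frame(gene = genes$gene_id[g], s = m[, 1], e = m[, 2],
                 strand = genes$strand[g], stringsAsFactors = FALSE)
    }))
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(ex$s + 1L, ex$e),
                                 strand = ex$strand)
    S4Vectors::mcols(gr)$gene_id <- ex$gene
    S4Vectors::mcols(gr)$transcript_id <- paste0(ex$gene, ".1")
    gr
  } else GenomicRanges::GRanges()

  structure(list(genome = c(chr1 = genome), models = models, genes = genes,
                 expression = expr, invasion_sites = sites$sites,
                 contaminant = c(rRNA_synthetic = contaminant),
                 config = config),
            class = "SimulatedReference")
}

# Rewrite the genomic base a read would start on so it is not G on the
# read's strand (G would merge with the linker G-run during trimming).
.force_non_g <- function(genome, pos0, strand) {
  for (i in seq_along(pos0)) {
    p <- pos0[i] + 1L  # 1-based
    b <- substr(genome, p, p)
    if (strand[i] == "+" && b == "G") {
      substr(genome, p, p) <- sample(c("A", "C", "T"), 1L)
    } else if (strand[i] == "-" && b == "C") {
      substr(genome, p, p) <- sample(c("A", "G", "T"), 1L)
    }
  }
  genome
}

.plant_invasion_sites <- function(genome, genes, config) {
  n <- config$n_invasion_sites
  L <- nchar(genome)
  motif <- ts_oligo_spec()$linker  # TATAGGG
  w <- nchar(motif)
  if (n == 0L) {
    return(list(genome = genome,
                sites = data.frame(chrom = character(0),
                                   five_prime = integer(0),
                                   strand = character(0),
                                   mismatches = integer(0))))
  }
  in_gene <- function(p) {
    if (is.null(genes)) return(FALSE)
    any(p >= genes$span_start - 150L & p <= genes$span_end + 150L)
  }
  fp <- integer(n); strand <- character(n); mm <- integer(n)
  taken <- integer(0)
  max_mm <- config$invasion_site_max_mismatch
  mm_probs <- c(0.5, 0.3, 0.2)[seq_len(max_mm + 1L)]
  for (i in seq_len(n)) {
    repeat {
      p <- sample(100:(L - 100L), 1L)  # candidate five-prime position
      if (!in_gene(p) && (length(taken) == 0L ||
                          min(abs(taken - p)) > 80L)) break
    }
    taken <- c(taken, p)
    sgn <- sample(c("+", "-"), 1L)
    k <- sample(0:max_mm, 1L, prob = mm_probs)
    variant <- .mutate_motif(motif, k)
    if (sgn == "+") {
      # motif occupies [p-w, p), read starts at p
      substr(genome, p - w + 1L, p) <- variant
      if (substr(genome, p + 1L, p + 1L) == "G") {
        substr(genome, p + 1L, p + 1L) <- sample(c("A", "C", "T"), 1L)
      }
    } else {
      # upstream window on minus strand = revcomp of [p+1, p+1+w)
      substr(genome, p + 2L, p + 1L + w) <- .revcomp(variant)
      if (substr(genome, p + 1L, p + 1L) == "C") {
        substr(genome, p + 1L, p + 1L) <- sample(c("A", "G", "T"), 1L)
      }
    }
    fp[i] <- p; strand[i] <- sgn; mm[i] <- k
  }
  list(genome = genome,
       sites = data.frame(chrom = "chr1", five_prime = fp, strand = strand,
                          mismatches = mm, stringsAsFactors = FALSE))
}

# Hamming distance between the upstream window of a 5' position (read on
# the tag's strand) and the oligo-end motif; NA at contig edges.
.flank_mm <- function(genome, p0, strand, motif) {
  w <- nchar(motif)
  L <- nchar(genome)
  if (strand == "+") {
    if (p0 - w < 0L) return(NA_integer_)
    win <- substr(genome, p0 - w + 1L, p0)
  } else {
    if (p0 + 1L + w > L) return(NA_integer_)
    win <- .revcomp(substr(genome, p0 + 2L, p0 + 1L + w))
  }
  sum(strsplit(win, "", fixed = TRUE)[[1]] !=
        strsplit(motif, "", fixed = TRUE)[[1]])
}

# Rewrite motif-matching bases upstream of the given 5' positions until the
# window falls outside the Hamming ball of radius max_mm.
.scrub_motif_flank <- function(genome, fp, strand, motif, max_mm) {
  w <- nchar(motif)
  mv <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (i in seq_along(fp)) {
    repeat {
      mm <- .flank_mm(genome, fp[i], strand[i], motif)
      if (is.na(mm) || mm > max_mm) break
      win <- if (strand[i] == "+") {
        substr(genome, fp[i] - w + 1L, fp[i])
      } else {
        .revcomp(substr(genome, fp[i] + 2L, fp[i] + 1L + w))
      }
      j <- which(strsplit(win, "", fixed = TRUE)[[1]] == mv)[1]
      newb <- sample(setdiff(c("A", "C", "G", "T"), mv[j]), 1L)
      if (strand[i] == "+") {
        gpos <- fp[i] - w + j  # 1-based
        substr(genome, gpos, gpos) <- newb
      } else {
        gpos <- fp[i] + w + 2L - j  # 1-based, window pos j on minus strand
        substr(genome, gpos, gpos) <- .revcomp(newb)
      }
    }
  }
  genome
}

.mutate_motif <- function(motif, k) {
  if (k == 0L) return(motif)
  pos <- sample(nchar(motif), k)
  v <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

#' Simulate one barcoded nanoCAGE library
#'
#' Emits `n_reads` reads of layout barcode + UMI + `TATA` + `GGG` (+ extra
#' G's for capped reads, geometric with mean 0.5 — cap reverse
#' transcription adds unencoded cytosines) + insert, with per-base
#' substitution errors, together with a per-read ground-truth table.
#'
#' @param ref `SimulatedReference` from [simulate_reference()].
#' @param sample_id Sample to emit (must be in the config's sheet).
#' @param n_reads Number of reads (default from config).
#' @param class_rates Class mix (default from config; see
#'   [chemistry_preset()]).
#' @param seed Seed for this library's randomness.
#' @param error_rate Per-base substitution rate (default from config).
#' @return List: `reads` (data.frame `read_id`, `sequence`, `quality`),
#'   `truth` (data.frame `read_id`, `sample_id`, `true_class`, `chrom`,
#'   `pos` = true 5'-end position, `strand`, `gene`, `umi`).
#' @export
simulate_library <- function(ref, sample_id, n_reads = NULL,
                             class_rates = NULL, seed = 1L,
                             error_rate = NULL) {
  config <- ref$config
  sheet <- config$sheet
  if (!sample_id %in% sheet$sample_id) stop("unknown sample: ", sample_id)
  barcode <- sheet$barcode[sheet$sample_id == sample_id]
  if (is.null(n_reads)) n_reads <- config$reads_per_sample
  rates <- if (is.null(class_rates)) config$class_rates
           else .check_rates(class_rates)
  if (is.null(error_rate)) error_rate <- config$error_rate
  set.seed(as.integer(seed))

  cls_names <- names(rates)
  cls <- sample(cls_names, n_reads, replace = TRUE, prob = rates)
  if (any(cls %in% c("tss", "internal")) && config$n_genes == 0L) {
    stop("config has no genes but tss/internal rates are positive")
  }
  if (any(cls == "invasion") && nrow(ref$invasion_sites) == 0L) {
    stop("no invasion sites planted but invasion rate is positive")
  }
  umi <- .random_seqs(n_reads, 8L)
  extra_g <- ifelse(cls == "tss", pmin(rgeom(n_reads, 2 / 3), 5L), 0L)
  overhead <- 6L + 8L + 4L + 3L
  ins_len <- config$read_length - overhead - extra_g

  genome <- ref$genome[["chr1"]]
  pos <- rep(NA_integer_, n_reads)
  strand <- rep(NA_character_, n_reads)
  chrom <- rep(NA_character_, n_reads)
  gene <- rep(NA_character_, n_reads)

  i_tss <- which(cls == "tss")
  if (length(i_tss)) {
    g <- sample(config$n_genes, length(i_tss), replace = TRUE,
                prob = ref$expression)
    pos[i_tss] <- ref$genes$tss[g]
    strand[i_tss] <- ref$genes$strand[g]
    chrom[i_tss] <- "chr1"
    gene[i_tss] <- ref$genes$gene_id[g]
  }
  i_int <- which(cls == "internal")
  if (length(i_int)) {
    pick <- .internal_positions(ref, length(i_int), genome)
    pos[i_int] <- pick$pos
    strand[i_int] <- pick$strand
    chrom[i_int] <- "chr1"
    gene[i_int] <- pick$gene
  }
  i_inv <- which(cls == "invasion")
  if (length(i_inv)) {
    s <- sample(nrow(ref$invasion_sites), length(i_inv), replace = TRUE)
    pos[i_inv] <- ref$invasion_sites$five_prime[s]
    strand[i_inv] <- ref$invasion_sites$strand[s]
    chrom[i_inv] <- "chr1"
  }

  inserts <- character(n_reads)
  genomic <- which(cls %in% c("tss", "internal", "invasion"))
  if (length(genomic)) {
    inserts[genomic] <- .extract_inserts(genome, pos[genomic],
                                         strand[genomic],
                                         ins_len[genomic])
  }
  i_rrna <- which(cls == "rrna")
  if (length(i_rrna)) {
    cont <- ref$contaminant[[1]]
    st <- sample(nchar(cont) - max(ins_len[i_rrna]), length(i_rrna),
                 replace = TRUE)
    raw <- substr(rep(cont, length(i_rrna)), st, st + ins_len[i_rrna] - 1L)
    flip <- runif(length(i_rrna)) < 0.5
    raw[flip] <- .revcomp(raw[flip])
    inserts[i_rrna] <- raw
  }
  i_art <- which(cls == "artifact")
  if (length(i_art)) {
    oligo <- ts_oligo_spec()
    unit <- paste0(oligo$head, oligo$linker)
    concat <- strrep(unit, 4L)
    off <- sample(nchar(unit), length(i_art), replace = TRUE)
    inserts[i_art] <- substr(rep(concat, length(i_art)), off,
                             off + ins_len[i_art] - 1L)
  }

  reads <- paste0(barcode, umi, "TATA", "GGG", strrep("G", extra_g),
                  inserts)
  reads <- .apply_errors(reads, error_rate)
  read_id <- paste0(sample_id, "_r", seq_len(n_reads))
  list(
    reads = data.frame(read_id = read_id, sequence = reads,
                       quality = strrep("I", nchar(reads)),
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, sample_id = sample_id,
                       true_class = cls, chrom = chrom, pos = pos,
                       strand = strand, gene = gene, umi = umi,
                       stringsAsFactors = FALSE)
  )
}

# Uniform positions within mature transcripts (exonic coordinates mapped to
# the genome), resampled so that (a) the read-start base is never G on the
# read's strand (linker G-run trimming would eat it) and (b) the upstream
# flank does not fall inside the strand-invasion filter ball — an uncapped
# read with a motif-like flank would be mislabelled by definition.
.internal_positions <- function(ref, n, genome) {
  ex <- ref$models
  gene_of <- S4Vectors::mcols(ex)$gene_id
  widths <- BiocGenerics::width(ex)
  motif <- ts_oligo_spec()$linker
  max_mm <- ref$config$invasion_site_max_mismatch
  g <- sample(length(ref$expression), n, replace = TRUE,
              prob = ref$expression)
  gid <- ref$genes$gene_id[g]
  pos <- integer(n); strand <- ref$genes$strand[g]
  for (i in seq_len(n)) {
    rows <- which(gene_of == gid[i])
    for (attempt in 1:100) {
      r <- if (length(rows) == 1L) rows else
        sample(rows, 1L, prob = widths[rows])
      p <- BiocGenerics::start(ex)[r] - 1L +
        sample(widths[r], 1L) - 1L  # 0-based genomic
      b <- substr(genome, p + 1L, p + 1L)
      bad <- (strand[i] == "+" && b == "G") ||
        (strand[i] == "-" && b == "C")
      if (!bad) {
        mm <- .flank_mm(genome, p, strand[i], motif)
        bad <- !is.na(mm) && mm <= max_mm
      }
      if (!bad) break
    }
    pos[i] <- p
  }
  list(pos = pos, strand = strand, gene = gid)
}

# Insert sequence downstream of a 5' position, read on the tag's strand.
.extract_inserts <- function(genome, pos0, strand, len) {
  L <- nchar(genome)
  plus <- strand == "+"
  out <- character(length(pos0))
  if (any(plus)) {
    s <- pos0[plus] + 1L
    out[plus] <- substr(rep(genome, sum(plus)), s,
                        pmin(s + len[plus] - 1L, L))
  }
  if (any(!plus)) {
    e <- pos0[!plus] + 1L
    s <- pmax(1L, e - len[!plus] + 1L)
    out[!plus] <- .revcomp(substr(rep(genome, sum(!plus)), s, e))
  }
  out
}

.random_seqs <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

.apply_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  hit <- which(runif(total) < rate)
  if (length(hit) == 0L) return(reads)
  ends <- cumsum(lens)
  ridx <- findInterval(hit - 1L, ends) + 1L
  posn <- hit - c(0L, ends)[ridx]
  for (j in seq_along(hit)) {
    i <- ridx[j]; p <- posn[j]
    old <- substr(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  reads
}

#' Alignments derived from simulation ground truth
#'
#' Builds the alignment table an error-free mapper would produce for the
#' genomic read classes (tss, internal, invasion) — a fast stand-in for the
#' aligner when only downstream stages are under study.
#'
#' @param truth Ground-truth table from [simulate_library()].
#' @param ref The `SimulatedReference`.
#' @param insert_length Mapped tag length (default 31, the trimmed insert).
#' @return Alignment table (see [alignment_table()]).
#' @export
alignments_from_truth <- function(truth, ref, insert_length = 31L) {
  sub <- truth[truth$true_class %in% c("tss", "internal", "invasion"), ,
               drop = FALSE]
  L <- nchar(ref$genome[[1]])
  plus <- sub$strand == "+"
  start <- ifelse(plus, sub$pos, pmax(0L, sub$pos - insert_length + 1L))
  end <- ifelse(plus, pmin(sub$pos + insert_length, L), sub$pos + 1L)
  alignment_table(read_id = sub$read_id, chrom = sub$chrom,
                  start = start, end = end, strand = sub$strand,
                  sample_id = sub$sample_id)
}

#' Write a simulated reference to disk
#'
#' @param ref `SimulatedReference`.
#' @param dir Output directory: `genome.fa`, `models.gtf`,
#'   `contaminant.fa`, `invasion_sites.tsv`.
#' @return Invisibly, the paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$genome), gpath)
  cpath <- file.path(dir, "contaminant.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$contaminant), cpath)
  mpath <- file.path(dir, "models.gtf")
  gr <- ref$models
  if (length(gr)) {
    S4Vectors::mcols(gr)$type <- "exon"
    S4Vectors::mcols(gr)$source <- "nanocager"
  }
  rtracklayer::export(gr, mpath, format = "gtf")
  spath <- file.path(dir, "invasion_sites.tsv")
  utils::write.table(ref$invasion_sites, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genome = gpath, models = mpath, contaminant = cpath,
              sites = spath))
}

#' Write simulated reads as FASTQ
#'
#' @param lib Library from [simulate_library()], or a list of them
#'   (multiplexed into one file).
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_library_fastq <- function(lib, path) {
  if (!is.null(lib$reads)) lib <- list(lib)
  reads <- do.call(rbind, lapply(lib, `[[`, "reads"))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}
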