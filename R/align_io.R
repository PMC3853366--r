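#' Construct an alignment table
#'
#' Alignments are plain data.frames in 0-based half-open coordinates with a
#' derived `five_prime_pos` — the genomic position of the tag's 5' end
#' (`start` on the plus strand, `end - 1` on the minus strand) — which seeds
#' all downstream CTSS counting.
#'
#' @param read_id,sample_id Character vectors (sample may be `NA`).
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param n_best_hits Number of co-optimal hits (1 for unique alignments).
#' @return data.frame with class `c("nanocage_alignments", "data.frame")`.
#' @export
alignment_table <- function(read_id, chrom, start, end, strand,
                            sample_id = NA_character_, n_best_hits = 1L) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")))
  df <- data.frame(
    read_id = as.character(read_id),
    sample_id = rep_len(as.character(sample_id), length(read_id)),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    n_best_hits = rep_len(as.integer(n_best_hits), length(read_id)),
    stringsAsFactors = FALSE
  )
  df$five_prime_pos <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("nanocage_alignments", "data.frame")
  df
}

#' Read alignments from SAM, BAM or BED6
#'
#' SAM/BAM records are decoded with Rsamtools/GenomicAlignments (unmapped
#' and secondary records skipped, strand taken from the flag); BED6 via
#' rtracklayer. All coordinates are converted to 0-based half-open and the
#' 5'-end position derived per strand.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed6"`.
#' @param sample_id Optional sample label attached to every record.
#' @return Alignment table (see [alignment_table()]).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "bed6"),
                            sample_id = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", bed = "bed6",
                     stop("cannot guess format of ", path))
  }
  if (format %in% c("sam", "bam")) {
    bam <- if (format == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    } else path
    param <- Rsamtools::ScanBamParam(
      what = "qname",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE))
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    if (length(ga) == 0L) {
      return(alignment_table(character(0), character(0), integer(0),
                             integer(0), character(0)))
    }
    return(alignment_table(
      read_id = S4Vectors::mcols(ga)$qname,
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga) - 1L,
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga)),
      sample_id = sample_id))
  }
  # BED6
  fields <- utils::read.table(path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  if (ncol(fields) < 6L) {
    stop("BED input must have at least 6 columns, found ", ncol(fields))
  }
  strand <- fields[[6]]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("malformed BED strand at line ", bad[1])
  st <- suppressWarnings(as.integer(fields[[2]]))
  en <- suppressWarnings(as.integer(fields[[3]]))
  if (anyNA(st) || anyNA(en)) {
    stop("malformed BED coordinates at line ",
         which(is.na(st) | is.na(en))[1])
  }
  alignment_table(read_id = fields[[4]], chrom = fields[[1]],
                  start = st, end = en, strand = strand,
                  sample_id = sample_id)
}

#' Write alignments as BED6
#'
#' @param aln Alignment table.
#' @param path Output path. Score column carries `n_best_hits`.
#' @return Invisibly, `path`.
#' @export
write_alignments_bed6 <- function(aln, path) {
  out <- data.frame(aln$chrom, aln$start, aln$end, aln$read_id,
                    aln$n_best_hits, aln$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exhaustively align one insert to a small genome
#'
#' Best semi-global hit of the insert over both strands of every contig,
#' found with the bit-parallel matcher — an exact, exhaustive stand-in for a
#' read mapper on toy genomes (guard rail: total genome length 10 Mb).
#' Co-optimal hits at distinct loci make the read unmapped with
#' `n_best_hits` recording the tie, since CTSS counting needs unique 5'
#' positions.
#'
#' @param insert Insert sequence (single string).
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param max_errors Maximum edit distance (default 3).
#' @param read_id,sample_id Labels for the output row.
#' @return One-row alignment table, or zero rows when unmapped (the
#'   `unmapped` attribute then carries `n_best_hits`).
#' @export
naive_align <- function(insert, genome, max_errors = 3L,
                        read_id = "read1", sample_id = NA_character_) {
  res <- align_inserts(setNames(insert, read_id), genome,
                       max_errors = max_errors, sample_id = sample_id)
  aln <- res$alignments
  if (nrow(aln) == 0L) {
    attr(aln, "unmapped") <- res$unmapped
  }
  aln
}

#' Exhaustively align many inserts to a small genome
#'
#' Two passes: exact matches are located for all reads at once with a
#' Biostrings `PDict`; reads without an exact hit are rescanned with the
#' bit-parallel matcher up to `max_errors` edits.
#'
#' @param inserts Named character vector (names = read ids).
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param max_errors Maximum edit distance (default 3).
#' @param sample_id Sample label(s), recycled.
#' @return List: `alignments` (unique best hits), `unmapped` (data.frame of
#'   read_id and n_best_hits; 0 = no hit within `max_errors`,
#'   >1 = multimapper).
#' @export
align_inserts <- function(inserts, genome, max_errors = 3L,
                          sample_id = NA_character_) {
  seqs <- .genome_seqs(genome)
  if (sum(nchar(seqs)) > 10e6) {
    stop("genome larger than 10 Mb; use an external aligner")
  }
  if (is.null(names(inserts))) {
    names(inserts) <- paste0("read", seq_along(inserts))
  }
  inserts <- toupper(inserts)
  sample_id <- rep_len(as.character(sample_id), length(inserts))
  n <- length(inserts)
  hit_chrom <- character(n); hit_start <- integer(n); hit_end <- integer(n)
  hit_strand <- character(n); nbest <- integer(n); mapped <- logical(n)

  clean <- !is.na(inserts) & nzchar(inserts) &
    !grepl("[^ACGT]", inserts)
  exact_hits <- .exact_hits(inserts, seqs, which(clean))
  todo <- integer(0)
  for (i in seq_len(n)) {
    if (!clean[i] && (is.na(inserts[i]) || !nzchar(inserts[i]))) {
      nbest[i] <- 0L
      next
    }
    h <- exact_hits[[i]]
    if (!is.null(h) && nrow(h) >= 1L) {
      nbest[i] <- nrow(h)
      if (nrow(h) == 1L) {
        mapped[i] <- TRUE
        hit_chrom[i] <- h$chrom; hit_start[i] <- h$start
        hit_end[i] <- h$end; hit_strand[i] <- h$strand
      }
    } else {
      todo <- c(todo, i)
    }
  }
  for (i in todo) {
    h <- .scan_genome(inserts[i], seqs, max_errors)
    nbest[i] <- h$n_best
    if (h$n_best == 1L) {
      mapped[i] <- TRUE
      hit_chrom[i] <- h$chrom; hit_start[i] <- h$start
      hit_end[i] <- h$end; hit_strand[i] <- h$strand
    }
  }
  keep <- which(mapped)
  aln <- alignment_table(
    read_id = names(inserts)[keep], chrom = hit_chrom[keep],
    start = hit_start[keep], end = hit_end[keep],
    strand = hit_strand[keep], sample_id = sample_id[keep],
    n_best_hits = 1L)
  unm <- which(!mapped)
  list(alignments = aln,
       unmapped = data.frame(read_id = names(inserts)[unm],
                             n_best_hits = nbest[unm],
                             stringsAsFactors = FALSE))
}

# Exact-match pass: PDict per insert width, forward + reverse complement.
# Returns a list (index by read) of data.frames chrom/start/end/strand,
# NULL where the read was not eligible.
.exact_hits <- function(inserts, seqs, idx) {
  out <- vector("list", length(inserts))
  if (length(idx) == 0L) return(out)
  widths <- nchar(inserts[idx])
  chroms <- Biostrings::DNAStringSet(seqs)
  for (w in unique(widths)) {
    sub <- idx[widths == w]
    fwd <- Biostrings::DNAStringSet(inserts[sub])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    hits <- rep(list(NULL), length(sub))
    for (ci in seq_along(chroms)) {
      cname <- names(seqs)[ci]
      for (sgn in c("+", "-")) {
        pd <- if (sgn == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, chroms[[ci]])
        cnt <- S4Vectors::elementNROWS(m)
        for (j in which(cnt > 0L)) {
          st <- BiocGenerics::start(m[[j]]) - 1L
          hits[[j]] <- rbind(hits[[j]], data.frame(
            chrom = cname, start = st, end = st + w,
            strand = sgn, stringsAsFactors = FALSE))
        }
      }
    }
    for (j in seq_along(sub)) {
      out[[sub[j]]] <- if (is.null(hits[[j]])) {
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   stringsAsFactors = FALSE)
      } else hits[[j]]
    }
  }
  out
}

# Full bit-parallel scan of one insert over both strands of all contigs.
# Co-optimal end offsets within one locus (closer than pattern length) are
# collapsed before counting distinct best hits.
.scan_genome <- function(insert, seqs, max_errors) {
  rc <- .revcomp(insert)
  m <- nchar(insert)
  best <- m + 1L
  hits <- list()
  for (cname in names(seqs)) {
    txt <- seqs[[cname]]
    for (sgn in c("+", "-")) {
      pat <- if (sgn == "+") insert else rc
      r <- .cpp_scan_best(pat, txt, 1000L)
      if (r$min_distance < best) {
        best <- r$min_distance
        hits <- list()
      }
      if (r$min_distance == best) {
        hits[[length(hits) + 1L]] <- list(chrom = cname, strand = sgn,
                                          ends = r$end_positions)
      }
    }
  }
  if (best > max_errors) return(list(n_best = 0L))
  loci <- list()
  for (h in hits) {
    ends <- h$ends
    grp <- cumsum(c(TRUE, diff(ends) > m))
    for (g in unique(grp)) {
      loci[[length(loci) + 1L]] <- list(chrom = h$chrom, strand = h$strand,
                                        end = min(ends[grp == g]))
    }
  }
  if (length(loci) != 1L) return(list(n_best = length(loci)))
  loc <- loci[[1]]
  pat <- if (loc$strand == "+") insert else rc
  span <- .locate_span(pat, seqs[[loc$chrom]], loc$end, best)
  list(n_best = 1L, chrom = loc$chrom, strand = loc$strand,
       start = span$start, end = span$end)
}

# Given a best end offset and distance, recover the match start by scanning
# the reversed pattern against the reversed upstream window. Leftmost start
# among co-optimal spans, for determinism.
.locate_span <- function(pattern, text, end, dist) {
  m <- nchar(pattern)
  win_start <- max(0L, end - m - dist)
  win <- substr(text, win_start + 1L, end)
  r <- .cpp_scan_best(.str_rev(pattern), .str_rev(win), 64L)
  j <- max(r$end_positions)  # longest span = leftmost start
  list(start = end - j, end = end)
}

.str_rev <- function(s) intToUtf8(rev(utf8ToInt(s)))

.genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- setNames(toupper(as.character(genome)), names(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome) && !grepl("^[ACGTNacgtn]+$", genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("\\s.*$", "", names(x))
    seqs <- setNames(toupper(as.character(x)), names(x))
  } else {
    seqs <- toupper(genome)
    if (is.null(names(seqs))) {
      names(seqs) <- paste0("chr", seq_along(seqs))
    }
  }
  seqs
}
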