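#' Flag a read matching a ribosomal RNA contaminant
#'
#' A read is flagged when the whole insert (or its reverse complement)
#' aligns semi-globally to a substring of any contaminant record within `k`
#' edits — the screen used to drop rRNA carry-over before tag counting.
#' Matching runs on the Myers bit-parallel column update for inserts up to
#' 64 nt and the plain dynamic-programming scan beyond.
#'
#' @param insert Insert sequence (single string).
#' @param contaminants Contaminant sequences: a character vector, a
#'   `DNAStringSet`, or a FASTA path.
#' @param k Maximum edit distance; default `floor(0.1 * nchar(insert))`.
#' @return `TRUE` when the insert matches a contaminant. Inserts shorter
#'   than 12 nt are never flagged (too little specificity) and raise a
#'   warning.
#' @export
rrna_flag <- function(insert, contaminants, k = NULL) {
  insert <- .norm_seq(insert, "insert")
  res <- rrna_flag_many(insert, contaminants,
                        k = if (is.null(k)) NULL else as.integer(k))
  res$flagged[1L]
}

#' Vectorised rRNA contaminant screen
#'
#' @param inserts Character vector of insert sequences.
#' @param contaminants As in [rrna_flag()].
#' @param k Maximum edit distance; a single integer applied to every read,
#'   or `NULL` for the per-read default `floor(0.1 * insert length)`.
#' @return List with `flagged` (logical vector) and `short` (count of
#'   inserts under 12 nt, never flagged).
#' @export
rrna_flag_many <- function(inserts, contaminants, k = NULL) {
  refs <- .contaminant_seqs(contaminants)
  if (length(refs) == 0L) stop("contaminants must be non-empty")
  inserts <- toupper(inserts)
  lens <- nchar(inserts)
  kvec <- if (is.null(k)) as.integer(floor(0.1 * lens))
          else rep_len(as.integer(k), length(inserts))
  flagged <- logical(length(inserts))
  short <- lens < 12L
  if (any(short)) {
    warning(sum(short), " insert(s) shorter than 12 nt never flagged")
  }
  test <- which(!short & lens > 0L)
  if (length(test)) {
    flagged[test] <- .cpp_contaminant_flag(inserts[test], refs, kvec[test])
  }
  list(flagged = flagged, short = sum(short))
}

#' Screen a FASTQ file for rRNA contamination
#'
#' @param fastq Input FASTQ path.
#' @param contaminants Contaminant FASTA path (or sequences).
#' @param out Output FASTQ path; flagged reads are dropped when
#'   `action = "drop"`, or kept with `" rrna_failed"` appended to the header
#'   comment when `action = "mark"`.
#' @param k Maximum edit distance (see [rrna_flag_many()]).
#' @param action `"drop"` or `"mark"`.
#' @return List of counts: `input`, `flagged`, `kept`, `short`.
#' @export
rrna_filter_fastq <- function(fastq, contaminants, out, k = NULL,
                              action = c("drop", "mark")) {
  action <- match.arg(action)
  rd <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                     with.qualities = TRUE)
  res <- rrna_flag_many(as.character(rd), contaminants, k)
  keep <- if (action == "drop") !res$flagged else rep(TRUE, length(rd))
  x <- rd[keep]
  if (action == "mark") {
    nm <- names(x)
    nm[res$flagged] <- paste(nm[res$flagged], "rrna_failed")
    names(x) <- nm
  }
  quals <- Biostrings::BStringSet(S4Vectors::mcols(x)$qualities)
  Biostrings::writeXStringSet(x, out, format = "fastq", qualities = quals)
  list(input = length(rd), flagged = sum(res$flagged),
       kept = sum(keep), short = res$short)
}

.contaminant_seqs <- function(contaminants) {
  if (methods::is(contaminants, "DNAStringSet")) {
    return(toupper(as.character(contaminants)))
  }
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) {
    return(toupper(as.character(Biostrings::readDNAStringSet(contaminants))))
  }
  toupper(as.character(contaminants))
}
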