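#' Flag strand-invasion artifacts
#'
#' Strand invasion happens when the template-switching oligo hybridises to
#' a complementary stretch of the nascent first-strand cDNA instead of the
#' cap site, truncating reverse transcription. Such tags are recognisable
#' genomically: the sequence immediately upstream of the tag's 5' end, read
#' on the tag's strand, resembles the oligo 3' end. A tag is flagged when
#' the upstream window is within `max_mismatch` Hamming mismatches of the
#' motif (default `TATAGGG`, threshold 2).
#'
#' For minus-strand tags the window is the reverse complement of the
#' `w` bases genomically downstream of the 5' end. Tags closer than `w`
#' to the contig edge cannot be tested; they are never flagged and counted
#' under `edge`.
#'
#' @param aln Alignment table (see [alignment_table()]); a single row works.
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param oligo_end Motif compared against the upstream window
#'   (default `"TATAGGG"`).
#' @param max_mismatch Flagging threshold (default 2 mismatches).
#' @param n_g Optional tolerance for unencoded cap-derived G's: when the
#'   tag's first aligned base is G, up to `n_g` leading G's of the motif are
#'   excluded from mismatch counting (default 0 = off).
#' @return The alignment table with added columns `upstream_window`,
#'   `mismatches` (NA at contig edges) and `si_flagged`; attribute
#'   `edge` counts untestable tags.
#' @export
flag_strand_invasion <- function(aln, genome, oligo_end = "TATAGGG",
                                 max_mismatch = 2L, n_g = 0L) {
  oligo_end <- .norm_seq(oligo_end, "oligo_end")
  w <- nchar(oligo_end)
  seqs <- .genome_seqs(genome)
  lens <- nchar(seqs)
  fp <- aln$five_prime_pos
  plus <- aln$strand == "+"
  clen <- lens[aln$chrom]

  # window coordinates, 0-based half-open on the forward strand
  win_start <- ifelse(plus, fp - w, fp + 1L)
  win_end <- win_start + w
  testable <- win_start >= 0L & win_end <= clen

  windows <- rep(NA_character_, nrow(aln))
  if (any(testable)) {
    idx <- which(testable)
    raw <- substr(seqs[aln$chrom[idx]], win_start[idx] + 1L, win_end[idx])
    minus <- !plus[idx]
    if (any(minus)) raw[minus] <- .revcomp(raw[minus])
    windows[idx] <- raw
  }

  mism <- .hamming_to_motif(windows, oligo_end)
  if (n_g > 0L) {
    lead_g <- attr(regexpr("^G+", oligo_end), "match.length")
    drop <- min(as.integer(n_g), max(lead_g, 0L))
    if (drop > 0L) {
      first_base <- substr(.first_aligned_base(aln, seqs), 1L, 1L)
      trimmed <- substr(oligo_end, drop + 1L, w)
      alt <- .hamming_to_motif(substr(windows, drop + 1L, w), trimmed)
      use <- !is.na(mism) & first_base == "G"
      mism[use] <- pmin(mism[use], alt[use])
    }
  }

  aln$upstream_window <- windows
  aln$mismatches <- mism
  aln$si_flagged <- !is.na(mism) & mism <= max_mismatch
  attr(aln, "edge") <- sum(!testable)
  aln
}

.first_aligned_base <- function(aln, seqs) {
  fp <- aln$five_prime_pos
  out <- substr(seqs[aln$chrom], fp + 1L, fp + 1L)
  minus <- aln$strand == "-"
  if (any(minus)) out[minus] <- .revcomp(out[minus])
  out
}

#' Strand-invasion rate with binomial standard error
#'
#' @param calls Output of [flag_strand_invasion()] (needs `si_flagged`;
#'   groups by `sample_id` when present).
#' @param background Optional false-flag probability of a genuine tag
#'   (see [invasion_false_flag_prob()]). When given, an additional
#'   `rate_adjusted` column reports the unbiased invasion-rate estimate
#'   `(rate - background) / (1 - background)`, truncated at 0: a genuine
#'   tag is flagged with probability `background` by chance, so the raw
#'   flagged fraction overestimates the artifact rate by that amount.
#' @return data.frame with `sample_id`, `n`, `flagged`, `rate`, `se`
#'   (binomial standard error of the rate), plus `rate_adjusted` when
#'   `background` is supplied.
#' @export
invasion_rate <- function(calls, background = NULL) {
  if (nrow(calls) == 0L) stop("no invasion calls")
  grp <- if (all(is.na(calls$sample_id))) rep("all", nrow(calls))
         else ifelse(is.na(calls$sample_id), "unassigned", calls$sample_id)
  out <- do.call(rbind, lapply(split(calls$si_flagged, grp), function(f) {
    n <- length(f); x <- sum(f); p <- x / n
    data.frame(n = n, flagged = x, rate = p,
               se = sqrt(p * (1 - p) / n))
  }))
  out$sample_id <- rownames(out)
  rownames(out) <- NULL
  out <- out[, c("sample_id", "n", "flagged", "rate", "se")]
  if (!is.null(background)) {
    stopifnot(background >= 0, background < 1)
    out$rate_adjusted <- pmax(0, (out$rate - background) / (1 - background))
  }
  out
}

#' Split alignments by strand-invasion status
#'
#' @param calls Output of [flag_strand_invasion()].
#' @return List with `kept` and `flagged` alignment tables and `stats`
#'   (flagged, kept, edge, rate, se).
#' @export
split_strand_invasion <- function(calls) {
  flagged <- calls[calls$si_flagged, , drop = FALSE]
  kept <- calls[!calls$si_flagged, , drop = FALSE]
  n <- nrow(calls)
  p <- nrow(flagged) / max(n, 1L)
  list(kept = kept, flagged = flagged,
       stats = list(flagged = nrow(flagged), kept = nrow(kept),
                    edge = attr(calls, "edge") %||% 0L,
                    rate = p, se = sqrt(p * (1 - p) / max(n, 1L))))
}

#' Expected false-flag probability on a uniform random genome
#'
#' Closed form: the chance that a `w`-mer drawn i.i.d. uniform over
#' A/C/G/T lies within `max_mismatch` Hamming mismatches of a fixed motif,
#' \eqn{\sum_{i=0}^{k} \binom{w}{i} 3^i / 4^w}. For the default 7-nt motif
#' at 2 mismatches this is 211/16384, about 1.29% — the unavoidable
#' background loss of genuine tags to the filter.
#'
#' @param w Window length (default 7).
#' @param max_mismatch Threshold (default 2).
#' @return Probability.
#' @export
invasion_false_flag_prob <- function(w = 7L, max_mismatch = 2L) {
  i <- 0:max_mismatch
  sum(choose(w, i) * 3^i) / 4^w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
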