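#' Semi-global edit distance of a pattern against a text
#'
#' Aligns the whole `pattern` against any substring of `text` (both text ends
#' free) under unit-cost Levenshtein distance and reports the minimum distance
#' together with every 0-based text offset (1-past-end) at which a best match
#' ends. `N` never matches any symbol, including another `N` — conservative
#' behaviour for contaminant screening. Input is case-insensitive.
#'
#' Patterns of up to 64 nt are processed with the Myers bit-parallel column
#' update (see [myers_search()]); longer patterns fall back to the plain
#' dynamic-programming scan.
#'
#' @param pattern Non-empty nucleotide string (A/C/G/T/N).
#' @param text Nucleotide string; may be empty, in which case the distance is
#'   the pattern length and the single end offset is 0.
#' @return A `MatchResult`: list with `min_distance` (integer) and
#'   `end_positions` (strictly increasing integer vector of 0-based offsets).
#' @examples
#' edit_distance_semiglobal("GGG", "AGGGA")  # distance 0, end offset 4
#' @export
edit_distance_semiglobal <- function(pattern, text) {
  pattern <- .norm_seq(pattern, "pattern")
  text <- .norm_seq(text, "text", allow_empty = TRUE)
  res <- if (nchar(pattern) <= 64L) .cpp_myers(pattern, text)
         else .cpp_semiglobal(pattern, text)
  structure(res, class = "MatchResult")
}

#' Bit-parallel approximate search (Myers 1999)
#'
#' Searches `text` for matches of the whole `pattern` within at most `k`
#' edits, using the Myers bit-parallel dynamic-programming column update —
#' the same algorithm rRNA screening tools use for contaminant detection.
#' The hit set equals [edit_distance_semiglobal()]'s best-match set filtered
#' at distance `<= k`: `min_distance` is always the global minimum, and
#' `end_positions` is empty when that minimum exceeds `k`.
#'
#' @param pattern Nucleotide string of at most 64 symbols (one machine word).
#' @param text Nucleotide string to search.
#' @param k Maximum edit distance, `0 <= k < nchar(pattern)`.
#' @return A `MatchResult` (see [edit_distance_semiglobal()]); hits absent
#'   when no match within `k` exists.
#' @export
myers_search <- function(pattern, text, k) {
  pattern <- .norm_seq(pattern, "pattern")
  if (nchar(pattern) > 64L) {
    stop("pattern longer than 64 symbols; use edit_distance_semiglobal(), ",
         "which falls back to the plain DP scan")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k >= nchar(pattern)) {
    stop("k must satisfy 0 <= k < nchar(pattern)")
  }
  text <- .norm_seq(text, "text", allow_empty = TRUE)
  res <- .cpp_myers(pattern, text)
  if (res$min_distance > k) res$end_positions <- integer(0)
  structure(res, class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat("MatchResult: min_distance =", x$min_distance,
      "| ends =", paste(utils::head(x$end_positions, 10L), collapse = ","),
      if (length(x$end_positions) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Count mismatching positions between two equal-length strings
#'
#' Hamming distance with the convention that `N` differs from every symbol,
#' including another `N`.
#'
#' @param a,b Strings of equal length.
#' @return Non-negative integer count of differing positions.
#' @export
hamming_mismatches <- function(a, b) {
  a <- .norm_seq(a, "a", allow_empty = TRUE)
  b <- .norm_seq(b, "b", allow_empty = TRUE)
  if (nchar(a) != nchar(b)) stop("a and b must have equal length")
  if (nchar(a) == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# Vectorised Hamming mismatch counts of many windows against one motif.
# Windows shorter than the motif (contig edges) give NA.
.hamming_to_motif <- function(windows, motif) {
  w <- nchar(motif)
  out <- rep(NA_integer_, length(windows))
  ok <- !is.na(windows) & nchar(windows) == w
  if (any(ok)) {
    mv <- strsplit(motif, "", fixed = TRUE)[[1]]
    wm <- matrix(unlist(strsplit(windows[ok], "", fixed = TRUE),
                        use.names = FALSE), ncol = w, byrow = TRUE)
    mm <- t(t(wm) != mv) | wm == "N" | matrix(rep(mv == "N", sum(ok)),
                                              ncol = w, byrow = TRUE)
    out[ok] <- as.integer(rowSums(mm))
  }
  out
}

.norm_seq <- function(x, what, allow_empty = FALSE) {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    stop(what, " must be a single character string")
  }
  if (!allow_empty && nchar(x) == 0L) stop(what, " must be non-empty")
  toupper(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
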