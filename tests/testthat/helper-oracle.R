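# Independent oracles used across the suite. These are deliberately written
# as plain-R reference implementations, separate from the package's C++
# matcher and clustering code paths.

# Wagner-Fischer semi-global dynamic programming: whole pattern vs any
# substring of text (both text ends free), unit costs, N matches nothing.
# Returns min distance and all 0-based 1-past-end offsets achieving it.
dp_oracle <- function(pattern, text) {
  pv <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  tv <- if (nchar(text)) strsplit(toupper(text), "", fixed = TRUE)[[1]]
        else character(0)
  m <- length(pv)
  prev <- 0:m
  scores <- integer(length(tv) + 1L)
  scores[1L] <- m
  ivec <- 0:m
  for (j in seq_along(tv)) {
    sub <- as.integer(pv != tv[j] | pv == "N" | tv[j] == "N")
    tent <- pmin(prev[-(m + 1L)] + sub,  # diagonal
                 prev[-1L] + 1L)         # horizontal (consume text)
    # vertical (consume pattern) via running minimum
    base <- c(0L, tent)
    col <- cummin(base - ivec) + ivec
    prev <- col
    scores[j + 1L] <- col[m + 1L]
  }
  best <- min(scores)
  list(min_distance = best, end_positions = which(scores == best) - 1L)
}

# Oracle hit set for a search capped at k errors: best ends when the best
# distance is within k, empty otherwise.
dp_oracle_k <- function(pattern, text, k) {
  r <- dp_oracle(pattern, text)
  if (r$min_distance > k) r$end_positions <- integer(0)
  r
}

# Brute-force single-linkage clustering oracle: connected components of the
# graph joining CTSS (same chrom/strand) at gap <= max_gap.
cluster_oracle <- function(ctss, max_gap) {
  key <- paste(ctss$chrom, ctss$strand)
  comp <- integer(nrow(ctss))
  next_id <- 0L
  for (kv in unique(key)) {
    idx <- which(key == kv)
    pos <- ctss$pos[idx]
    n <- length(idx)
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          if (lab[a] != lab[b] && abs(pos[a] - pos[b]) <= max_gap) {
            lab[lab == max(lab[a], lab[b])] <- min(lab[a], lab[b])
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    comp[idx] <- next_id + match(lab, sort(unique(lab)))
    next_id <- next_id + length(unique(lab))
  }
  comp
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", intToUtf8(rev(utf8ToInt(x))))
}

# Small simulation shared by several tests: reference plus one library.
tiny_reference <- function(seed = 101, genome_length = 60000L,
                           n_genes = 15L, n_sites = 40L) {
  simulate_reference(simulation_config(
    seed = seed, genome_length = genome_length, n_genes = n_genes,
    n_invasion_sites = n_sites))
}
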