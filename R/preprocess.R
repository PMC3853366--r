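#' Preprocessing configuration
#'
#' Defaults for the read-layout parser and artifact screen. Reads are assumed
#' to start at the sample barcode: the nanoCAGE sequencing primer anneals to
#' the constant oligo head, so the head is not sequenced. Set
#' `head_included = TRUE` for layouts where the 24-nt head is present.
#'
#' @param trim_length Inserts are truncated to this many nt (default 31).
#' @param barcode_max_mismatch Maximum Hamming distance for barcode
#'   assignment (default 0; at 1, ambiguous reads become unassigned).
#' @param head_included Whether reads begin with the 24-nt constant head.
#' @param artifact_fraction Flag a read as artifact when at least this
#'   fraction of its insert is covered by matches to the artifact library.
#' @param artifact_k Maximum edit distance per artifact window match.
#' @param artifact_window Sliding-window length for artifact coverage.
#' @return A named list of settings.
#' @export
preprocess_config <- function(trim_length = 31L, barcode_max_mismatch = 0L,
                              head_included = FALSE, artifact_fraction = 0.8,
                              artifact_k = 1L, artifact_window = 12L) {
  list(trim_length = as.integer(trim_length),
       barcode_max_mismatch = as.integer(barcode_max_mismatch),
       head_included = isTRUE(head_included),
       artifact_fraction = artifact_fraction,
       artifact_k = as.integer(artifact_k),
       artifact_window = as.integer(artifact_window))
}

#' Parse one nanoCAGE read
#'
#' Extracts the 6-nt sample barcode and 8-nt UMI, removes the linker
#' (literal `TATA` followed by the full run of 3 or more G's — capped
#' templates make the reverse transcriptase add extra template-switching
#' C's, read here as extra G's), and trims the remaining insert to
#' `trim_length`.
#'
#' @param raw_sequence Read sequence as a single string.
#' @param raw_qualities Optional quality string of equal length.
#' @param sheet Sample sheet (see [default_sample_sheet()]).
#' @param config Settings from [preprocess_config()].
#' @return A `ParsedRead` list: `read_id`, `sample_id`, `umi`, `insert`,
#'   `insert_qualities`, `status` (one of `"assigned"`, `"unassigned"`,
#'   `"artifact"`).
#' @export
parse_read <- function(raw_sequence, raw_qualities = NULL,
                       sheet = default_sample_sheet(),
                       config = preprocess_config()) {
  df <- .parse_reads_vec(
    seqs = toupper(raw_sequence),
    quals = if (is.null(raw_qualities)) NA_character_ else raw_qualities,
    ids = "read1", sheet = sheet, config = config)
  structure(as.list(df[1L, ]), class = "ParsedRead")
}

# Vectorised layout parser shared by parse_read() and preprocess_fastq().
.parse_reads_vec <- function(seqs, quals, ids, sheet, config) {
  sheet <- validate_sample_sheet(sheet)
  if (config$head_included) {
    head_len <- nchar(ts_oligo_spec()$head)
    seqs <- substr(seqs, head_len + 1L, nchar(seqs))
    quals <- ifelse(is.na(quals), quals,
                    substr(quals, head_len + 1L, nchar(quals)))
  }
  n <- length(seqs)
  bc_len <- 6L; umi_len <- 8L
  min_len <- bc_len + umi_len + 7L  # barcode + UMI + TATA + GGG

  too_short <- nchar(seqs) < min_len
  barcode <- substr(seqs, 1L, bc_len)
  umi <- substr(seqs, bc_len + 1L, bc_len + umi_len)
  tata <- substr(seqs, bc_len + umi_len + 1L, bc_len + umi_len + 4L)
  tail <- substr(seqs, bc_len + umi_len + 5L, nchar(seqs))
  g_run <- attr(regexpr("^G+", tail), "match.length")
  g_run[g_run < 0L] <- 0L
  linker_ok <- tata == "TATA" & g_run >= 3L

  sample_idx <- match(barcode, sheet$barcode)
  if (config$barcode_max_mismatch > 0L && anyNA(sample_idx)) {
    unm <- which(is.na(sample_idx) & !too_short)
    if (length(unm)) {
      bmat <- .barcode_mismatch_matrix(barcode[unm], sheet$barcode)
      best <- apply(bmat, 1L, min)
      nbest <- rowSums(bmat == best)
      hit <- best <= config$barcode_max_mismatch & nbest == 1L
      sample_idx[unm[hit]] <- apply(bmat[hit, , drop = FALSE], 1L, which.min)
    }
  }

  ins_start <- bc_len + umi_len + 4L + g_run + 1L
  insert <- substr(seqs, ins_start, ins_start + config$trim_length - 1L)
  insert_q <- ifelse(is.na(quals), NA_character_,
                     substr(quals, ins_start,
                            ins_start + config$trim_length - 1L))

  status <- rep("assigned", n)
  status[is.na(sample_idx)] <- "unassigned"
  status[too_short | !linker_ok] <- "artifact"

  data.frame(
    read_id = ids,
    sample_id = ifelse(status == "assigned", sheet$sample_id[sample_idx],
                       NA_character_),
    umi = ifelse(status == "assigned", umi, NA_character_),
    insert = ifelse(status == "artifact", NA_character_, insert),
    insert_qualities = ifelse(status == "artifact", NA_character_, insert_q),
    status = status,
    stringsAsFactors = FALSE
  )
}

.barcode_mismatch_matrix <- function(queries, barcodes) {
  qm <- matrix(unlist(strsplit(queries, "", fixed = TRUE)), ncol = 6L,
               byrow = TRUE)
  cols <- lapply(barcodes, function(b) {
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    as.integer(rowSums(t(t(qm) != bv) | qm == "N"))
  })
  matrix(unlist(cols), nrow = nrow(qm), dimnames = list(NULL, barcodes))
}

#' Default oligonucleotide-artifact library
#'
#' Sequences a tag-dust read can be pieced from: the constant oligo head,
#' head-linker junctions as they appear in empty constructs, and linker
#' concatemers. The UMI is random in real artifacts and is therefore not
#' represented. Extra adapter sequences can be appended.
#'
#' @param oligo A `TSOligoSpec` (see [ts_oligo_spec()]).
#' @param adapters Optional character vector of extra adapter sequences.
#' @return Character vector of artifact reference sequences.
#' @export
default_artifact_library <- function(oligo = ts_oligo_spec(),
                                     adapters = character(0)) {
  toupper(c(
    oligo$head,
    paste0(oligo$head, oligo$linker),
    paste0(oligo$linker, oligo$head),
    strrep(oligo$linker, 6L),
    adapters
  ))
}

#' Flag oligonucleotide-artifact reads
#'
#' A read is an artifact when at least `artifact_fraction` of its insert is
#' covered by sliding windows (length `artifact_window`, step 1) matching
#' the artifact library within `artifact_k` edits — a deterministic coverage
#' criterion for empty constructs and oligo concatemers.
#'
#' @param parsed A `ParsedRead` or the data.frame from [preprocess_fastq()].
#' @param artifact_library Character vector of artifact sequences
#'   (default [default_artifact_library()]).
#' @param config Settings from [preprocess_config()].
#' @return Input with `status` set to `"artifact"` where flagged (assigned
#'   and unassigned reads are both screened); single `ParsedRead` in,
#'   single `ParsedRead` out.
#' @export
artifact_filter <- function(parsed,
                            artifact_library = default_artifact_library(),
                            config = preprocess_config()) {
  single <- inherits(parsed, "ParsedRead")
  df <- if (single) as.data.frame(unclass(parsed), stringsAsFactors = FALSE)
        else parsed
  if (length(artifact_library) == 0L) {
    warning("empty artifact library; no reads flagged")
    return(parsed)
  }
  idx <- which(df$status != "artifact" & !is.na(df$insert) &
                 nzchar(df$insert))
  if (length(idx)) {
    cov <- .cpp_artifact_coverage(toupper(df$insert[idx]),
                                  toupper(artifact_library),
                                  config$artifact_window, config$artifact_k)
    df$status[idx[cov >= config$artifact_fraction]] <- "artifact"
  }
  if (single) structure(as.list(df[1L, ]), class = "ParsedRead") else df
}

#' Parse, demultiplex and artifact-screen a FASTQ file
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param sheet Sample sheet.
#' @param config Settings from [preprocess_config()].
#' @param artifact_library Artifact sequences; `NULL` skips the screen.
#' @return List with `reads` (parsed data.frame; one row per input read) and
#'   `summary` (input, assigned per sample, unassigned, artifact counts).
#' @export
preprocess_fastq <- function(fastq, sheet = default_sample_sheet(),
                             config = preprocess_config(),
                             artifact_library = default_artifact_library()) {
  rd <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                     with.qualities = TRUE)
  seqs <- toupper(as.character(rd))
  quals <- as.character(S4Vectors::mcols(rd)$qualities)
  ids <- sub("\\s.*$", "", names(rd))
  df <- .parse_reads_vec(seqs, quals, ids, sheet, config)
  if (!is.null(artifact_library)) {
    df <- artifact_filter(df, artifact_library, config)
  }
  list(reads = df, summary = preprocess_summary(df, sheet))
}

#' Summarise a preprocessing run
#'
#' @param reads Parsed read data.frame.
#' @param sheet Sample sheet used.
#' @return List: `input`, `assigned` (named per-sample counts),
#'   `unassigned`, `artifact`.
#' @export
preprocess_summary <- function(reads, sheet = default_sample_sheet()) {
  assigned <- table(factor(reads$sample_id[reads$status == "assigned"],
                           levels = sheet$sample_id))
  list(input = nrow(reads),
       assigned = as.list(setNames(as.integer(assigned), names(assigned))),
       unassigned = sum(reads$status == "unassigned"),
       artifact = sum(reads$status == "artifact"))
}

#' Write demultiplexed per-sample FASTQ files
#'
#' @param reads Parsed read data.frame (assigned reads are written).
#' @param dir Output directory; one `<sample_id>.fastq` per sample.
#' @return Invisibly, the paths written.
#' @export
write_demux_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- reads[reads$status == "assigned" & !is.na(reads$insert) &
                  nzchar(reads$insert), , drop = FALSE]
  paths <- character(0)
  for (s in unique(keep$sample_id)) {
    sub <- keep[keep$sample_id == s, , drop = FALSE]
    x <- Biostrings::DNAStringSet(sub$insert)
    names(x) <- sub$read_id
    q <- sub$insert_qualities
    q[is.na(q)] <- strrep("I", nchar(sub$insert[is.na(q)]))
    path <- file.path(dir, paste0(s, ".fastq"))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(q))
    paths <- c(paths, path)
  }
  invisible(paths)
}
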