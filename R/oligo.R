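#' Template-switching oligonucleotide layout
#'
#' The nanoCAGE template-switching (TS) oligo is a constant 24-nt head used
#' for PCR and sequencing, a 6-nt sample barcode, an 8-nt unique molecular
#' identifier (UMI), and a TATA linker ending in the GGG tail that pairs with
#' cap-templated cytosines during template switching. The five chemistries
#' (R3 = 3 terminal RNA bases, D3 = all-DNA, L1/L2/L3 = 1-3 terminal locked
#' nucleic acid bases) share this sequence and differ only in the sugar
#' chemistry of the terminal G's, which the sequencer does not see.
#'
#' @param chemistry_label One of `"R3"`, `"D3"`, `"L1"`, `"L2"`, `"L3"`.
#' @return A `TSOligoSpec` list: `head`, `barcode_length`, `umi_length`,
#'   `linker` (the fixed `TATAGGG` motif), `chemistry_label`.
#' @export
ts_oligo_spec <- function(chemistry_label = "R3") {
  chemistry_label <- match.arg(chemistry_label, c("R3", "D3", "L1", "L2", "L3"))
  structure(list(
    head = "TAGTCGAACTGAAGGTCTCCAGCA",
    barcode_length = 6L,
    umi_length = 8L,
    linker = "TATAGGG",
    chemistry_label = chemistry_label
  ), class = "TSOligoSpec")
}

#' Default nanoCAGE sample sheet
#'
#' The fifteen published sample barcodes, three per chemistry, mapping each
#' barcode to a sample identifier (`<chemistry>_<replicate>`) and its
#' chemistry label.
#'
#' @return A data.frame with columns `barcode`, `sample_id`, `chemistry`.
#' @export
default_sample_sheet <- function() {
  bc <- list(
    R3 = c("CACTGA", "GCTCTC", "TCGCGT"),
    D3 = c("ATCGTG", "CACGAT", "GTATAC"),
    L1 = c("ACAGAT", "CTGACG", "GAGTGA"),
    L2 = c("AGTAGC", "GCTGCA", "TCGAGC"),
    L3 = c("ATCATA", "CGATGA", "TATAGC")
  )
  sheet <- data.frame(
    barcode = unlist(bc, use.names = FALSE),
    sample_id = unlist(lapply(names(bc), function(ch) paste0(ch, "_", 1:3)),
                       use.names = FALSE),
    chemistry = rep(names(bc), each = 3L),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with columns `barcode`, `sample_id`, `chemistry`.
#' @param barcode_length Expected barcode length (default 6).
#' @return The sheet, invisibly normalised (upper-case barcodes).
#' @export
validate_sample_sheet <- function(sheet, barcode_length = 6L) {
  stopifnot(is.data.frame(sheet),
            all(c("barcode", "sample_id", "chemistry") %in% names(sheet)))
  sheet$barcode <- toupper(sheet$barcode)
  if (anyDuplicated(sheet$barcode)) stop("sample sheet barcodes must be unique")
  if (anyDuplicated(sheet$sample_id)) stop("sample ids must be unique")
  if (!all(nchar(sheet$barcode) == barcode_length)) {
    stop("all barcodes must have length ", barcode_length)
  }
  sheet
}

#' Read a sample sheet from a headered TSV
#'
#' @param path TSV file with columns `barcode`, `sample_id`, `chemistry`.
#' @return Validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
}
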