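#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a FASTQ file (phred+33).
#' @param sample_id Optional sample label attached to every read.
#' @param mate Optional mate number (1 or 2). If `NA`, a trailing `/1` or
#'   `/2` on the read name is parsed instead.
#' @return A tibble with columns `read_id`, `mate`, `sequence`, `quality`,
#'   `sample_id`.
#' @export
read_fastq <- function(path, sample_id = NA_character_, mate = NA_integer_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  parsed_mate <- rep(as.integer(mate), length(ids))
  if (is.na(mate)) {
    suffix <- sub("^.*/([12])$", "\\1", ids)
    parsed_mate <- ifelse(grepl("/[12]$", ids), as.integer(suffix),
                          NA_integer_)
    ids <- sub("/[12]$", "", ids)
  }
  tibble(
    read_id = unname(ids),
    mate = unname(parsed_mate),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
    sample_id = sample_id)
}

#' Write a read tibble to a FASTQ file
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality` and
#'   optionally `mate` (appended to the name as `/1` or `/2`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  nm <- reads$read_id
  if ("mate" %in% names(reads) && !all(is.na(reads$mate))) {
    nm <- ifelse(is.na(reads$mate), nm, paste0(nm, "/", reads$mate))
  }
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, nm))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Quality pre-filter for reads
#'
#' Keeps a read iff its mean phred score exceeds `min_mean_phred` and its
#' fraction of ambiguous (non-ACGT) bases is at most `max_n_fraction`. This is
#' the package's stand-in for read QC trimming tools: adapter handling is out
#' of scope because the simulator emits adapter-free reads.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param min_mean_phred Strict lower cutoff on the mean phred score
#'   (default 20).
#' @param max_n_fraction Maximum tolerated fraction of N bases (default 0.10).
#' @return A list with `reads` (the kept tibble) and `report`, a one-row
#'   tibble counting input, kept, and dropped reads by reason. Reads failing
#'   both rules are counted under `dropped_low_quality`.
#' @export
quality_filter <- function(reads, min_mean_phred = 20, max_n_fraction = 0.10) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) {
    return(list(
      reads = reads,
      report = tibble(n_input = 0L, n_kept = 0L,
                      dropped_low_quality = 0L, dropped_poly_n = 0L)))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("sequence and quality lengths differ")
  }
  mean_q <- gm_mean_phred(reads$quality)
  frac_n <- gm_frac_n(reads$sequence)
  low_q <- mean_q <= min_mean_phred
  poly_n <- !low_q & frac_n > max_n_fraction
  keep <- !low_q & !poly_n
  list(
    reads = reads[keep, , drop = FALSE],
    report = tibble(
      n_input = nrow(reads),
      n_kept = sum(keep),
      dropped_low_quality = sum(low_q),
      dropped_poly_n = sum(poly_n)))
}

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with header
#' `sample_id  tissue  condition  replicate  fastq1  fastq2` describing the
#' one-grafted-plant/three-samples design: tissues HL (scion leaf), RR
#' (rootstock root) and RL (rootstock lateral-branch leaf) under conditions CK
#' and drought, three replicates each.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             replicate = readr::col_integer(),
                             .default = readr::col_character()))
  required <- c("sample_id", "tissue", "condition", "replicate",
                "fastq1", "fastq2")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    abort(paste0("sample sheet missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(sheet$tissue %not_in% tissues_all)) {
    abort("tissue must be one of HL, RR, RL")
  }
  if (any(sheet$condition %not_in% conditions_all)) {
    abort("condition must be CK or drought")
  }
  key <- paste(sheet$tissue, sheet$condition, sheet$replicate)
  if (anyDuplicated(key)) {
    abort("(tissue, condition, replicate) combinations must be unique")
  }
  as_tibble(sheet)
}
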