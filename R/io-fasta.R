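#' Read a FASTA file
#'
#' Reads chromosome sequences with Biostrings and returns them as an
#' uppercased named character vector (names are the first whitespace-delimited
#' token of each header).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA: ", conditionMessage(e))))
  if (length(x) == 0L) abort("malformed FASTA: no sequences found")
  nm <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  if (any(!nzchar(nm)) || anyDuplicated(nm)) {
    abort("malformed FASTA: empty or duplicated sequence names")
  }
  setNames(toupper(as.character(x)), nm)
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences, or a [genotype_reference()].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "genotype_reference")) x <- x$sequences
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene`, `mRNA`/`transcript` and `exon` features with rtracklayer
#' and collapses them to one model per gene. `exon_length` is the summed exon
#' span of the gene's longest transcript; a gene without annotated exons gets
#' its full span.
#'
#' @param path Path to a GFF3 file.
#' @param reference Optional [genotype_reference()] (or named character vector
#'   of sequences) used to validate that every feature lies within its
#'   chromosome.
#' @return A tibble of gene models (see [genotype_reference()]).
#' @export
read_gff3 <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  if (!"Parent" %in% names(df)) {
    df$Parent <- replicate(nrow(df), character(0), simplify = FALSE)
  }
  df$parent1 <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))

  genes <- filter(df, .data$type == "gene")
  if (nrow(genes) == 0L) abort("GFF3 contains no gene features")
  tx <- filter(df, .data$type %in% c("mRNA", "transcript"))
  exons <- filter(df, .data$type == "exon")

  # exon -> transcript -> gene; exons parented directly on a gene form an
  # implicit single transcript
  tx_gene <- setNames(tx$parent1, tx$ID)
  exons$tx_id <- ifelse(exons$parent1 %in% names(tx_gene), exons$parent1,
                        paste0(".direct.", exons$parent1))
  exons$gene_id <- ifelse(exons$parent1 %in% names(tx_gene),
                          unname(tx_gene[exons$parent1]), exons$parent1)

  if (!is.null(reference)) {
    seqs <- if (inherits(reference, "genotype_reference")) {
      reference$sequences
    } else {
      reference
    }
    feats <- bind_rows(
      tibble(id = genes$ID, chrom = genes$seqnames, end = genes$end),
      tibble(id = exons$ID %||% NA_character_, chrom = exons$seqnames,
             end = exons$end))
    missing_chrom <- feats$chrom %not_in% names(seqs)
    if (any(missing_chrom)) {
      abort(paste0("feature on chromosome absent from reference: ",
                   paste(unique(feats$id[missing_chrom]), collapse = ", ")))
    }
    beyond <- feats$end > nchar(seqs)[feats$chrom]
    if (any(beyond)) {
      abort(paste0("feature outside chromosome bounds: ",
                   paste(unique(feats$id[beyond]), collapse = ", ")))
    }
  }

  exlen <- exons |>
    group_by(.data$gene_id, .data$tx_id) |>
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(exon_length = max(.data$len), .groups = "drop")

  out <- tibble(
    gene_id = genes$ID,
    chromosome = genes$seqnames,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "+")) |>
    left_join(exlen, by = "gene_id") |>
    mutate(exon_length = as.integer(
      ifelse(is.na(.data$exon_length), .data$end - .data$start + 1L,
             .data$exon_length))) |>
    arrange(.data$chromosome, .data$start)
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA and exon rows (one exon spanning the gene body, matching
#' the intronless models this pipeline uses).
#'
#' @param x A [genotype_reference()] or a gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  genes <- if (inherits(x, "genotype_reference")) x$genes else as_tibble(x)
  mk <- function(type, id, parent) {
    GenomicRanges::GRanges(
      seqnames = genes$chromosome,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand,
      type = type, ID = id,
      Parent = if (is.null(parent)) NA_character_ else parent)
  }
  # parents before children: all genes, then mRNAs, then exons
  gr <- c(mk("gene", genes$gene_id, NULL),
          mk("mRNA", paste0(genes$gene_id, ".1"), genes$gene_id),
          mk("exon", paste0(genes$gene_id, ".1.exon1"),
             paste0(genes$gene_id, ".1")))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
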