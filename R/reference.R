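#' Genotype reference (genome plus gene models)
#'
#' Container for one graft partner's genome: a set of chromosome sequences and
#' a table of gene models. Coordinates in the gene table are 1-based inclusive
#' (the GFF3 convention); internal alignment code converts to 0-based
#' half-open at the boundary.
#'
#' @param genotype_id Single non-empty label, e.g. `"SCI"` for the scion
#'   genotype.
#' @param sequences Named character vector of chromosome sequences
#'   (A/C/G/T/N). Stored uppercased.
#' @param genes Data frame of gene models with columns `gene_id`,
#'   `chromosome`, `start`, `end`, `strand` and `exon_length` (summed exon
#'   span of the longest transcript, the length used for TPM).
#'
#' @return An object of class `genotype_reference`.
#' @export
genotype_reference <- function(genotype_id, sequences, genes) {
  if (!is.character(genotype_id) || length(genotype_id) != 1L ||
      is.na(genotype_id) || !nzchar(genotype_id)) {
    abort("`genotype_id` must be a single non-empty string")
  }
  if (!is.character(sequences) || is.null(names(sequences)) ||
      anyDuplicated(names(sequences))) {
    abort("`sequences` must be a named character vector with unique names")
  }
  sequences <- toupper(sequences)
  genes <- as_tibble(genes)
  required <- c("gene_id", "chromosome", "start", "end", "strand",
                "exon_length")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    abort(paste0("`genes` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("gene ids must be unique within a genotype")
  }
  if (any(genes$start > genes$end)) {
    abort("gene start must be <= end")
  }
  if (any(genes$exon_length < 1)) {
    abort("exon_length must be >= 1")
  }
  bad_chrom <- setdiff(unique(genes$chromosome), names(sequences))
  if (length(bad_chrom)) {
    abort(paste0("genes reference unknown chromosomes: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  chrom_len <- nchar(sequences)[genes$chromosome]
  outside <- genes$start < 1L | genes$end > chrom_len
  if (any(outside)) {
    abort(paste0("gene interval outside chromosome bounds: ",
                 paste(genes$gene_id[outside], collapse = ", ")))
  }
  genes <- arrange(genes, .data$chromosome, .data$start)
  structure(
    list(genotype_id = genotype_id, sequences = sequences, genes = genes),
    class = "genotype_reference")
}

#' @export
print.genotype_reference <- function(x, ...) {
  cat(sprintf(
    "<genotype_reference> %s: %d chromosome(s), %s nt, %d gene(s)\n",
    x$genotype_id, length(x$sequences),
    format(sum(nchar(x$sequences)), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' Extract transcript (gene-body) sequences from a reference
#'
#' Returns the spliced transcript of each gene. Gene models here are
#' single-exon (the simulator emits intronless genes and mapping is
#' transcriptome-level), so the transcript is the gene span, reverse
#' complemented for minus-strand genes.
#'
#' @param reference A [genotype_reference()].
#' @return A tibble with columns `gene_id`, `sequence`, `length`.
#' @export
gene_transcripts <- function(reference) {
  stopifnot(inherits(reference, "genotype_reference"))
  g <- reference$genes
  seqs <- substr(reference$sequences[g$chromosome], g$start, g$end)
  minus <- g$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  tibble(gene_id = g$gene_id, sequence = unname(seqs),
         length = nchar(seqs))
}
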