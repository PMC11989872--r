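#' Count reads per gene from alignment hits
#'
#' Best-hit counting: each hit increments exactly the gene it was assigned to
#' by overlap; hits overlapping no gene go to the unassigned bucket.
#'
#' @param hits Hits tibble from [align_reads()] (must carry `gene_id`).
#' @param genes Gene-model tibble; output is completed with zero counts for
#'   genes without hits.
#' @return A tibble `gene_id`, `count` (all genes, coordinate order), with
#'   attribute `n_unassigned` holding the number of gene-less hits.
#' @export
count_reads_per_gene <- function(hits, genes) {
  genes <- as_tibble(genes)
  assigned <- hits$gene_id[!is.na(hits$gene_id)]
  tab <- table(factor(assigned, levels = genes$gene_id))
  out <- tibble(gene_id = genes$gene_id, count = as.integer(tab))
  attr(out, "n_unassigned") <- sum(is.na(hits$gene_id))
  out
}

#' Transcripts per million
#'
#' `TPM_g = (c_g / L_g[kb]) / sum_h(c_h / L_h[kb]) * 1e6`. An all-zero count
#' vector yields all zeros (no division error).
#'
#' @param counts Non-negative numeric vector of raw counts.
#' @param lengths Positive numeric vector of gene lengths in nt
#'   (`exon_length`), recycled against `counts`.
#' @return Numeric vector of TPM values summing to 1e6 (or all zero).
#' @export
tpm <- function(counts, lengths) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(lengths < 1)) abort("lengths must be >= 1")
  rate <- counts / (lengths / 1000)
  total <- sum(rate)
  if (total == 0) return(rep(0, length(rate)))
  rate / total * 1e6
}

#' Bin source-tissue abundance and overlay mobility
#'
#' Six abundance classes on the TPM scale: (0,1], (1,10], (10,100],
#' (100,500], (500,1000] and (1000, Inf). Only genes with positive TPM are
#' binned (the bins partition the positive axis).
#'
#' @param source_tpm Tibble with columns `gene_id`, `tpm`, or a named
#'   numeric vector.
#' @param mobile_ids Character vector of genes called mobile.
#' @return A tibble `bin`, `n_genes`, `n_mobile`, `mobile_fraction` of class
#'   `abundance_bins`.
#' @export
bin_abundance <- function(source_tpm, mobile_ids) {
  if (is.numeric(source_tpm)) {
    source_tpm <- tibble(gene_id = names(source_tpm),
                         tpm = unname(source_tpm))
  }
  source_tpm <- as_tibble(source_tpm)
  edges <- c(0, 1, 10, 100, 500, 1000, Inf)
  labels <- c("(0,1]", "(1,10]", "(10,100]", "(100,500]", "(500,1000]",
              ">1000")
  pos <- filter(source_tpm, .data$tpm > 0)
  bin <- cut(pos$tpm, breaks = edges, labels = labels, right = TRUE)
  out <- tibble(bin = factor(labels, levels = labels)) |>
    left_join(
      tibble(bin = bin, mobile = pos$gene_id %in% mobile_ids) |>
        group_by(.data$bin) |>
        summarise(n_genes = dplyr::n(), n_mobile = sum(.data$mobile),
                  .groups = "drop"),
      by = "bin") |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes),
           n_mobile = ifelse(is.na(.data$n_mobile), 0L, .data$n_mobile),
           mobile_fraction = ifelse(.data$n_genes > 0,
                                    .data$n_mobile / .data$n_genes, NA_real_))
  class(out) <- c("abundance_bins", class(out))
  out
}

#' Per-base read coverage over a gene
#'
#' Depth at each position of the gene body: the number of hits whose aligned
#' interval covers it (hit intervals are clipped to the gene span).
#'
#' @param hits Hits tibble from [align_reads()] on the gene's reference.
#' @param gene One-row gene-model tibble (or list) with `gene_id`,
#'   `chromosome`, `start`, `end`.
#' @return A tibble `pos` (1-based), `depth` of class `coverage_track`, with
#'   attributes `gene_id` and `chromosome`.
#' @export
coverage_track <- function(hits, gene) {
  gene <- as.list(gene)
  span <- gene$start:gene$end
  depth <- integer(length(span))
  h <- hits[hits$chromosome == gene$chromosome, , drop = FALSE]
  if (nrow(h)) {
    hs <- pmax(h$start + 1L, gene$start)
    he <- pmin(h$start + h$width, gene$end)
    ok <- hs <= he
    if (any(ok)) {
      delta <- integer(length(span) + 1L)
      ii <- hs[ok] - gene$start + 1L
      jj <- he[ok] - gene$start + 2L
      for (x in seq_along(ii)) {
        delta[ii[x]] <- delta[ii[x]] + 1L
        delta[jj[x]] <- delta[jj[x]] - 1L
      }
      depth <- cumsum(delta[-length(delta)])
    }
  }
  out <- tibble(pos = span, depth = as.integer(depth))
  attr(out, "gene_id") <- gene$gene_id
  attr(out, "chromosome") <- gene$chromosome
  class(out) <- c("coverage_track", class(out))
  out
}

#' Export a coverage track as bedGraph
#'
#' Intervals are 0-based half-open, depth-constant and non-overlapping;
#' adjacent positions with equal depth are merged.
#'
#' @param track A [coverage_track()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chrom <- attr(track, "chromosome") %||% "chr"
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  off <- track$pos[1] - 1L
  lines <- sprintf("%s\t%d\t%d\t%d", chrom, off + starts, off + ends,
                   r$values)
  writeLines(lines, path)
  invisible(path)
}
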