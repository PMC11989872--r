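#' Draw a tissue expression profile
#'
#' Log-normal abundances on the TPM scale, normalised to sum to 1e6. Each
#' gene has a baseline log-abundance shared across tissues and conditions
#' (drawn by gene index, so homologous genes of the two genotypes get
#' correlated baselines), plus a tissue-by-condition deviation. The profile
#' is deterministic for a given `(seed, condition, tissue)`.
#'
#' @param genes Gene-model tibble (only the number and order of rows is
#'   used).
#' @param condition Condition label (e.g. `"CK"` or `"drought"`).
#' @param tissue Tissue label (e.g. `"HL"`).
#' @param seed Master integer seed.
#' @param baseline_sdlog Standard deviation of the per-gene baseline on the
#'   log scale.
#' @param tissue_sdlog Standard deviation of the tissue/condition deviation
#'   on the log scale.
#' @return A tibble with columns `gene_id` and `tpm` (sums to 1e6).
#' @export
sample_expression <- function(genes, condition, tissue, seed = 1L,
                              baseline_sdlog = 1.5, tissue_sdlog = 0.4) {
  genes <- as_tibble(genes)
  n <- nrow(genes)
  if (n == 0L) abort("`genes` has no rows")
  base <- with_seed(sub_seed(seed, "expr-baseline"),
                    rnorm(n, 0, baseline_sdlog))
  dev <- with_seed(sub_seed(seed, paste("expr", condition, tissue)),
                   rnorm(n, 0, tissue_sdlog))
  w <- exp(base + dev)
  tibble(gene_id = genes$gene_id, tpm = w / sum(w) * 1e6)
}
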