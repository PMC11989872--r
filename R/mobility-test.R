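#' Permutation test of mobility against source abundance
#'
#' Tests whether mobile genes differ in source-tissue abundance from
#' non-mobile genes. The statistic is the Wilcoxon rank-sum of the mobile
#' group's TPM ranks; its null distribution is generated by permuting the
#' mobile labels, and the two-sided p-value counts permutations at least as
#' far from the null mean as the observed statistic. Also reports the overlap
#' between the mobile set and the `top_k` most abundant genes (the
#' field's customary top-100 comparison).
#'
#' @param source_tpm Tibble `gene_id`, `tpm` (or named numeric vector) of
#'   source-tissue abundance for all genes of the source genotype.
#' @param mobile_ids Genes called mobile.
#' @param n_permutations Number of label permutations (>= 1000 recommended).
#' @param seed Integer seed for the permutation stream.
#' @param top_k Size of the most-abundant set for the overlap count.
#' @return An object of class `mobility_test`; see [tidy()]/[glance()]
#'   methods. If fewer than 2 mobile (or 2 non-mobile) genes are present the
#'   test is skipped and flagged.
#' @export
mobility_abundance_test <- function(source_tpm, mobile_ids,
                                    n_permutations = 1000L, seed = 1L,
                                    top_k = 100L) {
  if (is.numeric(source_tpm)) {
    source_tpm <- tibble(gene_id = names(source_tpm),
                         tpm = unname(source_tpm))
  }
  source_tpm <- as_tibble(source_tpm)
  n <- nrow(source_tpm)
  is_mobile <- source_tpm$gene_id %in% mobile_ids
  m <- sum(is_mobile)

  top_ids <- source_tpm$gene_id[order(-source_tpm$tpm)][
    seq_len(min(top_k, n))]
  overlap <- length(intersect(top_ids, mobile_ids))

  out <- list(
    n_genes = n, n_mobile = m, top_k = top_k, top_k_overlap = overlap,
    n_permutations = as.integer(n_permutations), seed = seed)
  if (m < 2L || n - m < 2L) {
    out$skipped <- TRUE
    out$reason <- sprintf(
      "need >= 2 mobile and >= 2 non-mobile genes (have %d and %d)",
      m, n - m)
    out$statistic <- NA_real_
    out$p_value <- NA_real_
    class(out) <- "mobility_test"
    return(out)
  }

  rk <- rank(source_tpm$tpm)
  obs <- sum(rk[is_mobile])
  mu <- m * (n + 1) / 2
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
    sum(rk[sample.int(n, m)]), numeric(1)))
  p <- (1 + sum(abs(perm - mu) >= abs(obs - mu))) / (n_permutations + 1)

  out$skipped <- FALSE
  out$reason <- NA_character_
  out$statistic <- obs
  out$expected <- mu
  out$p_value <- p
  out$permutations <- perm
  class(out) <- "mobility_test"
  out
}

#' @export
print.mobility_test <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<mobility_test> skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<mobility_test> rank-sum %.1f (null mean %.1f), permutation ",
    "p = %.4g (%d permutations); top-%d overlap %d of %d mobile genes\n"),
    x$statistic, x$expected, x$p_value, x$n_permutations, x$top_k,
    x$top_k_overlap, x$n_mobile))
  invisible(x)
}

#' @rdname mobility_abundance_test
#' @param x A `mobility_test` object.
#' @param ... Unused.
#' @method tidy mobility_test
#' @export
tidy.mobility_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    null_mean = x$expected %||% NA_real_,
    p_value = x$p_value,
    n_genes = x$n_genes,
    n_mobile = x$n_mobile,
    top_k = x$top_k,
    top_k_overlap = x$top_k_overlap,
    skipped = isTRUE(x$skipped))
}

#' @rdname mobility_abundance_test
#' @method glance mobility_test
#' @export
glance.mobility_test <- function(x, ...) tidy.mobility_test(x)
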