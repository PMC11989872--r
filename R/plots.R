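#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_vline
#'   geom_step labs theme_minimal
NULL

#' Plot a transport-pattern summary
#'
#' Bar chart of the three downward transport classes.
#'
#' @param object A `transport_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transport_summary
#' @export
autoplot.transport_summary <- function(object, ...) {
  df <- tidy.transport_summary(object)
  df$pattern <- factor(df$pattern,
                       levels = c("rl_direct", "through_root",
                                  "rr_only_degraded"),
                       labels = c("RL direct", "RR and RL (through root)",
                                  "RR only (degraded)"))
  ggplot(df, aes(x = .data$pattern, y = .data$n_genes)) +
    geom_col(fill = "#4C72B0") +
    labs(x = NULL, y = "downward mobile genes",
         title = sprintf("Transport patterns (%d downward genes)",
                         object$total_down)) +
    theme_minimal()
}

#' Plot abundance-class mobility fractions
#'
#' @param object An `abundance_bins` tibble from [bin_abundance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abundance_bins
#' @export
autoplot.abundance_bins <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$mobile_fraction)) +
    geom_col(fill = "#55A868") +
    labs(x = "source abundance class (TPM)",
         y = "fraction of genes called mobile",
         title = "Mobility by source-abundance class") +
    theme_minimal()
}

#' Plot the permutation null of a mobility test
#'
#' Histogram of permuted rank-sum statistics with the observed value marked.
#'
#' @param object A `mobility_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mobility_test
#' @export
autoplot.mobility_test <- function(object, ...) {
  if (isTRUE(object$skipped)) {
    abort(paste0("test was skipped: ", object$reason))
  }
  df <- tibble(statistic = object$permutations)
  ggplot(df, aes(x = .data$statistic)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$statistic, colour = "#C44E52",
               linewidth = 1) +
    labs(x = "permuted rank-sum", y = "permutations",
         title = sprintf("Abundance vs mobility: p = %.3g",
                         object$p_value)) +
    theme_minimal()
}

#' Plot a coverage track
#'
#' @param object A `coverage_track` from [coverage_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, ...) {
  ggplot(object, aes(x = .data$pos, y = .data$depth)) +
    geom_step(colour = "#4C72B0") +
    labs(x = sprintf("%s position (nt)",
                     attr(object, "chromosome") %||% "reference"),
         y = "read depth",
         title = attr(object, "gene_id") %||% "coverage") +
    theme_minimal()
}
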