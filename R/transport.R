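#' Classify downward mobile genes into transport patterns
#'
#' Partitions the downward mobile genes along the transport model scion (HL)
#' -> rootstock root (RR) -> rootstock leaf (RL):
#' \describe{
#'   \item{through_root}{detected in both RR and RL (moved through the
#'     root to the distal leaf);}
#'   \item{rl_direct}{detected in RL only (reached the lateral leaf without
#'     detectable passage through the root);}
#'   \item{rr_only_degraded}{detected in RR but not RL (inferred degraded or
#'     diluted below detection in transit).}
#' }
#' The three classes partition the union of the RR and RL call sets; the
#' inference is purely set-theoretic (no decay kinetics are fitted).
#'
#' @param calls Mobile-call tibble (see [call_mobile_genes()]); conditions
#'   may be mixed, in which case the summary pools them and records which
#'   conditions contributed.
#' @return An object of class `transport_summary`: counts plus the gene-id
#'   sets.
#' @export
classify_transport <- function(calls) {
  calls <- as_tibble(calls)
  bad <- calls$direction == "down" & calls$tissue == "HL"
  if (any(bad)) {
    abort("invalid call: direction 'down' in tissue HL")
  }
  if (any(calls$direction == "up" & calls$tissue != "HL")) {
    abort("invalid call: direction 'up' outside tissue HL")
  }
  down <- filter(calls, .data$direction == "down")
  rr_set <- sort(unique(down$gene_id[down$tissue == "RR"]))
  rl_set <- sort(unique(down$gene_id[down$tissue == "RL"]))
  through <- intersect(rr_set, rl_set)
  rl_direct <- setdiff(rl_set, rr_set)
  rr_only <- setdiff(rr_set, rl_set)
  up_set <- sort(unique(calls$gene_id[calls$direction == "up"]))
  conds <- sort(unique(calls$condition))

  structure(list(
    total_down = length(union(rr_set, rl_set)),
    total_up = length(up_set),
    n_rr = length(rr_set), n_rl = length(rl_set),
    n_through_root = length(through),
    n_rl_direct = length(rl_direct),
    n_rr_only_degraded = length(rr_only),
    rr_set = rr_set, rl_set = rl_set,
    through_root = sort(through),
    rl_direct = sort(rl_direct),
    rr_only_degraded = sort(rr_only),
    up_set = up_set,
    conditions = conds), class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<transport_summary> %d downward mobile gene(s) ",
    "(RR %d, RL %d): through-root %d, RL-direct %d, ",
    "RR-only (degraded in transit) %d; upward %d [conditions: %s]\n"),
    x$total_down, x$n_rr, x$n_rl, x$n_through_root, x$n_rl_direct,
    x$n_rr_only_degraded, x$total_up,
    paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' @rdname classify_transport
#' @param x A `transport_summary` object.
#' @param ... Unused.
#' @method tidy transport_summary
#' @export
tidy.transport_summary <- function(x, ...) {
  tibble(
    pattern = c("through_root", "rl_direct", "rr_only_degraded"),
    n_genes = c(x$n_through_root, x$n_rl_direct, x$n_rr_only_degraded),
    genes = list(x$through_root, x$rl_direct, x$rr_only_degraded))
}

#' @rdname classify_transport
#' @method glance transport_summary
#' @export
glance.transport_summary <- function(x, ...) {
  tibble(
    total_down = x$total_down, total_up = x$total_up,
    n_rr = x$n_rr, n_rl = x$n_rl,
    n_through_root = x$n_through_root,
    n_rl_direct = x$n_rl_direct,
    n_rr_only_degraded = x$n_rr_only_degraded)
}

#' Condition-specific call sets (CK vs drought)
#'
#' Three-way partition of the union of two call sets from the same tissue and
#' direction: genes called under CK only, drought only, or both. Swapping the
#' arguments swaps the two specific cells.
#'
#' @param calls_ck,calls_drought Mobile-call tibbles for one tissue and
#'   direction under the two conditions.
#' @return A one-row tibble with counts `ck_only`, `drought_only`, `both`
#'   and matching gene-id list columns.
#' @export
condition_specific_sets <- function(calls_ck, calls_drought) {
  calls_ck <- as_tibble(calls_ck)
  calls_drought <- as_tibble(calls_drought)
  td <- unique(c(paste(calls_ck$tissue, calls_ck$direction),
                 paste(calls_drought$tissue, calls_drought$direction)))
  if (length(td) > 1L) {
    abort("calls must come from a single tissue and direction")
  }
  a <- unique(calls_ck$gene_id)
  b <- unique(calls_drought$gene_id)
  tibble(
    tissue = if (length(td)) strsplit(td, " ")[[1]][1] else NA_character_,
    direction = if (length(td)) strsplit(td, " ")[[1]][2] else NA_character_,
    ck_only = length(setdiff(a, b)),
    drought_only = length(setdiff(b, a)),
    both = length(intersect(a, b)),
    ck_only_genes = list(sort(setdiff(a, b))),
    drought_only_genes = list(sort(setdiff(b, a))),
    both_genes = list(sort(intersect(a, b))))
}
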