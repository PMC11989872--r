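#' Parameters of the mobile-mRNA calling pipeline
#'
#' @param k_first Edit-distance cap for the native first-pass mapping
#'   (default 2).
#' @param k_second Edit-distance cap for the foreign second-pass mapping
#'   (default 1). Must not exceed `k_first`.
#' @param min_reads_per_gene Retained reads required to support a gene within
#'   one replicate (default 2, suppressing singleton artefacts).
#' @param min_replicates Replicates (out of `n_replicates`) in which a gene
#'   must be supported (default 2 of 3).
#' @param source_expressed_min_count Raw-count threshold for "expressed in
#'   the source tissue" (default 5).
#' @param source_expressed_min_replicates Source replicates that must reach
#'   the count threshold (default 2).
#' @param min_aligned_fraction,min_identity Cross-check hit criterion (see
#'   [local_search()]).
#' @param index_k Seed length of the bounded-edit-distance aligner index.
#' @param local_k Seed length of the local-search index.
#' @param min_mean_phred,max_n_fraction Read QC thresholds (see
#'   [quality_filter()]).
#' @return A validated `pipeline_params` list.
#' @export
pipeline_params <- function(k_first = 2L, k_second = 1L,
                            min_reads_per_gene = 2L, min_replicates = 2L,
                            source_expressed_min_count = 5L,
                            source_expressed_min_replicates = 2L,
                            min_aligned_fraction = 0.9,
                            min_identity = 97.5,
                            index_k = 21L, local_k = 11L,
                            min_mean_phred = 20, max_n_fraction = 0.10) {
  p <- as.list(environment())
  if (p$k_second > p$k_first) abort("k_second must be <= k_first")
  if (p$k_first < 0L) abort("k_first must be >= 0")
  if (p$min_reads_per_gene < 1L) abort("min_reads_per_gene must be >= 1")
  if (p$min_replicates < 1L) abort("min_replicates must be >= 1")
  structure(p, class = "pipeline_params")
}

# Indexes used repeatedly across the samples of one experiment.
build_pipeline_indexes <- function(scion, rootstock, params) {
  list(
    SCI = list(map = build_index(scion, params$index_k),
               local = build_index(scion, params$local_k)),
    ROO = list(map = build_index(rootstock, params$index_k),
               local = build_index(rootstock, params$local_k)))
}

#' Classify one sample's reads by genome of origin
#'
#' Implements the per-sample stage of the mobile-mRNA pipeline:
#' \enumerate{
#'   \item map reads to the native reference at edit distance `k_first`;
#'   \item cross-check each unmapped read against both references by local
#'     alignment: a hit to the foreign reference only makes the read a
#'     candidate mobile read (set A for upward, A' for downward); any hit to
#'     the native reference makes it a false positive (B/B'); no hit
#'     discards it;
#'   \item re-map candidate reads to the foreign reference at the stricter
#'     `k_second`; reads that map are retained (C/C') and accumulated into
#'     per-gene support counts (toward D/D').
#' }
#' For scion leaf tissue (HL) the foreign reference is the rootstock genotype
#' (upward direction); for rootstock tissues (RR, RL) it is the scion
#' genotype (downward direction).
#'
#' @param reads QC-filtered read tibble for one sample.
#' @param native_ref,foreign_ref [genotype_reference()] objects.
#' @param params A [pipeline_params()] object.
#' @param tissue Tissue of the sample (`"HL"`, `"RR"` or `"RL"`).
#' @param condition,replicate Sample annotations carried through to calling.
#' @param indexes Optional prebuilt index set from the internal index cache;
#'   when `NULL`, indexes are built on the fly.
#' @return An object of class `classified_reads` with counts and read-id
#'   sets for every stage, native per-gene counts, and the per-gene support
#'   table of retained foreign reads.
#' @export
classify_sample_reads <- function(reads, native_ref, foreign_ref,
                                  params = pipeline_params(),
                                  tissue, condition = NA_character_,
                                  replicate = NA_integer_,
                                  indexes = NULL) {
  if (!tissue %in% tissues_all) {
    abort(paste0("unknown tissue: ", tissue))
  }
  direction <- if (tissue == "HL") "up" else "down"
  reads <- as_tibble(reads)
  sample_id <- if (nrow(reads) && "sample_id" %in% names(reads)) {
    reads$sample_id[1]
  } else {
    NA_character_
  }

  if (is.null(indexes)) {
    indexes <- list(
      native = list(map = build_index(native_ref, params$index_k),
                    local = build_index(native_ref, params$local_k)),
      foreign = list(map = build_index(foreign_ref, params$index_k),
                     local = build_index(foreign_ref, params$local_k)))
  }

  first <- align_reads(reads, indexes$native$map, native_ref,
                       params$k_first)
  native_counts <- count_reads_per_gene(first$hits, native_ref$genes)

  unmapped_ids <- first$unmapped
  key <- read_keys(reads)
  un <- reads[match(unmapped_ids, key), , drop = FALSE]
  un$read_id <- unmapped_ids

  if (nrow(un)) {
    cross <- local_search(un, native_ref, foreign_ref,
                          params$min_aligned_fraction, params$min_identity,
                          params$local_k,
                          index_a = indexes$native$local,
                          index_b = indexes$foreign$local)
    false_positive <- cross$read_id[cross$hit_a]
    candidate <- cross$read_id[!cross$hit_a & cross$hit_b]
    discarded <- cross$read_id[!cross$hit_a & !cross$hit_b]
  } else {
    false_positive <- candidate <- discarded <- character(0)
  }

  cand_reads <- un[un$read_id %in% candidate, , drop = FALSE]
  second <- align_reads(cand_reads, indexes$foreign$map, foreign_ref,
                        params$k_second)
  retained <- second$hits
  gene_support <- retained |>
    filter(!is.na(.data$gene_id)) |>
    count(.data$gene_id, name = "reads") |>
    arrange(.data$gene_id)

  structure(list(
    sample_id = sample_id,
    tissue = tissue, condition = condition, replicate = replicate,
    direction = direction,
    foreign_genotype = foreign_ref$genotype_id,
    n_input = nrow(reads),
    n_mapped_native = nrow(first$hits),
    native_gene_counts = native_counts,
    unmapped = unmapped_ids,
    candidate_mobile = candidate,
    false_positive = false_positive,
    n_discarded = length(discarded),
    retained = retained,
    gene_support = gene_support), class = "classified_reads")
}

#' @export
print.classified_reads <- function(x, ...) {
  cat(sprintf(paste0(
    "<classified_reads> %s (%s, %s, rep %s): %d reads; mapped %d, ",
    "unmapped %d (A %d, B %d, discarded %d), retained C %d, ",
    "%d supported gene(s)\n"),
    x$sample_id, x$tissue, x$condition, x$replicate, x$n_input,
    x$n_mapped_native, length(x$unmapped), length(x$candidate_mobile),
    length(x$false_positive), x$n_discarded, nrow(x$retained),
    nrow(x$gene_support)))
  invisible(x)
}

#' Call mobile genes from replicate classifications
#'
#' A gene is called mobile in a tissue-by-condition group iff (a) it is
#' supported by at least `min_reads_per_gene` retained foreign reads in at
#' least `min_replicates` replicates, and (b) it is expressed in the source
#' tissue (the D minus E exclusion): raw count at least
#' `source_expressed_min_count` in at least
#' `source_expressed_min_replicates` source replicates in some source tissue.
#'
#' @param replicate_sets List of [classify_sample_reads()] results sharing
#'   tissue and condition (one per replicate).
#' @param source_counts Tibble of raw counts in the source tissue(s) of the
#'   same condition: columns `gene_id`, `tissue`, `replicate`, `count`. For
#'   downward calls the source is the scion leaf (HL); for upward calls, the
#'   rootstock tissues (RR, RL).
#' @param params A [pipeline_params()] object.
#' @return A tibble of mobile calls: `gene_id`, `genotype`, `direction`,
#'   `tissue`, `condition`, `replicate_support` and per-replicate read counts
#'   `reads_r1`, `reads_r2`, ...
#' @export
call_mobile_genes <- function(replicate_sets, source_counts,
                              params = pipeline_params()) {
  stopifnot(length(replicate_sets) >= 1L)
  if (is.null(source_counts)) abort("`source_counts` is required")
  tiss <- unique(vapply(replicate_sets, `[[`, character(1), "tissue"))
  cond <- unique(vapply(replicate_sets, function(x)
    as.character(x$condition), character(1)))
  if (length(tiss) != 1L || length(cond) != 1L) {
    abort("replicate sets must share tissue and condition")
  }
  direction <- replicate_sets[[1]]$direction
  genotype <- replicate_sets[[1]]$foreign_genotype
  n_rep <- length(replicate_sets)

  support <- bind_rows(lapply(seq_len(n_rep), function(i) {
    gs <- replicate_sets[[i]]$gene_support
    if (nrow(gs) == 0L) return(NULL)
    mutate(gs, replicate = i)
  }))
  empty <- tibble(
    gene_id = character(0), genotype = character(0),
    direction = character(0), tissue = character(0),
    condition = character(0), replicate_support = integer(0))
  for (i in seq_len(n_rep)) empty[[paste0("reads_r", i)]] <- integer(0)
  if (nrow(support) == 0L) return(empty)

  wide <- support |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "reads",
                       names_prefix = "reads_r", values_fill = 0L)
  for (i in seq_len(n_rep)) {
    nm <- paste0("reads_r", i)
    if (!nm %in% names(wide)) wide[[nm]] <- 0L
  }
  read_cols <- paste0("reads_r", seq_len(n_rep))
  wide <- wide[, c("gene_id", read_cols)]
  supp_mat <- as.matrix(wide[, read_cols])
  wide$replicate_support <- as.integer(
    rowSums(supp_mat >= params$min_reads_per_gene))

  src <- as_tibble(source_counts)
  if (!all(c("gene_id", "replicate", "count") %in% names(src))) {
    abort("`source_counts` needs columns gene_id, replicate, count")
  }
  if (!"tissue" %in% names(src)) src$tissue <- "source"
  expressed <- src |>
    group_by(.data$gene_id, .data$tissue) |>
    summarise(n_ok = sum(.data$count >= params$source_expressed_min_count),
              .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(expressed = any(
      .data$n_ok >= params$source_expressed_min_replicates),
      .groups = "drop")

  out <- wide |>
    filter(.data$replicate_support >= params$min_replicates) |>
    left_join(expressed, by = "gene_id") |>
    filter(!is.na(.data$expressed) & .data$expressed) |>
    mutate(genotype = genotype, direction = direction, tissue = tiss,
           condition = cond) |>
    select("gene_id", "genotype", "direction", "tissue", "condition",
           "replicate_support", dplyr::all_of(read_cols)) |>
    arrange(.data$gene_id)
  out
}
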