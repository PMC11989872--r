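#' Run the full mobile-mRNA pipeline on a dataset
#'
#' Processes every sample of the sheet one at a time (QC, native first-pass
#' mapping, cross-check, foreign second-pass mapping), assembles gene-level
#' expression (counts and TPM), and calls mobile genes per tissue-by-condition
#' group with the replicate-consensus and source-expression rules. Downward
#' calls (RR, RL) use the scion leaf (HL) of the same condition as source;
#' upward calls (HL) use the rootstock tissues (RR and RL).
#'
#' @param dataset A `graft_dataset` from [generate_dataset()], or a list with
#'   elements `scion`, `rootstock` ([genotype_reference()]s) and
#'   `sample_sheet`; reads are then loaded from the FASTQ paths in the sheet
#'   (resolved against `fastq_dir`).
#' @param params A [pipeline_params()] object.
#' @param fastq_dir Directory for the sheet's FASTQ paths when reads come
#'   from disk.
#' @param quiet Suppress per-sample progress messages.
#' @return An object of class `graft_run` with elements `calls`,
#'   `read_set_summary`, `expression`, `transport` (pooled conditions),
#'   `transport_by_condition`, `condition_venn`, `params`, and `ground_truth`
#'   when the dataset carries one.
#' @export
run_experiment <- function(dataset, params = pipeline_params(),
                           fastq_dir = NULL, quiet = TRUE) {
  scion <- dataset$scion
  rootstock <- dataset$rootstock
  sheet <- as_tibble(dataset$sample_sheet)
  simulated <- inherits(dataset, "graft_dataset")
  refs <- list(SCI = scion, ROO = rootstock)
  idx <- build_pipeline_indexes(scion, rootstock, params)

  classified <- vector("list", nrow(sheet))
  names(classified) <- sheet$sample_id
  expr_rows <- vector("list", nrow(sheet))
  qc_rows <- vector("list", nrow(sheet))

  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    if (!quiet) message("classifying ", row$sample_id)
    reads <- if (simulated) {
      simulate_sample_reads(dataset, row$sample_id)
    } else {
      f1 <- if (is.null(fastq_dir)) row$fastq1 else
        file.path(fastq_dir, row$fastq1)
      f2 <- if (is.null(fastq_dir)) row$fastq2 else
        file.path(fastq_dir, row$fastq2)
      bind_rows(read_fastq(f1, row$sample_id, 1L),
                read_fastq(f2, row$sample_id, 2L))
    }
    qc <- quality_filter(reads, params$min_mean_phred, params$max_n_fraction)
    qc_rows[[i]] <- mutate(qc$report, sample_id = row$sample_id)
    native <- native_genotype(row$tissue)
    foreign <- if (native == "SCI") "ROO" else "SCI"
    cls <- classify_sample_reads(
      qc$reads, refs[[native]], refs[[foreign]], params,
      tissue = row$tissue, condition = row$condition,
      replicate = row$replicate,
      indexes = list(native = idx[[native]], foreign = idx[[foreign]]))
    cls$sample_id <- row$sample_id
    # drop the bulky per-read id vectors once counted; keep the small sets
    summary_row <- tibble(
      sample_id = row$sample_id, tissue = row$tissue,
      condition = row$condition, replicate = row$replicate,
      direction = cls$direction,
      n_reads = cls$n_input,
      n_mapped = cls$n_mapped_native,
      n_unmapped = length(cls$unmapped),
      n_candidate = length(cls$candidate_mobile),
      n_false_positive = length(cls$false_positive),
      n_discarded = cls$n_discarded,
      n_retained = nrow(cls$retained))
    cls$summary <- summary_row
    cls$unmapped <- character(0)
    cls$candidate_mobile <- character(0)
    cls$false_positive <- character(0)
    cls$retained <- cls$retained[0, , drop = FALSE]
    classified[[i]] <- cls
    expr_rows[[i]] <- cls$native_gene_counts |>
      mutate(sample_id = row$sample_id, tissue = row$tissue,
             condition = row$condition, replicate = row$replicate,
             genotype = native)
  }

  expression <- bind_rows(expr_rows) |>
    left_join(bind_rows(
      mutate(select(scion$genes, "gene_id", "exon_length"),
             genotype = "SCI"),
      mutate(select(rootstock$genes, "gene_id", "exon_length"),
             genotype = "ROO")),
      by = c("gene_id", "genotype")) |>
    group_by(.data$sample_id) |>
    mutate(tpm = tpm(.data$count, .data$exon_length)) |>
    ungroup()

  source_counts_for <- function(direction, condition) {
    src_tissues <- if (direction == "down") "HL" else c("RR", "RL")
    expression |>
      filter(.data$tissue %in% src_tissues,
             .data$condition == !!condition) |>
      select("gene_id", "tissue", "replicate", "count")
  }

  groups <- distinct(sheet, .data$tissue, .data$condition)
  calls <- bind_rows(lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    reps <- classified[sheet$tissue == g$tissue &
                         sheet$condition == g$condition]
    direction <- reps[[1]]$direction
    call_mobile_genes(reps, source_counts_for(direction, g$condition),
                      params)
  }))

  venn <- NULL
  if (all(c("CK", "drought") %in% sheet$condition)) {
    venn <- bind_rows(lapply(unique(sheet$tissue), function(ts) {
      ck <- filter(calls, .data$tissue == ts, .data$condition == "CK")
      dr <- filter(calls, .data$tissue == ts, .data$condition == "drought")
      condition_specific_sets(ck, dr)
    }))
  }

  run <- structure(list(
    calls = calls,
    read_set_summary = bind_rows(lapply(classified, `[[`, "summary")) |>
      left_join(bind_rows(qc_rows), by = "sample_id"),
    expression = expression,
    transport = classify_transport(calls),
    transport_by_condition = lapply(
      setNames(unique(sheet$condition), unique(sheet$condition)),
      function(cd) classify_transport(
        filter(calls, .data$condition == cd))),
    condition_venn = venn,
    params = params,
    ground_truth = if (simulated) dataset$ground_truth else NULL),
    class = "graft_run")
  run
}

#' @export
print.graft_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<graft_run> %d sample(s); %d mobile call(s): ",
    "%d upward gene(s), %d downward gene(s) ",
    "(RR %d, RL %d)\n"),
    nrow(x$read_set_summary), nrow(x$calls),
    x$transport$total_up, x$transport$total_down,
    x$transport$n_rr, x$transport$n_rl))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `graft_run` object.
#' @param ... Unused.
#' @method glance graft_run
#' @export
glance.graft_run <- function(x, ...) {
  tibble(
    n_samples = nrow(x$read_set_summary),
    n_calls = nrow(x$calls),
    n_up = x$transport$total_up,
    n_down = x$transport$total_down,
    n_through_root = x$transport$n_through_root,
    n_rl_direct = x$transport$n_rl_direct,
    n_rr_only_degraded = x$transport$n_rr_only_degraded)
}

#' @rdname run_experiment
#' @method tidy graft_run
#' @export
tidy.graft_run <- function(x, ...) x$calls

#' Compare mobile calls against simulator ground truth
#'
#' A truly mobile gene counts as recovered if it is called in any
#' tissue-by-condition group; a call is a false positive if its gene was
#' never spiked (in that direction). Sensitivity is
#' recovered / truly-mobile, precision true-calls / all-calls.
#'
#' @param calls Mobile-call tibble.
#' @param ground_truth Truth tibble from [generate_dataset()].
#' @return A tibble with one row per direction plus an `"overall"` row:
#'   `direction`, `n_true`, `n_called`, `n_recovered`, `n_false`,
#'   `sensitivity`, `precision`.
#' @export
evaluate_calls <- function(calls, ground_truth) {
  calls <- as_tibble(calls)
  gt <- filter(as_tibble(ground_truth), .data$mobile)
  one <- function(dir) {
    truth_ids <- gt$gene_id[gt$direction == dir]
    called_ids <- unique(calls$gene_id[calls$direction == dir])
    hit <- intersect(called_ids, truth_ids)
    tibble(
      direction = dir,
      n_true = length(truth_ids),
      n_called = length(called_ids),
      n_recovered = length(hit),
      n_false = length(setdiff(called_ids, truth_ids)),
      sensitivity = if (length(truth_ids)) {
        length(hit) / length(truth_ids)
      } else {
        NA_real_
      },
      precision = if (length(called_ids)) {
        length(hit) / length(called_ids)
      } else {
        NA_real_
      })
  }
  per_dir <- bind_rows(one("down"), one("up"))
  overall <- tibble(
    direction = "overall",
    n_true = sum(per_dir$n_true),
    n_called = sum(per_dir$n_called),
    n_recovered = sum(per_dir$n_recovered),
    n_false = sum(per_dir$n_false),
    sensitivity = if (sum(per_dir$n_true)) {
      sum(per_dir$n_recovered) / sum(per_dir$n_true)
    } else {
      NA_real_
    },
    precision = if (sum(per_dir$n_called)) {
      sum(per_dir$n_recovered) / sum(per_dir$n_called)
    } else {
      NA_real_
    })
  bind_rows(per_dir, overall)
}
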