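#' Read a run configuration file
#'
#' A single YAML file drives both the simulator and the pipeline. Recognised
#' sections: `seed` (integer), `outdir`, `simulation` (fields of
#' [simulation_params()]) and `pipeline` (fields of [pipeline_params()]);
#' for runs on existing data, `paths` with `scion_fasta`, `scion_gff3`,
#' `rootstock_fasta`, `rootstock_gff3`, `sample_sheet` and `fastq_dir`.
#' Command-line overrides (see the `graftmobile` script under `inst/cli`)
#' take precedence over file values.
#'
#' @param path Path to the YAML file; `NULL` yields an all-default config.
#' @param overrides Named list merged over the file contents.
#' @return A `run_config` list with fully-resolved `simulation` and
#'   `pipeline` parameter objects.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  seed <- as.integer(raw$seed %||% 1L)
  sim_args <- raw$simulation %||% list()
  sim_args$seed <- seed
  pipe_args <- raw$pipeline %||% list()
  structure(list(
    seed = seed,
    outdir = raw$outdir %||% "graftmobile_out",
    paths = raw$paths %||% list(),
    simulation = do.call(simulation_params, sim_args),
    pipeline = do.call(pipeline_params, pipe_args)),
    class = "run_config")
}

#' Simulate a dataset to disk
#'
#' Generates the synthetic heterograft experiment of `config$simulation` and
#' writes every artefact (references, FASTQ, truth, manifest) under
#' `config$outdir`.
#'
#' @param config A [read_run_config()] object.
#' @return The manifest tibble, invisibly.
#' @export
simulate_to_dir <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- generate_dataset(config$simulation)
  write_dataset(dataset, config$outdir)
}

#' Run the pipeline from a configuration
#'
#' Either simulates the dataset in memory (default) or, when
#' `config$paths` is populated, loads references and FASTQ files from disk;
#' then runs [run_experiment()] and writes all stage outputs plus a JSON run
#' report under `config$outdir`.
#'
#' @param config A [read_run_config()] object.
#' @param quiet Suppress progress messages.
#' @return The `graft_run`, invisibly.
#' @export
run_from_config <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  if (length(p) && !is.null(p$scion_fasta)) {
    scion <- genotype_reference(
      p$scion_id %||% "SCI", read_fasta(p$scion_fasta),
      read_gff3(p$scion_gff3))
    rootstock <- genotype_reference(
      p$rootstock_id %||% "ROO", read_fasta(p$rootstock_fasta),
      read_gff3(p$rootstock_gff3))
    dataset <- list(scion = scion, rootstock = rootstock,
                    sample_sheet = read_sample_sheet(p$sample_sheet))
    run <- run_experiment(dataset, config$pipeline,
                          fastq_dir = p$fastq_dir, quiet = quiet)
  } else {
    dataset <- generate_dataset(config$simulation)
    run <- run_experiment(dataset, config$pipeline, quiet = quiet)
  }
  write_run_outputs(run, config$outdir)
  invisible(run)
}

#' Write the stage outputs and JSON report of a run
#'
#' Emits `mobile_calls.tsv`, `read_sets_summary.tsv`,
#' `transport_summary.tsv`, `condition_venn.tsv`, `expression_tpm.tsv` and
#' `report.json`. Every number in the report is recomputed from the tibbles
#' being written, so the report is a pure function of the stage outputs.
#'
#' @param run A `graft_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "graft_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  readr::write_tsv(run$calls, file.path(dir, "mobile_calls.tsv"))
  readr::write_tsv(run$read_set_summary,
                   file.path(dir, "read_sets_summary.tsv"))

  transport_tbl <- bind_rows(lapply(
    c(list(pooled = run$transport), run$transport_by_condition),
    glance), .id = "condition_set")
  readr::write_tsv(transport_tbl, file.path(dir, "transport_summary.tsv"))

  if (!is.null(run$condition_venn)) {
    venn_flat <- run$condition_venn |>
      mutate(dplyr::across(dplyr::where(is.list),
                           ~ vapply(.x, paste, character(1),
                                    collapse = ";")))
    readr::write_tsv(venn_flat, file.path(dir, "condition_venn.tsv"))
  }

  readr::write_tsv(run$expression, file.path(dir, "expression_tpm.tsv"))

  call_cells <- run$calls |>
    count(.data$direction, .data$tissue, .data$condition, name = "n_genes")
  report <- list(
    parameters = unclass(run$params),
    samples = nrow(run$read_set_summary),
    read_sets = lapply(split(
      run$read_set_summary, run$read_set_summary$sample_id),
      function(r) as.list(r[1, c("tissue", "condition", "replicate",
                                 "n_reads", "n_mapped", "n_unmapped",
                                 "n_candidate", "n_false_positive",
                                 "n_retained")])),
    calls = list(
      total = nrow(run$calls),
      by_cell = lapply(seq_len(nrow(call_cells)), function(i)
        as.list(call_cells[i, ])),
      upward_genes = run$transport$total_up,
      downward_genes = run$transport$total_down),
    transport = as.list(glance(run$transport)))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
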