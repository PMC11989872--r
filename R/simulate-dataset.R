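#' Parameters for the synthetic heterograft experiment
#'
#' Defaults encode the study design the pipeline assumes: two genotypes at 5%
#' sequence divergence (cultivated-by-wild scale), three tissues (HL scion
#' leaf, RR rootstock root, RL rootstock lateral-branch leaf) under CK and
#' drought with three biological replicates, 150 bp paired-end reads, and
#' mobile transcripts spiked into sink tissues at low TPM. The downward
#' pattern fractions default to the three-way split observed in real
#' heterograft data (roughly a third each RL-direct, RR-only, RR-and-RL).
#'
#' @param seed Master seed; every random stream derives a sub-seed from it.
#' @param n_genes_per_genotype Genes per genotype.
#' @param gene_length_range,intergenic_range,n_chromosomes Genome layout
#'   passed to [random_reference()].
#' @param divergence,indel_rate Between-genotype substitution and indel rates
#'   per site (see [diverge_genome()]).
#' @param read_length Read length in nt.
#' @param fragments_per_sample Sequenced fragments (read pairs) per sample.
#'   The default (500,000) is sized so that a sink transcript at 2 TPM yields
#'   on the order of 1-2 supporting reads per replicate after cross-check
#'   attrition, the floor at which the replicate-consensus caller is designed
#'   to operate.
#' @param fragment_length_mean,fragment_length_sd Fragment length model.
#' @param error_rate Per-base substitution sequencing error rate.
#' @param n_replicates Biological replicates per tissue-by-condition group.
#' @param mobile_down_fraction Fraction of scion genes spiked as downwardly
#'   mobile.
#' @param mobile_up_fraction Fraction of rootstock genes spiked as upwardly
#'   mobile.
#' @param drought_specific_fraction Fraction of mobile genes present only
#'   under drought.
#' @param mobile_abundance_range Sink-tissue TPM interval for spiked
#'   transcripts (uniform draw).
#' @param rl_direct_fraction Fraction of downward mobile genes deposited in
#'   RL without passing detection in RR.
#' @param degradation_fraction Fraction of downward mobile genes detected in
#'   RR only (degraded in transit before RL).
#' @param conditions Condition labels.
#' @param baseline_sdlog,tissue_sdlog Expression profile dispersion (see
#'   [sample_expression()]).
#' @param qual_hi,qual_lo Phred scores written for correct and erroneous
#'   bases.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(seed = 1L,
                              n_genes_per_genotype = 300L,
                              gene_length_range = c(500L, 2000L),
                              intergenic_range = c(200L, 400L),
                              n_chromosomes = 3L,
                              divergence = 0.05,
                              indel_rate = 5e-4,
                              read_length = 150L,
                              fragments_per_sample = 500000L,
                              fragment_length_mean = 300,
                              fragment_length_sd = 30,
                              error_rate = 0.001,
                              n_replicates = 3L,
                              mobile_down_fraction = 0.10,
                              mobile_up_fraction = 1 / 30,
                              drought_specific_fraction = 0.25,
                              mobile_abundance_range = c(0.5, 50),
                              rl_direct_fraction = 0.34,
                              degradation_fraction = 0.33,
                              conditions = c("CK", "drought"),
                              baseline_sdlog = 1.5,
                              tissue_sdlog = 0.4,
                              qual_hi = 37L,
                              qual_lo = 20L) {
  p <- as.list(environment())
  for (nm in c("divergence", "indel_rate", "error_rate",
               "mobile_down_fraction", "mobile_up_fraction",
               "drought_specific_fraction", "rl_direct_fraction",
               "degradation_fraction")) {
    assert_scalar_number(p[[nm]], nm, 0, 1)
  }
  if (p$rl_direct_fraction + p$degradation_fraction > 1) {
    abort("rl_direct_fraction + degradation_fraction must be <= 1")
  }
  if (p$read_length > min(p$gene_length_range)) {
    abort("read_length must not exceed the minimum gene length")
  }
  if (any(p$mobile_abundance_range <= 0) ||
      diff(p$mobile_abundance_range) < 0) {
    abort("mobile_abundance_range must be a positive increasing interval")
  }
  if (p$n_replicates < 1L) abort("n_replicates must be >= 1")
  structure(p, class = "simulation_params")
}

# Deterministic partition of the selected downward genes into the three
# transport classes: the first round(f_rl * n) are RL-direct, the next
# round(f_deg * n) RR-only, the remainder both tissues.
partition_down_patterns <- function(gene_ids, rl_direct_fraction,
                                    degradation_fraction) {
  n <- length(gene_ids)
  n_rl <- round(rl_direct_fraction * n)
  n_rr <- round(degradation_fraction * n)
  if (n_rl + n_rr > n) n_rr <- n - n_rl
  sinks <- rep("RR;RL", n)
  if (n_rl > 0) sinks[seq_len(n_rl)] <- "RL"
  if (n_rr > 0) sinks[n_rl + seq_len(n_rr)] <- "RR"
  tibble(gene_id = gene_ids, sink_tissues = sinks)
}

#' Generate a complete synthetic heterograft experiment
#'
#' Builds the scion genotype, derives the rootstock genotype by divergence,
#' spikes mobile transcripts (upward: rootstock genes sinking in HL;
#' downward: scion genes sinking in RR/RL per the three transport classes),
#' and prepares the sample sheet and ground truth. Reads themselves are
#' generated per sample by [simulate_sample_reads()] so that large
#' experiments can be processed one sample at a time; [write_dataset()]
#' materialises everything (FASTA/GFF3/FASTQ/TSV) on disk.
#'
#' Fixed seed implies byte-identical output for a given build of the package.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `graft_dataset`: references, sample sheet,
#'   ground truth, variant table and per-genotype transcript tables.
#' @export
generate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- params$seed

  scion <- random_reference(
    "SCI", params$n_genes_per_genotype, params$gene_length_range,
    params$intergenic_range, params$n_chromosomes,
    seed = sub_seed(seed, "genome"))
  div <- diverge_genome(scion, params$divergence, params$indel_rate,
                        seed = seed, genotype_id = "ROO",
                        protect_boundaries = TRUE)
  rootstock <- div$reference

  n <- params$n_genes_per_genotype
  n_down <- round(params$mobile_down_fraction * n)
  n_up <- round(params$mobile_up_fraction * n)

  truth <- with_seed(sub_seed(seed, "truth"), {
    down_ids <- if (n_down > 0) {
      sample(scion$genes$gene_id, n_down)
    } else {
      character(0)
    }
    up_ids <- if (n_up > 0) {
      sample(rootstock$genes$gene_id, n_up)
    } else {
      character(0)
    }
    down_pat <- partition_down_patterns(
      down_ids, params$rl_direct_fraction, params$degradation_fraction)
    cond_of <- function(ids) {
      if (!"drought" %in% params$conditions) {
        return(rep(paste(params$conditions, collapse = ";"), length(ids)))
      }
      out <- rep("CK;drought", length(ids))
      k <- round(params$drought_specific_fraction * length(ids))
      if (k > 0 && length(ids) > 0) {
        # independent of the transport-pattern ordering
        out[sample(length(ids), k)] <- "drought"
      }
      out
    }
    sink_tpm_down <- runif(n_down, params$mobile_abundance_range[1],
                           params$mobile_abundance_range[2])
    sink_tpm_up <- runif(n_up, params$mobile_abundance_range[1],
                         params$mobile_abundance_range[2])
    bind_rows(
      tibble(gene_id = down_pat$gene_id, genotype = "SCI",
             direction = "down", sink_tissues = down_pat$sink_tissues,
             conditions = cond_of(down_ids), sink_tpm = sink_tpm_down),
      tibble(gene_id = up_ids, genotype = "ROO", direction = "up",
             sink_tissues = "HL", conditions = cond_of(up_ids),
             sink_tpm = sink_tpm_up))
  })

  # source-tissue abundance of each gene (HL for scion genes, RR for
  # rootstock genes), under the first condition in which the gene is present
  all_genes <- bind_rows(
    mutate(scion$genes, genotype = "SCI"),
    mutate(rootstock$genes, genotype = "ROO"))
  expr_src <- list(
    SCI = lapply(setNames(params$conditions, params$conditions), function(cd)
      sample_expression(scion$genes, cd, "HL", seed,
                        params$baseline_sdlog, params$tissue_sdlog)),
    ROO = lapply(setNames(params$conditions, params$conditions), function(cd)
      sample_expression(rootstock$genes, cd, "RR", seed,
                        params$baseline_sdlog, params$tissue_sdlog)))
  ground_truth <- all_genes |>
    select("gene_id", "genotype") |>
    left_join(truth, by = c("gene_id", "genotype")) |>
    mutate(mobile = !is.na(.data$direction))
  src_tpm <- vapply(seq_len(nrow(ground_truth)), function(i) {
    gt <- ground_truth[i, ]
    cond <- if (gt$mobile) strsplit(gt$conditions, ";")[[1]][1] else
      params$conditions[1]
    tab <- expr_src[[gt$genotype]][[cond]]
    tab$tpm[match(gt$gene_id, tab$gene_id)]
  }, numeric(1))
  ground_truth$source_tpm <- src_tpm
  ground_truth <- select(ground_truth, "gene_id", "genotype", "mobile",
                         "direction", "sink_tissues", "conditions",
                         "source_tpm", "sink_tpm")

  sheet <- tidyr::expand_grid(
    condition = params$conditions,
    tissue = tissues_all,
    replicate = seq_len(params$n_replicates)) |>
    mutate(sample_id = sprintf("%s%s_%d",
                               ifelse(.data$condition == "CK", "CK", "D"),
                               .data$tissue, .data$replicate),
           fastq1 = paste0(.data$sample_id, "_R1.fastq"),
           fastq2 = paste0(.data$sample_id, "_R2.fastq")) |>
    select("sample_id", "tissue", "condition", "replicate",
           "fastq1", "fastq2")

  structure(list(
    params = params,
    scion = scion,
    rootstock = rootstock,
    variants = div$variants,
    homologs = attr(rootstock, "homologs"),
    sample_sheet = sheet,
    ground_truth = ground_truth,
    transcripts = list(SCI = gene_transcripts(scion),
                       ROO = gene_transcripts(rootstock))),
    class = "graft_dataset")
}

#' @export
print.graft_dataset <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(paste0(
    "<graft_dataset> %d genes/genotype, divergence %.3g, %d samples, ",
    "%d mobile genes (%d down, %d up)\n"),
    x$params$n_genes_per_genotype, x$params$divergence,
    nrow(x$sample_sheet), sum(gt$mobile),
    sum(gt$mobile & gt$direction == "down", na.rm = TRUE),
    sum(gt$mobile & gt$direction == "up", na.rm = TRUE)))
  invisible(x)
}

# The native genotype of a tissue: HL is scion tissue, RR/RL rootstock.
native_genotype <- function(tissue) {
  if (tissue == "HL") "SCI" else "ROO"
}

#' Simulate the paired-end reads of one sample
#'
#' Draws fragment counts from a multinomial over the sample's transcript pool
#' (native transcripts at the tissue profile abundances plus foreign
#' transcripts of mobile genes sinking in this tissue and condition at their
#' spiked TPM, weighted by transcript length) and generates mate pairs with
#' i.i.d. substitution errors. Deterministic per (dataset seed, sample).
#'
#' @param dataset A `graft_dataset`.
#' @param sample_id One of `dataset$sample_sheet$sample_id`.
#' @return A read tibble (two rows per fragment: mates 1 and 2) with columns
#'   `read_id`, `mate`, `sequence`, `quality`, `sample_id`.
#' @export
simulate_sample_reads <- function(dataset, sample_id) {
  stopifnot(inherits(dataset, "graft_dataset"))
  p <- dataset$params
  row <- dataset$sample_sheet[dataset$sample_sheet$sample_id == sample_id, ]
  if (nrow(row) != 1L) abort(paste0("unknown sample: ", sample_id))

  native <- native_genotype(row$tissue)
  foreign <- if (native == "SCI") "ROO" else "SCI"
  native_ref <- if (native == "SCI") dataset$scion else dataset$rootstock
  prof <- sample_expression(native_ref$genes, row$condition, row$tissue,
                            p$seed, p$baseline_sdlog, p$tissue_sdlog)
  native_tx <- dataset$transcripts[[native]]
  pool <- tibble(gene_id = native_tx$gene_id,
                 sequence = native_tx$sequence,
                 length = native_tx$length,
                 tpm = prof$tpm[match(native_tx$gene_id, prof$gene_id)])

  gt <- dataset$ground_truth
  spikes <- gt[gt$mobile &
                 gt$genotype == foreign &
                 vapply(gt$sink_tissues, function(s)
                   !is.na(s) && row$tissue %in% strsplit(s, ";")[[1]],
                   logical(1)) &
                 vapply(gt$conditions, function(s)
                   !is.na(s) && row$condition %in% strsplit(s, ";")[[1]],
                   logical(1)), , drop = FALSE]
  if (nrow(spikes)) {
    ftx <- dataset$transcripts[[foreign]]
    idx <- match(spikes$gene_id, ftx$gene_id)
    pool <- bind_rows(pool, tibble(
      gene_id = spikes$gene_id, sequence = ftx$sequence[idx],
      length = ftx$length[idx], tpm = spikes$sink_tpm))
  }

  w <- pool$tpm * pool$length
  counts <- with_seed(sub_seed(p$seed, paste0("frag-", sample_id)),
                      as.integer(rmultinom(1L, p$fragments_per_sample,
                                           w / sum(w))))
  sim <- gm_simulate_reads(pool$sequence, counts, p$read_length,
                           p$fragment_length_mean, p$fragment_length_sd,
                           p$error_rate, p$qual_hi, p$qual_lo,
                           sub_seed(p$seed, paste0("reads-", sample_id)))
  nfrag <- length(sim$seq1)
  frag_ids <- sprintf("%s_f%07d", sample_id, seq_len(nfrag))
  tibble(
    read_id = c(frag_ids, frag_ids),
    mate = rep(1:2, each = nfrag),
    sequence = c(sim$seq1, sim$seq2),
    quality = c(sim$qual1, sim$qual2),
    sample_id = sample_id)
}

#' Write a synthetic dataset to disk
#'
#' Materialises references (FASTA + GFF3), per-sample FASTQ pairs, the sample
#' sheet, `ground_truth.tsv`, `variants.tsv` and a `manifest.tsv` with the
#' md5 checksum of every file written.
#'
#' @param dataset A `graft_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "graft_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L) {
    abort(paste0("output directory not writable: ", dir))
  }
  files <- character(0)
  put <- function(fn) files <<- c(files, fn)

  write_fasta(dataset$scion, file.path(dir, "scion.fasta"))
  put("scion.fasta")
  write_fasta(dataset$rootstock, file.path(dir, "rootstock.fasta"))
  put("rootstock.fasta")
  write_gff3(dataset$scion, file.path(dir, "scion.gff3"))
  put("scion.gff3")
  write_gff3(dataset$rootstock, file.path(dir, "rootstock.gff3"))
  put("rootstock.gff3")
  readr::write_tsv(dataset$ground_truth, file.path(dir, "ground_truth.tsv"))
  put("ground_truth.tsv")
  readr::write_tsv(dataset$variants, file.path(dir, "variants.tsv"))
  put("variants.tsv")
  readr::write_tsv(dataset$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  put("sample_sheet.tsv")

  for (i in seq_len(nrow(dataset$sample_sheet))) {
    row <- dataset$sample_sheet[i, ]
    reads <- simulate_sample_reads(dataset, row$sample_id)
    write_fastq(reads[reads$mate == 1L, ], file.path(dir, row$fastq1))
    write_fastq(reads[reads$mate == 2L, ], file.path(dir, row$fastq2))
    put(row$fastq1)
    put(row$fastq2)
  }

  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
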