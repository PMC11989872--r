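test_that("zero divergence reproduces the base genome exactly", {
  ref <- random_reference("SCI", 10, c(200, 400), c(60, 120), 2, seed = 3)
  div <- diverge_genome(ref, 0, 0, seed = 9, genotype_id = "ROO")
  expect_identical(div$reference$sequences, ref$sequences)
  expect_equal(nrow(div$variants), 0L)
  expect_equal(div$reference$genes$start, ref$genes$start)
  expect_equal(div$reference$genes$gene_id,
               sub("^SCI_", "ROO_", ref$genes$gene_id))
})

test_that("substitution counts follow the binomial divergence model", {
  # ~100 kb genome, three seeds: observed substitutions within 3 sd of
  # Binomial(L, divergence)
  ref <- random_reference("SCI", 50, c(1500, 2500), c(100, 200), 1,
                          seed = 21)
  L <- sum(nchar(ref$sequences))
  expect_gt(L, 75000)
  for (s in c(1, 2, 3)) {
    div <- diverge_genome(ref, 0.05, 0, seed = s)
    n_sub <- sum(div$variants$type == "sub")
    mu <- L * 0.05
    sdv <- sqrt(L * 0.05 * 0.95)
    expect_lt(abs(n_sub - mu), 3 * sdv)
  }
})

test_that("divergence and read simulation are deterministic in the seed", {
  p <- simulation_params(seed = 17, n_genes_per_genotype = 15,
                         fragments_per_sample = 300)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$rootstock$sequences, d2$rootstock$sequences)
  expect_identical(d1$variants, d2$variants)
  expect_identical(d1$ground_truth, d2$ground_truth)
  r1 <- simulate_sample_reads(d1, "DRR_2")
  r2 <- simulate_sample_reads(d2, "DRR_2")
  expect_identical(r1, r2)
})

test_that("a deletion destroying a gene boundary is reported by gene", {
  ref <- genotype_reference(
    "SCI", c(c1 = strrep("ACGT", 100)),
    tibble::tibble(gene_id = "SCI_g0001", chromosome = "c1", start = 11L,
                   end = 390L, strand = "+", exon_length = 380L))
  # drive the indel rate up until some seed deletes a boundary
  hit <- FALSE
  for (s in 1:50) {
    res <- tryCatch(
      diverge_genome(ref, 0, indel_rate = 0.1, seed = s),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      hit <- TRUE
      expect_match(res, "SCI_g0001")
      break
    }
  }
  expect_true(hit)
})

test_that("expression profiles normalise to 1e6 and are reproducible", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40))
  prof <- sample_expression(genes, "CK", "HL", seed = 4)
  expect_equal(sum(prof$tpm), 1e6, tolerance = 1e-6)
  expect_identical(prof, sample_expression(genes, "CK", "HL", seed = 4))
  expect_false(identical(
    prof$tpm, sample_expression(genes, "drought", "HL", seed = 4)$tpm))

  single <- sample_expression(genes[1, ], "CK", "HL", seed = 4)
  expect_equal(single$tpm, 1e6)
})

test_that("downward genes partition into the three transport classes", {
  p <- simulation_params(seed = 8, n_genes_per_genotype = 100,
                         mobile_down_fraction = 1, mobile_up_fraction = 0,
                         rl_direct_fraction = 0.3,
                         degradation_fraction = 0.3,
                         fragments_per_sample = 100)
  gt <- generate_dataset(p)$ground_truth
  down <- gt[gt$mobile & gt$direction == "down", ]
  expect_equal(nrow(down), 100L)
  expect_equal(sum(down$sink_tissues == "RL"), 30L)
  expect_equal(sum(down$sink_tissues == "RR"), 30L)
  expect_equal(sum(down$sink_tissues == "RR;RL"), 40L)
})

test_that("zero mobile fractions yield an all-native experiment", {
  p <- simulation_params(seed = 6, n_genes_per_genotype = 20,
                         fragments_per_sample = 400, error_rate = 0,
                         mobile_down_fraction = 0, mobile_up_fraction = 0)
  ds <- generate_dataset(p)
  expect_equal(sum(ds$ground_truth$mobile), 0L)
  # with no errors and no spikes, every read of a rootstock sample maps to
  # the rootstock reference exactly
  reads <- simulate_sample_reads(ds, "CKRR_1")
  idx <- build_index(ds$rootstock)
  al <- align_reads(reads, idx, ds$rootstock, 2)
  expect_length(al$unmapped, 0L)
  expect_true(all(al$hits$edit_distance == 0L))
})

test_that("realised fragment counts match the abundance model", {
  # error-free reads, no spikes: mapped read counts / 2 are the multinomial
  # fragment draw over transcripts with p ~ tpm * length
  p <- simulation_params(seed = 12, n_genes_per_genotype = 25,
                         fragments_per_sample = 5000, error_rate = 0,
                         mobile_down_fraction = 0, mobile_up_fraction = 0)
  ds <- generate_dataset(p)
  reads <- simulate_sample_reads(ds, "CKHL_1")
  idx <- build_index(ds$scion)
  al <- align_reads(reads, idx, ds$scion, 2)
  counts <- count_reads_per_gene(al$hits, ds$scion$genes)
  prof <- sample_expression(ds$scion$genes, "CK", "HL", p$seed,
                            p$baseline_sdlog, p$tissue_sdlog)
  tx <- ds$transcripts$SCI
  w <- prof$tpm[match(counts$gene_id, prof$gene_id)] *
    tx$length[match(counts$gene_id, tx$gene_id)]
  pexp <- w / sum(w)
  frag_counts <- counts$count / 2
  expect_equal(sum(frag_counts), 5000)
  gof <- suppressWarnings(stats::chisq.test(frag_counts, p = pexp))
  expect_gt(gof$p.value, 0.01)
})

test_that("foreign reads are far from the native genome at 5% divergence", {
  # error-free foreign 150-mers rarely fall within edit distance 2 of the
  # native reference: the i.i.d. substitution model gives
  # P(Binom(150, 0.05) <= 2) ~ 1.8%, so the observed rate over 400 reads
  # should stay below 4%
  p <- simulation_params(seed = 19, n_genes_per_genotype = 40,
                         fragments_per_sample = 100, error_rate = 0)
  ds <- generate_dataset(p)
  tx <- ds$transcripts$SCI
  set.seed(33)
  picks <- sample(nrow(tx), 400, replace = TRUE)
  starts <- vapply(tx$length[picks] - 149L, function(m)
    sample.int(m, 1), integer(1))
  foreign <- substring(tx$sequence[picks], starts, starts + 149L)
  idx <- build_index(ds$rootstock)
  al <- align_reads(reads_from_seqs(foreign), idx, NULL, 2)
  expect_lt(nrow(al$hits) / length(foreign), 0.04)
})
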