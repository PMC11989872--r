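make_pair <- function(seed = 31, n_genes = 25) {
  base <- random_reference("ROO", n_genes, c(400, 900), c(80, 160), 2,
                           seed = seed)
  # scion derived from the rootstock so the two genomes are homologous
  div <- diverge_genome(base, 0.05, 0, seed = seed, genotype_id = "SCI")
  list(rootstock = base, scion = div$reference)
}

test_that("an all-native error-free sample produces no candidates", {
  refs <- make_pair()
  tx <- gene_transcripts(refs$rootstock)
  set.seed(1)
  picks <- sample(nrow(tx), 400, replace = TRUE)
  starts <- vapply(tx$length[picks] - 149L, function(m)
    sample.int(m, 1), integer(1))
  reads <- reads_from_seqs(substring(tx$sequence[picks], starts,
                                     starts + 149L))
  cls <- classify_sample_reads(reads, refs$rootstock, refs$scion,
                               pipeline_params(), tissue = "RR")
  expect_equal(length(cls$candidate_mobile), 0L)
  expect_equal(length(cls$false_positive), 0L)
  expect_equal(cls$n_mapped_native, 400L)
  expect_equal(cls$direction, "down")
})

test_that("spiked foreign reads are retained and recover exactly their gene", {
  refs <- make_pair(seed = 45)
  g <- refs$scion$genes[7, ]
  tx <- gene_transcripts(refs$scion)
  seqi <- tx$sequence[tx$gene_id == g$gene_id]
  set.seed(2)
  starts <- sample(nchar(seqi) - 150, 100, replace = TRUE)
  spike <- reads_from_seqs(substring(seqi, starts, starts + 149L),
                           ids = sprintf("spk%03d", 1:100))
  cls <- classify_sample_reads(spike, refs$rootstock, refs$scion,
                               pipeline_params(), tissue = "RR")
  expect_equal(cls$gene_support$gene_id, g$gene_id)
  # nearly all spiked reads survive the cross-check and the k = 1 re-map
  expect_gt(cls$gene_support$reads, 70)
  expect_equal(nrow(cls$retained),
               sum(cls$gene_support$reads))
})

test_that("reads from conserved regions with errors become false positives", {
  # both genotypes share an identical segment; a read from it perturbed by 3
  # errors is unmapped at k = 2 yet hits both references in the local search,
  # so the native hit wins and the read lands in B
  set.seed(3)
  shared <- random_dna(800)
  nat <- c(c1 = paste0(random_dna(2000), shared, random_dna(500)))
  forn <- c(c1 = paste0(random_dna(1500), shared, random_dna(900)))
  ref_n <- seqs_as_reference(nat, "ROO")
  ref_f <- seqs_as_reference(forn, "SCI")
  rd <- substr(shared, 301, 450)
  for (p in c(25, 75, 125)) {
    substr(rd, p, p) <- setdiff(c("A", "C", "G", "T"), substr(rd, p, p))[1]
  }
  expect_equal(oracle_edit_distance(rd, nat), 3)
  cls <- classify_sample_reads(reads_from_seqs(rd, ids = "shared1"),
                               ref_n, ref_f, pipeline_params(),
                               tissue = "RR")
  expect_equal(cls$false_positive, "shared1")
  expect_length(cls$candidate_mobile, 0L)
})

test_that("classification partitions every QC-passed read exactly once", {
  refs <- make_pair(seed = 61)
  tx_n <- gene_transcripts(refs$rootstock)
  tx_f <- gene_transcripts(refs$scion)
  set.seed(4)
  native <- vapply(1:300, function(i) {
    j <- sample(nrow(tx_n), 1)
    st <- sample(tx_n$length[j] - 150, 1)
    mutate_seq(substring(tx_n$sequence[j], st, st + 149),
               n_sub = sample(0:4, 1))
  }, character(1))
  foreign <- vapply(1:60, function(i) {
    j <- sample(nrow(tx_f), 1)
    st <- sample(tx_f$length[j] - 150, 1)
    substring(tx_f$sequence[j], st, st + 149)
  }, character(1))
  junk <- vapply(1:20, function(i) random_dna(150), character(1))
  reads <- reads_from_seqs(c(native, foreign, junk))
  cls <- classify_sample_reads(reads, refs$rootstock, refs$scion,
                               pipeline_params(), tissue = "RL")
  expect_equal(
    cls$n_mapped_native + length(cls$candidate_mobile) +
      length(cls$false_positive) + cls$n_discarded,
    nrow(reads))
  expect_length(intersect(cls$candidate_mobile, cls$false_positive), 0L)
  expect_true(all(cls$retained$read_id %in% cls$candidate_mobile))
  # every supported gene belongs to the foreign genotype
  expect_true(all(startsWith(cls$gene_support$gene_id, "SCI_")))
})

test_that("the replicate-consensus rule is exact over all support patterns", {
  params <- pipeline_params()  # 2 reads per gene, 2 of 3 replicates
  src_ok <- expressed_source("SCI_g0001")
  src_zero <- dplyr::mutate(src_ok, count = 0L)
  for (pattern in 0:7) {
    present <- as.logical(bitwAnd(pattern, c(1L, 2L, 4L)) > 0L)
    reps <- lapply(1:3, function(i) {
      fake_classified(
        if (present[i]) c(SCI_g0001 = 3L) else c(SCI_g0001 = 0L),
        replicate = i)
    })
    expect_call <- sum(present) >= 2L
    calls <- call_mobile_genes(reps, src_ok, params)
    expect_equal(nrow(calls), as.integer(expect_call),
                 info = paste("pattern", pattern))
    if (expect_call) {
      expect_equal(calls$replicate_support, sum(present))
    }
    # without source expression the gene is always excluded (E-filter)
    expect_equal(nrow(call_mobile_genes(reps, src_zero, params)), 0L)
  }
  # single-replicate support with one read never calls
  lone <- lapply(1:3, function(i)
    fake_classified(c(SCI_g0001 = if (i == 3) 1L else 0L), replicate = i))
  expect_equal(nrow(call_mobile_genes(lone, src_ok, params)), 0L)
})

test_that("raising thresholds never adds a call", {
  set.seed(9)
  genes <- sprintf("SCI_g%04d", 1:12)
  for (trial in 1:20) {
    reps <- lapply(1:3, function(i) {
      supp <- stats::rpois(12, 1.5)
      fake_classified(setNames(supp, genes), replicate = i)
    })
    src <- expressed_source(genes)
    base <- call_mobile_genes(reps, src, pipeline_params())
    stricter_reads <- call_mobile_genes(
      reps, src, pipeline_params(min_reads_per_gene = 4L))
    stricter_reps <- call_mobile_genes(
      reps, src, pipeline_params(min_replicates = 3L))
    expect_true(all(stricter_reads$gene_id %in% base$gene_id))
    expect_true(all(stricter_reps$gene_id %in% base$gene_id))
  }
})

test_that("upward and downward directions use the right foreign genome", {
  refs <- make_pair(seed = 88)
  expect_error(
    classify_sample_reads(reads_from_seqs("ACGT"), refs$scion,
                          refs$rootstock, pipeline_params(),
                          tissue = "XX"),
    "unknown tissue")
  tx_f <- gene_transcripts(refs$rootstock)
  rd <- substring(tx_f$sequence[3], 1, 150)
  up <- classify_sample_reads(reads_from_seqs(rd), refs$scion,
                              refs$rootstock, pipeline_params(),
                              tissue = "HL")
  expect_equal(up$direction, "up")
  expect_true(all(startsWith(up$gene_support$gene_id, "ROO_")))
})
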