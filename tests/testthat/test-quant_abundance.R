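test_that("per-gene counting is best-hit and tracks unassigned hits", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chromosome = "c1",
    start = c(101L, 501L), end = c(300L, 800L), strand = "+",
    exon_length = c(200L, 300L))
  hits <- tibble::tibble(
    read_id = sprintf("r%02d", 1:13),
    chromosome = "c1",
    start = c(rep(150L, 10), 520L, 900L, 950L),
    width = 50L,
    gene_id = c(rep("g1", 10), "g2", NA, NA))
  counts <- count_reads_per_gene(hits, genes)
  expect_equal(counts$count[counts$gene_id == "g1"], 10L)
  expect_equal(counts$count[counts$gene_id == "g2"], 1L)
  expect_equal(attr(counts, "n_unassigned"), 2L)
  expect_equal(sum(counts$count) + attr(counts, "n_unassigned"), nrow(hits))
})

test_that("TPM matches its defining identity and edge cases", {
  expect_equal(tpm(5, 1000), 1e6)                       # single gene
  expect_equal(tpm(c(10, 10), c(1000, 2000)),
               c(2e6 / 3, 1e6 / 3))                     # 2:1 length ratio
  set.seed(13)
  for (i in 1:20) {
    counts <- rpois(50, 40)
    lens <- sample(200:3000, 50)
    v <- tpm(counts, lens)
    expect_equal(sum(v), 1e6, tolerance = 1e-6)
    # invariance under count rescaling
    expect_equal(tpm(counts * 7, lens), v, tolerance = 1e-9)
    # defining formula
    rate <- counts / (lens / 1000)
    expect_equal(v, rate / sum(rate) * 1e6)
  }
  expect_equal(tpm(c(0, 0), c(100, 200)), c(0, 0))
  expect_error(tpm(-1, 100), "non-negative")
})

test_that("abundance bins partition the positive axis into six classes", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e", "f", "g"),
                        tpm = c(0.5, 3, 55, 250, 750, 3000, 0))
  bins <- bin_abundance(tab, mobile_ids = c("a", "d"))
  expect_equal(nrow(bins), 6L)
  expect_equal(sum(bins$n_genes), 6L)  # zero-TPM gene excluded
  expect_equal(bins$n_genes[bins$bin == "(0,1]"], 1L)
  expect_equal(bins$n_mobile[bins$bin == "(100,500]"], 1L)

  set.seed(14)
  tpms <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                         tpm = exp(rnorm(300, 3, 2.5)))
  mob <- sample(tpms$gene_id, 40)
  bins <- bin_abundance(tpms, mob)
  edges <- c(0, 1, 10, 100, 500, 1000, Inf)
  naive <- table(cut(tpms$tpm, edges))
  expect_equal(bins$n_genes, as.integer(naive))
  expect_equal(sum(bins$n_genes), 300L)
  expect_true(all(bins$n_mobile <= bins$n_genes))
  expect_equal(sum(bins$n_mobile), 40L)
})

test_that("the mobility test matches Wilcoxon and flags degenerate input", {
  set.seed(15)
  tab <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                        tpm = exp(rnorm(200, 2, 1.5)))
  mob <- sample(tab$gene_id, 30)
  mt <- mobility_abundance_test(tab, mob, n_permutations = 500, seed = 8)
  # rank-sum statistic relates to stats::wilcox.test's W by m(m+1)/2
  w <- stats::wilcox.test(tab$tpm[tab$gene_id %in% mob],
                          tab$tpm[!tab$gene_id %in% mob],
                          exact = FALSE)
  expect_equal(mt$statistic - 30 * 31 / 2, unname(w$statistic))
  expect_identical(
    mt$p_value,
    mobility_abundance_test(tab, mob, n_permutations = 500,
                            seed = 8)$p_value)

  # mobile = the most abundant genes: maximal overlap, tiny p
  top <- tab$gene_id[order(-tab$tpm)][1:100]
  mt_top <- mobility_abundance_test(tab, top, n_permutations = 1000,
                                    seed = 9)
  expect_equal(mt_top$top_k_overlap, 100L)
  expect_lt(mt_top$p_value, 0.01)

  skipped <- mobility_abundance_test(tab, character(0))
  expect_true(skipped$skipped)
  expect_true(is.na(skipped$p_value))
  expect_match(skipped$reason, "mobile")

  td <- tidy(mt_top)
  expect_equal(td$top_k_overlap, 100L)
  expect_false(td$skipped)
})

test_that("coverage tracks conserve read mass and export valid bedGraph", {
  gene <- list(gene_id = "g1", chromosome = "c1", start = 201L, end = 900L)
  one <- tibble::tibble(read_id = "r1", chromosome = "c1", start = 300L,
                        width = 150L)
  tr <- coverage_track(one, gene)
  expect_equal(sum(tr$depth), 150L)
  expect_equal(range(tr$pos), c(201L, 900L))
  expect_equal(unique(tr$depth[tr$pos %in% 301:450]), 1L)
  expect_equal(unique(tr$depth[tr$pos < 301]), 0L)

  two <- dplyr::bind_rows(one, one)
  expect_equal(max(coverage_track(two, gene)$depth), 2L)

  set.seed(16)
  hits <- tibble::tibble(
    read_id = sprintf("r%03d", 1:80), chromosome = "c1",
    start = sample(100:850, 80, replace = TRUE), width = 150L)
  tr <- coverage_track(hits, gene)
  clipped <- pmin(hits$start + hits$width, gene$end) -
    pmax(hits$start + 1L, gene$start) + 1L
  expect_equal(sum(tr$depth), sum(pmax(clipped, 0L)))

  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  bg <- read.table(f, sep = "\t",
                   col.names = c("chrom", "start", "end", "depth"))
  expect_true(all(bg$end > bg$start))
  expect_true(all(bg$start[-1] == bg$end[-nrow(bg)]))  # non-overlapping
  expect_equal(sum((bg$end - bg$start) * bg$depth), sum(tr$depth))
})
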