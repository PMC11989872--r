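calls_from_sets <- function(rr, rl, up = character(0),
                            condition = "CK") {
  dplyr::bind_rows(
    tibble::tibble(gene_id = rr, genotype = "SCI", direction = "down",
                   tissue = "RR", condition = condition,
                   replicate_support = 3L),
    tibble::tibble(gene_id = rl, genotype = "SCI", direction = "down",
                   tissue = "RL", condition = condition,
                   replicate_support = 3L),
    tibble::tibble(gene_id = up, genotype = "ROO", direction = "up",
                   tissue = "HL", condition = condition,
                   replicate_support = 3L))
}

test_that("transport set algebra reproduces the published arithmetic", {
  shared <- sprintf("S%04d", 1:322)
  rr <- c(shared, sprintf("R%04d", 1:327))   # |RR| = 649
  rl <- c(shared, sprintf("L%04d", 1:341))   # |RL| = 663
  ts <- classify_transport(calls_from_sets(rr, rl))
  expect_equal(ts$n_rr, 649L)
  expect_equal(ts$n_rl, 663L)
  expect_equal(ts$n_through_root, 322L)
  expect_equal(ts$total_down, 990L)
  expect_equal(ts$n_rl_direct, 341L)
  expect_equal(ts$n_rr_only_degraded, 327L)
})

test_that("empty call sets give an all-zero summary", {
  ts <- classify_transport(calls_from_sets(character(0), character(0)))
  expect_equal(ts$total_down, 0L)
  expect_equal(ts$n_rl_direct, 0L)
  expect_equal(ts$n_rr_only_degraded, 0L)
  expect_equal(ts$n_through_root, 0L)
  expect_equal(ts$total_up, 0L)
})

test_that("summaries equal brute-force set enumeration on random inputs", {
  set.seed(606)
  pool <- sprintf("g%03d", 1:80)
  for (i in 1:200) {
    rr <- sample(pool, sample(0:40, 1))
    rl <- sample(pool, sample(0:40, 1))
    ts <- classify_transport(calls_from_sets(rr, rl))
    both <- length(intersect(rr, rl))
    expect_equal(ts$total_down, length(unique(c(rr, rl))))
    expect_equal(ts$n_through_root, both)
    expect_equal(ts$n_rl_direct, length(rl) - both)
    expect_equal(ts$n_rr_only_degraded, length(rr) - both)
    # inclusion-exclusion identities
    expect_equal(ts$n_rl_direct + ts$n_rr_only_degraded + ts$n_through_root,
                 ts$total_down)
  }
})

test_that("classification is order-independent and idempotent", {
  set.seed(7)
  calls <- calls_from_sets(sprintf("g%02d", 1:20), sprintf("g%02d", 11:25))
  shuffled <- calls[sample(nrow(calls)), ]
  a <- classify_transport(calls)
  b <- classify_transport(shuffled)
  expect_identical(glance(a), glance(b))
  expect_identical(a$rl_direct, b$rl_direct)
  expect_identical(glance(classify_transport(rbind(calls, calls))),
                   glance(a))
})

test_that("invalid direction-tissue combinations are rejected", {
  bad <- tibble::tibble(gene_id = "g1", genotype = "SCI",
                        direction = "down", tissue = "HL",
                        condition = "CK", replicate_support = 3L)
  expect_error(classify_transport(bad), "down")
})

test_that("condition Venn partitions and is symmetric in its arguments", {
  a <- calls_from_sets(sprintf("g%02d", 1:3), character(0))
  a <- a[a$tissue == "RR", ]
  b <- calls_from_sets(sprintf("h%02d", 1:4), character(0),
                       condition = "drought")
  b <- b[b$tissue == "RR", ]

  v <- condition_specific_sets(a, b)
  expect_equal(c(v$ck_only, v$drought_only, v$both), c(3L, 4L, 0L))
  sw <- condition_specific_sets(b, a)
  expect_equal(c(sw$ck_only, sw$drought_only), c(4L, 3L))

  same <- condition_specific_sets(a, a)
  expect_equal(c(same$ck_only, same$drought_only, same$both), c(0L, 0L, 3L))

  set.seed(11)
  pool <- sprintf("g%03d", 1:50)
  for (i in 1:50) {
    x <- calls_from_sets(sample(pool, 20), character(0))
    x <- x[x$tissue == "RR", ]
    y <- calls_from_sets(sample(pool, 15), character(0),
                         condition = "drought")
    y <- y[y$tissue == "RR", ]
    v <- condition_specific_sets(x, y)
    expect_equal(v$both, length(intersect(unique(x$gene_id),
                                          unique(y$gene_id))))
    expect_equal(v$ck_only + v$both, length(unique(x$gene_id)))
    expect_equal(v$drought_only + v$both, length(unique(y$gene_id)))
  }

  mixed <- calls_from_sets(sprintf("g%02d", 1:3), sprintf("g%02d", 4:6))
  expect_error(condition_specific_sets(mixed, b), "single tissue")
})
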