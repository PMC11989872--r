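test_that("index construction is complete, deterministic and validated", {
  ref25 <- seqs_as_reference(c(c1 = "ACGTACGTACGTACGTACGTACGTA"))
  idx <- build_index(ref25, 21)
  expect_equal(idx$n_kmers, 5)  # 25 - 21 + 1 forward positions

  ref <- seqs_as_reference(c(c1 = random_dna(500)))
  expect_identical(build_index(ref, 21)$core, build_index(ref, 21)$core)

  short <- seqs_as_reference(c(c1 = "ACGTACGTAC"))
  expect_error(build_index(short, 21), "shorter than k")
})

test_that("exact substrings map at distance 0; > k edits stay unmapped", {
  set.seed(77)
  seqs <- c(c1 = random_dna(4000))
  ref <- seqs_as_reference(seqs)
  idx <- build_index(ref, 21)

  rd <- substr(seqs[[1]], 1001, 1150)
  hit <- align_reads(setNames(rd, "r"), idx, ref, 2)$hits
  expect_equal(hit$edit_distance, 0L)
  expect_equal(hit$start, 1000L)  # 0-based
  expect_equal(hit$strand, "+")

  # three well-separated substitutions: oracle distance 3 > 2
  mut <- rd
  for (p in c(20, 75, 130)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  }
  expect_equal(oracle_edit_distance(mut, seqs), 3)
  res <- align_reads(setNames(mut, "r"), idx, ref, 2)
  expect_equal(nrow(res$hits), 0L)
  expect_equal(res$unmapped, "r")
})

test_that("reported distances equal the brute-force oracle on random suites", {
  set.seed(1234)
  n_agree <- 0L
  for (case in 1:150) {
    nchrom <- sample(1:2, 1)
    seqs <- setNames(
      vapply(seq_len(nchrom), function(i)
        random_dna(sample(200:3000, 1)), character(1)),
      paste0("c", seq_len(nchrom)))
    ref <- seqs_as_reference(seqs)
    idx <- build_index(ref, 21)
    L <- sample(c(40, 60, 100, 150), 1)
    src <- sample(nchrom, 1)
    rd <- if (runif(1) < 0.8 && nchar(seqs[src]) > L + 5) {
      st <- sample(nchar(seqs[src]) - L, 1)
      x <- substr(seqs[src], st, st + L - 1)
      ne <- sample(0:4, 1)
      if (ne > 0) {
        x <- mutate_seq(x, n_sub = sample(0:ne, 1),
                        n_ins = sample(0:1, 1), n_del = sample(0:1, 1))
      }
      if (runif(1) < 0.5) revcomp_chr(x) else x
    } else {
      random_dna(L)
    }
    k <- sample(0:2, 1)
    res <- align_reads(setNames(rd, "r"), idx, NULL, k)
    want <- oracle_edit_distance(rd, seqs)
    if (want <= k) {
      expect_equal(res$hits$edit_distance, want)
    } else {
      expect_equal(nrow(res$hits), 0L)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 150L)
})

test_that("the k = 1 mapped set is a subset of the k = 2 mapped set", {
  set.seed(99)
  seqs <- c(c1 = random_dna(5000))
  ref <- seqs_as_reference(seqs)
  idx <- build_index(ref, 21)
  reads <- vapply(1:120, function(i) {
    st <- sample(4800, 1)
    mutate_seq(substr(seqs[[1]], st, st + 149),
               n_sub = sample(0:3, 1), n_ins = sample(0:1, 1))
  }, character(1))
  r1 <- align_reads(reads_from_seqs(reads), idx, NULL, 1)
  r2 <- align_reads(reads_from_seqs(reads), idx, NULL, 2)
  expect_true(all(r1$hits$read_id %in% r2$hits$read_id))
  # and distances can only shrink or stay when k grows
  j <- dplyr::inner_join(r1$hits, r2$hits, by = "read_id")
  expect_true(all(j$edit_distance.y <= j$edit_distance.x))
})

test_that("reverse-complementing reads flips strand but not mapping", {
  set.seed(55)
  seqs <- c(c1 = random_dna(3000), c2 = random_dna(1500))
  ref <- seqs_as_reference(seqs)
  idx <- build_index(ref, 21)
  reads <- vapply(1:60, function(i) {
    ch <- sample(2, 1)
    st <- sample(nchar(seqs[ch]) - 150, 1)
    mutate_seq(substr(seqs[ch], st, st + 149), n_sub = sample(0:3, 1))
  }, character(1))
  fwd <- align_reads(reads_from_seqs(reads), idx, NULL, 2)
  rev <- align_reads(reads_from_seqs(revcomp_chr(reads)), idx, NULL, 2)
  expect_equal(sort(fwd$hits$read_id), sort(rev$hits$read_id))
  expect_equal(fwd$unmapped, rev$unmapped)
  j <- dplyr::inner_join(fwd$hits, rev$hits, by = "read_id")
  expect_true(all(j$edit_distance.x == j$edit_distance.y))
})

test_that("local search arbitrates verbatim, foreign and conserved reads", {
  set.seed(202)
  a <- c(c1 = random_dna(5000))
  b <- c(c1 = random_dna(5000))
  ref_a <- seqs_as_reference(a, "A")
  ref_b <- seqs_as_reference(b, "B")

  verbatim <- substr(a[[1]], 2001, 2150)
  res <- local_search(setNames(verbatim, "v"), ref_a, ref_b)
  expect_true(res$hit_a)
  expect_false(res$hit_b)
  expect_equal(res$identity_a, 100)

  rnd <- random_dna(150)
  res2 <- local_search(setNames(rnd, "x"), ref_a, ref_b)
  expect_false(res2$hit_a)
  expect_false(res2$hit_b)

  # a region present identically in both genotypes hits both
  shared <- substr(a[[1]], 101, 850)
  b2 <- c(c1 = paste0(substr(b[[1]], 1, 3000), shared))
  ref_b2 <- seqs_as_reference(b2, "B2")
  res3 <- local_search(setNames(substr(shared, 301, 450), "s"),
                       ref_a, ref_b2)
  expect_true(res3$hit_a)
  expect_true(res3$hit_b)
})

test_that("random reads essentially never pass the cross-check criterion", {
  # empirical false-hit calibration: 10,000 random 150-mers against a
  # ~100 kb reference
  set.seed(404)
  ref <- seqs_as_reference(c(c1 = random_dna(100000)))
  idx11 <- build_index(ref, 11)
  reads <- vapply(1:10000, function(i) random_dna(150), character(1))
  raw <- graftmobile:::gm_local_search(reads, idx11$core, 30L, 16L)
  hit <- raw$found & raw$aligned_fraction >= 0.9 & raw$identity >= 97.5
  expect_lt(mean(hit), 1e-3)
})
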