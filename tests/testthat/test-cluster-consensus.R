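test_that("naive clustering collapses, orders, and pads/trims", {
  rs <- read_set(c("AAAA", "AAAT", "AAAA", "AAAA"))
  cs <- naive_cluster(rs, L = 4)
  expect_equal(cs$sequences, c("AAAA", "AAAT"))
  expect_equal(cs$sizes, c(3L, 1L))
  # permutation invariance
  rs2 <- read_set(c("AAAT", "AAAA", "AAAA", "AAAA"))
  expect_identical(naive_cluster(rs2, 4), cs)
  # pad/trim to the design length with a fixed pad base
  rs3 <- read_set(c("ACGTGG", "ACG"))
  cs3 <- naive_cluster(rs3, L = 4)
  expect_setequal(cs3$sequences, c("ACGT", "ACGA"))
  # noiseless reads collapse to exactly the references
  pool <- random_pool(10, 30, seed = 2)
  reads <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0), copies = 30, seed = 1))
  cs4 <- naive_cluster(reads, 30)
  expect_setequal(cs4$sequences, pool$sequences)
  expect_equal(cs4$sizes, rep(30L, 10))
})

test_that("MinHash clustering groups same-origin reads without mixing", {
  pool <- random_pool(50, 150, seed = 42)
  reads <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0.02), copies = 30, seed = 3))
  cl <- lsh_cluster(reads, seed = 1)
  expect_gte(length(cl), 50)
  expect_lte(length(cl), 1.2 * 50)
  # zero clusters mixing two origins (ground-truth oracle)
  omap <- setNames(reads$origins, reads$sequences)
  mixed <- vapply(cl, function(x) length(unique(omap[x$members])) > 1,
                  logical(1))
  expect_equal(sum(mixed), 0L)
})

test_that("MinHash degenerate cases behave", {
  rs <- read_set(c("ACGTACGTACGT", "ACGTACGTACGT"))
  cl <- lsh_cluster(rs, k = 4)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$size, 2L)
  expect_error(lsh_cluster(read_set("ACGTA"), k = 6), "smaller")
  # tau = 1 with noisy reads degenerates toward unique sequences
  pool <- random_pool(5, 60, seed = 4)
  reads <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0.05), copies = 10, seed = 5))
  cl1 <- lsh_cluster(reads, tau = 1.0, seed = 1)
  n_unique <- length(unique(reads$sequences))
  expect_gte(length(cl1), 0.9 * n_unique)
})

test_that("consensus calling is exact for unanimity and majority", {
  expect_equal(call_consensus(rep("ACGTAC", 3), 6), "ACGTAC")
  m <- c(rep("ACGTACGTACGT", 29), "ACGTACCTACGT")
  expect_equal(call_consensus(m, 12), "ACGTACGTACGT")
  # indels: deletion and insertion variants are outvoted
  m2 <- c(rep("ACGTACGT", 5), "ACGACGT", "ACGTTACGT")
  expect_equal(call_consensus(m2, 8), "ACGTACGT")
  # abundance weighting: 3 identical copies beat 2 distinct reads
  cl <- list(members = c("AAAA", "TTTT"), abundance = c(3L, 2L))
  expect_equal(call_consensus(cl, 4), "AAAA")
})

test_that("consensus recovers references at 4% error with 30 copies", {
  pool <- random_pool(100, 150, seed = 42)
  reads <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0.04), copies = 30, seed = 7))
  recovered <- 0L
  for (i in 1:100) {
    memb <- reads$sequences[reads$origins == i]
    recovered <- recovered +
      (call_consensus(memb, 150) == pool$sequences[i])
  }
  expect_gte(recovered, 99L)
})

test_that("consensus error rate does not increase with coverage", {
  pool <- random_pool(40, 100, seed = 11)
  errs <- vapply(c(5, 15, 45), function(cc) {
    reads <- run_basic_scenario(pool, basic_scenario_params(
      error_spec(0.04), copies = cc, seed = 13))
    bad <- 0L
    for (i in 1:40) {
      memb <- reads$sequences[reads$origins == i]
      bad <- bad + (call_consensus(memb, 100) != pool$sequences[i])
    }
    bad
  }, integer(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("clustering metrics match their printed definitions", {
  # perfect recovery
  pool <- random_pool(8, 40, seed = 6)
  m <- evaluate_clustering(consensus_set(pool$sequences, L = 40), pool)
  expect_equal(c(m$sensitivity, m$accuracy, m$specificity), c(1, 1, 1))
  # worked two-reference example (fixed by the recorded conventions)
  m2 <- evaluate_clustering(consensus_set("ACCT", L = 4),
                            reference_pool(c("ACGT", "TTTT")))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$accuracy, 0.5)     # mean(0.75, 0.25)
  expect_equal(m2$specificity, 1.0)
  expect_equal(m2$assignment, 1L)
  # 10 references, 20 consensus sequences all nearest to reference 1
  refs <- random_pool(10, 40, seed = 7)
  cons <- consensus_set(rep(refs$sequences[1], 20), L = 40)
  m3 <- evaluate_clustering(cons, refs)
  expect_equal(m3$sensitivity, 0.1)
  expect_equal(m3$specificity, 0.05)
})

test_that("metric distances equal an independent DP oracle", {
  oligobench:::with_seed(15, {
    a <- vapply(1:12, function(i) paste(
      sample(c("A", "C", "G", "T"), sample(8:14, 1), replace = TRUE),
      collapse = ""), character(1))
    b <- vapply(1:10, function(i) paste(
      sample(c("A", "C", "G", "T"), sample(8:14, 1), replace = TRUE),
      collapse = ""), character(1))
  })
  d_pkg <- adist(a, b)
  d_oracle <- outer(seq_along(a), seq_along(b),
                    Vectorize(function(i, j) dp_levenshtein(a[i], b[j])))
  expect_equal(unname(d_pkg), d_oracle)
  # similarity convention: 1 - d / max(length)
  s <- levenshtein_similarity(a, b)
  expect_equal(unname(s),
               1 - d_oracle / outer(nchar(a), nchar(b), pmax))
})

test_that("error-free reads reproduce the pool through any clusterer", {
  pool <- random_pool(20, 80, seed = 9)
  reads <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0), copies = 10, seed = 2))
  for (cs in list(naive_cluster(reads, 80),
                  consensus_from_clusters(lsh_cluster(reads, seed = 1),
                                          80))) {
    m <- evaluate_clustering(cs, pool)
    expect_equal(c(m$sensitivity, m$accuracy, m$specificity), c(1, 1, 1))
  }
})
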