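test_that("error specs validate their composition", {
  expect_error(error_spec(0.01, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(error_spec(-0.1), "rate")
  s <- error_spec(0.05)
  expect_equal(unname(s$composition), c(0.53, 0.45, 0.02))
})

test_that("zero-rate and all-deletion limits behave exactly", {
  expect_identical(inject_errors("ACGTACGT", error_spec(0), seed = 1),
                   "ACGTACGT")
  expect_identical(inject_errors(character(0), error_spec(0.5)),
                   character(0))
  expect_identical(inject_errors("ACGTACGT", error_spec(1, c(0, 1, 0)),
                                 seed = 1), "")
})

test_that("per-type error counts match the generative model", {
  # 1e5 positions at r = 0.05, composition 53:45:2: expected per-type
  # counts (2650, 2250, 100); each within 4 binomial sd
  n <- 1e5
  spec <- error_spec(0.05)
  ops <- oligobench:::with_seed(11,
    oligobench:::draw_error_events(n, spec))
  counts <- tabulate(ops, nbins = 3)
  expected <- n * spec$rate * spec$composition
  sds <- sqrt(n * spec$rate * spec$composition *
                (1 - spec$rate * spec$composition))
  expect_true(all(abs(counts - expected) < 4 * sds))
  # chi-square goodness of fit of the type split is not rejected
  pval <- chisq.test(counts, p = spec$composition)$p.value
  expect_gt(pval, 0.001)
})

test_that("substitutions never reproduce the original base", {
  out <- inject_errors(strrep("A", 5000), error_spec(1, c(1, 0, 0)),
                       seed = 2)
  expect_false(grepl("A", out))
  expect_equal(nchar(out), 5000)
})

test_that("insertions add a base before the template position", {
  out <- inject_errors("AAAA", error_spec(1, c(0, 0, 1)), seed = 3)
  expect_equal(nchar(out), 8)
  # template bases are all retained
  expect_equal(nchar(gsub("[^A]", "", out)), 4)
})

test_that("basic scenario: noiseless channel copies the references", {
  pool <- random_pool(100, 40, seed = 5)
  rs <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0), copies = 30, seed = 1))
  expect_equal(sum(rs$abundance), 3000)
  expect_equal(read_depth(rs), 30)
  expect_true(all(rs$sequences == pool$sequences[rs$origins]))
})

test_that("basic scenario: dropout removes the stated fraction", {
  pool <- random_pool(100, 40, seed = 5)
  rs <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0.01), copies = 30, dropout = 0.25, seed = 2))
  expect_equal(length(unique(rs$origins)), 75)
  expect_error(basic_scenario_params(error_spec(0), dropout = 1),
               "dropout")
})

test_that("basic scenario is deterministic per seed", {
  pool <- random_pool(10, 40, seed = 5)
  p <- basic_scenario_params(error_spec(0.1), copies = 1, dropout = 0.5,
                             seed = 9)
  expect_identical(run_basic_scenario(pool, p),
                   run_basic_scenario(pool, p))
})

test_that("downsampling is exact, seeded, and bounded", {
  pool <- random_pool(100, 40, seed = 5)
  rs <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0), copies = 30, seed = 1))
  expect_equal(sum(downsample_reads(rs, 30, seed = 1)$abundance), 3000)
  down <- downsample_reads(rs, 1, seed = 1)
  expect_equal(sum(down$abundance), 100)
  expect_identical(down, downsample_reads(rs, 1, seed = 1))
  expect_error(downsample_reads(rs, 31, seed = 1), "available")
})
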