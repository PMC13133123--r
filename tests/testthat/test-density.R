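test_that("storage densities reproduce the printed values", {
  sig2 <- function(x) signif(x, 2)
  # theoretical dsDNA maximum: 2 bit/nt at one copy per sequence
  expect_equal(sig2(storage_density(2, 1)$density_EB_per_g), 230)
  expect_equal(round(storage_density(2, 1)$density_EB_per_g), 227)
  # no-ECC baseline relying on clustering: 1.85 bit/nt at 32x
  expect_equal(sig2(storage_density(1.85, 32)$density_EB_per_g), 6.6)
  # fountain-style codec: 1.00 bit/nt at 7.6x
  expect_equal(sig2(storage_density(1.00, 7.6)$density_EB_per_g), 15)
  # 1.07 bit/nt at 3.2x
  expect_equal(sig2(storage_density(1.07, 3.2)$density_EB_per_g), 38)
})

test_that("density is monotone in its arguments", {
  d <- function(...) storage_density(...)$density_EB_per_g
  expect_gt(d(1.5, 10), d(1.0, 10))    # increasing in rate
  expect_lt(d(1.0, 20), d(1.0, 10))    # decreasing in redundancy
  expect_lt(d(1.0, 10, mw = 700), d(1.0, 10, mw = 662))
  expect_error(storage_density(0, 1), "positive")
})

test_that("the adapter basis scales by the payload fraction", {
  full <- storage_density(1, 1)$density_EB_per_g
  withad <- storage_density(1, 1, basis = "with_adapters",
                            payload_nt = 126, total_nt = 170)
  expect_equal(withad$density_EB_per_g, full * 126 / 170)
})

test_that("redundancy from mass follows the molar arithmetic", {
  # 1 ng of an 11293-sequence pool of 170 bp dsDNA at 662 g/mol/bp
  r <- redundancy_mass(11293, 170, mass_ng = 1)
  expect_equal(r, 1e-9 * 6.02214076e23 / (11293 * 170 * 662))
  expect_equal(signif(r, 2), 4.7e5)
  # linear in mass
  expect_equal(redundancy_mass(11293, 170, mass_ng = 2), 2 * r)
  expect_error(redundancy_mass(0, 170, 1), "positive")
})

test_that("error profiling is exact on clean reads and recovers rates", {
  pool <- random_pool(20, 100, seed = 2)
  clean <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0), copies = 10, seed = 1))
  ep <- analyze_error_rates(clean, pool)
  expect_equal(ep$rate_overall, 0)
  expect_equal(ep$dropout, 0)
  expect_equal(ep$coverage_cv, 0)

  # parameter recovery at r = 0.01, 53:45:2, >= 1e5 aligned nt
  pool2 <- random_pool(70, 150, seed = 3)
  noisy <- run_basic_scenario(pool2, basic_scenario_params(
    error_spec(0.01), copies = 10, seed = 6))
  ep2 <- analyze_error_rates(noisy, pool2)
  n_nt <- sum(ep2$per_reference_counts) * 150
  expect_gte(n_nt, 1e5)
  expected <- 0.01 * c(0.53, 0.45, 0.02)
  got <- c(ep2$rate_sub, ep2$rate_del, ep2$rate_ins)
  sds <- sqrt(expected * (1 - expected) / n_nt)
  expect_true(all(abs(got - expected) < 4 * sds))
  expect_equal(ep2$rate_overall, sum(got))
})

test_that("reads without origins are assigned by nearest reference", {
  pool <- random_pool(10, 80, seed = 4)
  noisy <- run_basic_scenario(pool, basic_scenario_params(
    error_spec(0.02), copies = 5, seed = 2))
  anon <- read_set(noisy$sequences, pool_size = 10)
  ep <- analyze_error_rates(anon, pool)
  ep_truth <- analyze_error_rates(noisy, pool)
  expect_equal(ep$rate_overall, ep_truth$rate_overall, tolerance = 0.1)
  expect_error(analyze_error_rates(read_set(character(0)), pool), "empty")
})

test_that("coverage CV summarizes per-reference counts", {
  rs <- read_set(rep(c("ACGT", "AAAA", "TTTT", "GGGG"), 10),
                 origins = rep(1:4, 10), pool_size = 4)
  pool <- reference_pool(c("ACGT", "AAAA", "TTTT", "GGGG"))
  expect_equal(analyze_error_rates(rs, pool)$coverage_cv, 0)
})
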