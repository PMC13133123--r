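test_that("the adaptive scan recovers a deterministic step threshold", {
  est <- adaptive_scan(function(x) x <= 0.05, c(0.001, 0.4))
  expect_equal(nrow(est$outcomes), 30L)       # exactly 30 trials
  expect_gt(est$threshold, 0.05 / 1.25)
  expect_lt(est$threshold, 0.05 * 1.25)
})

test_that("censored scans pin the threshold to the range ends", {
  est_s <- adaptive_scan(function(x) TRUE, c(0.001, 0.4))
  expect_equal(est_s$censoring, "all_success")
  expect_equal(est_s$threshold, 0.4)
  est_f <- adaptive_scan(function(x) FALSE, c(0.001, 0.4))
  expect_equal(est_f$censoring, "all_fail")
  expect_equal(est_f$threshold, 0.001)
  # harder-is-smaller flips the pinned end
  est_s2 <- adaptive_scan(function(x) TRUE, c(0.001, 0.4),
                          direction = "harder-is-smaller")
  expect_equal(est_s2$threshold, 0.001)
  expect_error(adaptive_scan(function(x) TRUE, c(0.4, 0.001)), "range")
})

test_that("separation falls back to a threshold strictly inside the gap", {
  fe <- fit_logistic_threshold(c(0.01, 0.02, 0.08, 0.16),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(fe$separation)
  expect_gt(fe$threshold, 0.02)
  expect_lt(fe$threshold, 0.08)
  # single success below all failures
  fe2 <- fit_logistic_threshold(c(0.01, 0.04, 0.08),
                                c(TRUE, FALSE, FALSE))
  expect_gt(fe2$threshold, 0.01)
  expect_lt(fe2$threshold, 0.04)
  # all-same outcomes are censored, no fit
  fe3 <- fit_logistic_threshold(c(0.1, 0.2), c(TRUE, TRUE))
  expect_equal(fe3$censoring, "all_success")
})

test_that("mixed outcomes cross inside the success/failure gap", {
  x <- c(0.01, 0.015, 0.02, 0.03, 0.05, 0.08, 0.1, 0.2)
  y <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  fe <- fit_logistic_threshold(x, y)
  expect_equal(fe$censoring, "none")
  expect_false(fe$separation)
  expect_gt(fe$threshold, 0.01)
  expect_lt(fe$threshold, 0.1)
})

test_that("threshold estimates are equivariant under axis rescaling", {
  e1 <- adaptive_scan(function(x) x <= 0.05, c(0.001, 0.4))
  e2 <- adaptive_scan(function(x) x <= 5, c(0.1, 40))
  expect_equal(e2$threshold / e1$threshold, 100, tolerance = 1e-8)
})

test_that("run_trial executes the full pipeline and isolates failures", {
  payload <- generate_payload(100, seed = 1)
  cdc <- baseline_codec(40)
  noiseless <- function(pool, x, seed) {
    run_basic_scenario(pool, basic_scenario_params(
      error_spec(0), copies = 5, seed = seed))
  }
  out <- run_trial(cdc, noiseless, make_clusterer("naive"), payload, 0)
  expect_true(out$success)
  expect_true(all(out$stage_s[c("encode", "channel", "cluster",
                                "decode")] >= 0))
  # a crashing channel becomes a failure outcome, not an exception
  crash <- function(pool, x, seed) stop("boom")
  out2 <- run_trial(cdc, crash, NULL, payload, 0)
  expect_false(out2$success)
  expect_match(out2$diagnostics$reason, "channel")
})

test_that("a decoder sleeping past the wall limit fails with a timeout", {
  sleeper <- oligobench:::new_codec(
    "sleeper", list(),
    fn_encode = function(data, params)
      list(sequences = strrep("A", 20), meta = list()),
    fn_decode = function(cand, params, meta) {
      Sys.sleep(5)
      decode_result("failure")
    })
  payload <- generate_payload(10, seed = 1)
  noiseless <- function(pool, x, seed) read_set(pool$sequences)
  out <- run_trial(sleeper, noiseless, NULL, payload, 0,
                   limits = resource_limits(wall_s = 1))
  expect_false(out$success)
  expect_match(out$diagnostics$reason, "timeout")
})

test_that("dropout just beyond the outer bound fails the trial", {
  cdc <- rs_codec(L = 48, inner_parity = 4, outer_n = 7, outer_k = 4)
  payload <- generate_payload(20, seed = 4)
  channel <- function(pool, x, seed) {
    run_basic_scenario(pool, basic_scenario_params(
      error_spec(0), copies = 5, dropout = x, seed = seed))
  }
  # 3/7 dropped is within the bound, 4/7 beyond it
  expect_true(run_trial(cdc, channel, make_clusterer("naive"), payload,
                        3 / 7 - 0.01)$success)
  expect_false(run_trial(cdc, channel, make_clusterer("naive"), payload,
                         4 / 7 - 0.01)$success)
})
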