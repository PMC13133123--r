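# The evaluation engine: resource-limited decode trials, logistic
# 95%-success threshold estimation, and the three-stage adaptive
# one-dimensional sensitivity analysis.

#' Resource limits for a decode trial
#'
#' Each pipeline stage is limited to `wall_s` seconds of wall time; any
#' violation (or a component crash) converts the trial outcome into a
#' failure, never an exception.  The memory limit is enforced for
#' subprocess (external-codec) stages and advisory for in-process
#' stages; `cores` is fixed at 1.  The benchmark-scale limits are one
#' hour and 8 GiB per stage; `test_limits()` gives small limits for
#' quick runs.
#'
#' @param wall_s Wall-clock seconds per stage.
#' @param mem_bytes Memory limit in bytes.
#' @param cores CPU cores (always 1).
#' @return A `resource_limits` object.
#' @export
resource_limits <- function(wall_s = 3600, mem_bytes = 8 * 1024^3,
                            cores = 1L) {
  stopifnot(wall_s > 0, mem_bytes > 0, cores == 1L)
  structure(list(wall_s = wall_s, mem_bytes = mem_bytes, cores = 1L),
            class = "resource_limits")
}

#' @rdname resource_limits
#' @export
test_limits <- function() resource_limits(wall_s = 60, mem_bytes = 1024^3)

with_stage_limit <- function(limits, expr) {
  setTimeLimit(elapsed = limits$wall_s, transient = TRUE)
  on.exit(setTimeLimit(elapsed = Inf))
  expr
}

#' Run one resource-limited decode trial
#'
#' Executes encode -> channel -> cluster/consensus -> decode and reports
#' a `trial_outcome`.  Success means byte-identical payload recovery
#' with every stage inside its wall-time limit.  Component errors and
#' timeouts become failures with a diagnostic; no exception escapes the
#' harness.
#'
#' @param codec A codec object.
#' @param channel_fn `function(pool, x, seed) -> read_set`: the channel
#'   at parameter value `x`.
#' @param clusterer `function(read_set, L) -> consensus_set` (e.g. built
#'   by [make_clusterer()]), or `NULL` to feed raw reads to the decoder.
#' @param payload A [generate_payload()] object.
#' @param x Parameter value under test.
#' @param limits A [resource_limits()].
#' @param seed Integer seed for the channel.
#' @return A `trial_outcome`: list with `x`, `success`, `runtime_s`,
#'   `stage_s` and `diagnostics`.
#' @export
run_trial <- function(codec, channel_fn, clusterer, payload, x,
                      limits = test_limits(), seed = 1L) {
  t_all <- proc.time()[["elapsed"]]
  stage_s <- c(encode = NA_real_, channel = NA_real_, cluster = NA_real_,
               decode = NA_real_)
  fail <- function(reason) {
    structure(list(x = x, success = FALSE,
                   runtime_s = proc.time()[["elapsed"]] - t_all,
                   stage_s = stage_s,
                   diagnostics = list(reason = reason)),
              class = "trial_outcome")
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(with_stage_limit(limits, fun()),
                    error = function(e) {
                      msg <- conditionMessage(e)
                      structure(list(msg = if (grepl("elapsed time limit", msg))
                        paste0(name, " timeout") else paste0(name, ": ", msg)),
                        class = "stage_error")
                    })
    stage_s[[name]] <<- proc.time()[["elapsed"]] - t0
    if (stage_s[[name]] > limits$wall_s && !inherits(out, "stage_error")) {
      out <- structure(list(msg = paste0(name, " timeout")),
                       class = "stage_error")
    }
    out
  }
  enc <- stage("encode", function() codec_encode(codec, payload))
  if (inherits(enc, "stage_error")) return(fail(enc$msg))
  reads <- stage("channel", function() channel_fn(enc$pool, x, seed))
  if (inherits(reads, "stage_error")) return(fail(reads$msg))
  if (length(reads$sequences) == 0L) return(fail("channel produced no reads"))
  cons <- if (is.null(clusterer)) reads else {
    stage("cluster", function() clusterer(reads, enc$pool$length))
  }
  if (inherits(cons, "stage_error")) return(fail(cons$msg))
  res <- stage("decode", function() codec_decode(codec, cons, enc$meta))
  if (inherits(res, "stage_error")) return(fail(res$msg))
  structure(list(x = x, success = res$status == "success",
                 runtime_s = proc.time()[["elapsed"]] - t_all,
                 stage_s = stage_s, diagnostics = res$diagnostics),
            class = "trial_outcome")
}

#' Build a clusterer function for [run_trial()]
#'
#' @param method `"naive"` or `"lsh"`.
#' @param ... Parameters passed to [lsh_cluster()].
#' @return `function(read_set, L) -> consensus_set`.
#' @export
make_clusterer <- function(method = c("naive", "lsh"), ...) {
  method <- match.arg(method)
  args <- list(...)
  if (method == "naive") {
    function(readset, L) naive_cluster(readset, L)
  } else {
    function(readset, L) {
      cl <- do.call(lsh_cluster, c(list(readset = readset), args))
      consensus_from_clusters(cl, L)
    }
  }
}

#' Fit the logistic 95%-success threshold
#'
#' Maximum-likelihood logistic regression of trial success on
#' `log(x)`; the threshold `t` solves
#' `plogis(b0 + b1 * log t) = p_star`.  On complete separation (every
#' success strictly easier than every failure, where the MLE diverges)
#' the fit falls back to interpolation between the extreme success and
#' failure points: the `p_star`-quantile of the log-linear interpolant
#' across the gap, `t = s^p_star * f^(1 - p_star)` for the
#' harder-is-larger direction.  This lands strictly inside the gap and,
#' unlike the gap midpoint (the 50% point), respects that a 95%-success
#' threshold should sit close to the last observed success.  When
#' all outcomes agree the result is censored (`all_success` /
#' `all_fail`) with the threshold pinned to the relevant range end.
#'
#' @param x Parameter values tested.
#' @param success Logical outcomes.
#' @param p_star Target success probability (default 0.95).
#' @param direction `"harder-is-larger"` (success probability falls with
#'   `x`; e.g. error rate, dropout) or `"harder-is-smaller"` (e.g.
#'   redundancy, depth).
#' @param range Optional `c(min, max)` used to pin censored estimates
#'   and clip the threshold.
#' @return A `threshold_estimate`: list with `threshold`, `b0`, `b1`,
#'   `censoring` (`"none"`, `"all_success"`, `"all_fail"`),
#'   `separation` flag, and the outcomes.
#' @export
fit_logistic_threshold <- function(x, success, p_star = 0.95,
                                   direction = c("harder-is-larger",
                                                 "harder-is-smaller"),
                                   range = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(success), length(x) >= 1L, all(x > 0))
  success <- as.logical(success)
  rng <- range %||% c(min(x), max(x))
  easy_end <- if (direction == "harder-is-larger") rng[1L] else rng[2L]
  hard_end <- if (direction == "harder-is-larger") rng[2L] else rng[1L]
  out <- function(t, b0 = NA_real_, b1 = NA_real_, censoring = "none",
                  separation = FALSE) {
    structure(list(threshold = t, b0 = b0, b1 = b1, censoring = censoring,
                   separation = separation,
                   outcomes = data.frame(x = x, success = success)),
              class = "threshold_estimate")
  }
  if (all(success)) return(out(hard_end, censoring = "all_success"))
  if (!any(success)) return(out(easy_end, censoring = "all_fail"))
  lx <- log(x)
  # complete separation: every success strictly easier than every failure
  sep <- if (direction == "harder-is-larger") {
    max(lx[success]) < min(lx[!success])
  } else {
    min(lx[success]) > max(lx[!success])
  }
  if (sep) {
    bound_s <- if (direction == "harder-is-larger") max(lx[success])
               else min(lx[success])
    bound_f <- if (direction == "harder-is-larger") min(lx[!success])
               else max(lx[!success])
    t <- exp(p_star * bound_s + (1 - p_star) * bound_f)
    return(out(clip(t, rng), separation = TRUE))
  }
  fit <- suppressWarnings(glm(success ~ lx, family = binomial()))
  b <- coef(fit)
  if (anyNA(b) || abs(b[2L]) < 1e-12) {
    # degenerate fit (e.g. all x identical): fall back to the boundary
    return(out(clip(exp(mean(lx)), rng), separation = TRUE))
  }
  t <- exp((qlogis(p_star) - b[[1L]]) / b[[2L]])
  out(clip(t, rng), b0 = b[[1L]], b1 = b[[2L]])
}

clip <- function(x, rng) min(max(x, rng[1L]), rng[2L])

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> t = %.4g (censoring: %s%s)\n",
              x$threshold, x$censoring,
              if (isTRUE(x$separation)) ", separation fallback" else ""))
  invisible(x)
}

#' Three-stage adaptive sensitivity scan
#'
#' Stage 1 evaluates the trial function at 10 logarithmically spaced
#' points across the full parameter range and fits a rough threshold;
#' stages 2 and 3 each add 10 log-spaced points over `[t/2, 2t]` around
#' the current estimate (clipped to the range; if the current fit is
#' censored, the refinement window defaults to the hardest decade of the
#' range).  The final logistic fit uses all 30 outcomes and reports the
#' parameter value at 95% success probability.  Exactly 30 trials are
#' issued.
#'
#' @param trial_fn `function(x) -> logical` (or anything with a
#'   `success` element, e.g. a `trial_outcome`).
#' @param range `c(x_min, x_max)`, `0 < x_min < x_max`.
#' @param direction See [fit_logistic_threshold()].
#' @param p_star Target success probability (default 0.95).
#' @return A `threshold_estimate` with all 30 outcomes.
#' @export
#' @examples
#' est <- adaptive_scan(function(x) x <= 0.05, c(0.001, 0.4))
#' est$threshold  # close to 0.05
adaptive_scan <- function(trial_fn, range,
                          direction = c("harder-is-larger",
                                        "harder-is-smaller"),
                          p_star = 0.95) {
  direction <- match.arg(direction)
  if (!(is.numeric(range) && length(range) == 2L && range[1L] > 0 &&
        range[1L] < range[2L])) {
    stop("`range` must be c(x_min, x_max) with 0 < x_min < x_max")
  }
  eval_points <- function(xs) {
    vapply(xs, function(x) {
      r <- trial_fn(x)
      if (is.list(r)) isTRUE(r$success) else isTRUE(r)
    }, logical(1))
  }
  log_space <- function(lo, hi, n = 10L) exp(seq(log(lo), log(hi),
                                                 length.out = n))
  refine_window <- function(est) {
    if (est$censoring != "none") {
      # refine in the hardest decade of the range
      if (direction == "harder-is-larger") {
        c(max(range[2L] / 10, range[1L]), range[2L])
      } else {
        c(range[1L], min(range[1L] * 10, range[2L]))
      }
    } else {
      t <- est$threshold
      c(max(t / 2, range[1L]), min(2 * t, range[2L]))
    }
  }
  xs <- log_space(range[1L], range[2L])
  ok <- eval_points(xs)
  for (stage in 2:3) {
    est <- fit_logistic_threshold(xs, ok, p_star, direction, range)
    w <- refine_window(est)
    xs_new <- log_space(w[1L], w[2L])
    xs <- c(xs, xs_new)
    ok <- c(ok, eval_points(xs_new))
  }
  fit_logistic_threshold(xs, ok, p_star, direction, range)
}
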