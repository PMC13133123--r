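# Convenience wrappers wiring codec + channel + clusterer into the
# three standard one-dimensional sensitivity analyses: error rate,
# sequence dropout, and a workflow parameter (physical redundancy or
# sequencing depth).

#' Standard sensitivity scans
#'
#' Each scan runs the full pipeline (encode, channel at the scanned
#' parameter value, cluster/consensus, decode) through the three-stage
#' [adaptive_scan()] and reports the 95%-success threshold.
#'
#' `scan_error_rate()` scans the overall error rate of the basic
#' iid channel (53:45:2 substitutions:deletions:insertions by default);
#' `scan_dropout()` scans the fraction of reference sequences removed
#' (error-free reads); `scan_workflow()` scans physical redundancy or
#' sequencing depth of the multi-stage workflow channel with the other
#' held fixed.
#'
#' @param codec A codec object.
#' @param payload A [generate_payload()] object.
#' @param clusterer Clusterer function from [make_clusterer()], or
#'   `NULL` for raw reads.
#' @param copies Reads per surviving sequence (default 30).
#' @param range Scanned parameter range `c(min, max)`.
#' @param composition Error composition for the basic channel.
#' @param param `"redundancy"` or `"depth"` for `scan_workflow()`.
#' @param workflow A [workflow_params()] carrying the fixed parameters
#'   (its scanned field is overwritten).
#' @param limits A [resource_limits()].
#' @param seed Integer root seed (each trial derives its own stream).
#' @return A `threshold_estimate` (see [fit_logistic_threshold()]).
#' @export
scan_error_rate <- function(codec, payload, clusterer = NULL,
                            copies = 30L, range = c(0.001, 0.40),
                            composition = c(0.53, 0.45, 0.02),
                            limits = test_limits(), seed = 1L) {
  i <- 0L
  channel <- function(pool, x, s) {
    run_basic_scenario(pool, basic_scenario_params(
      error_spec(x, composition), copies = copies, seed = s))
  }
  adaptive_scan(function(x) {
    i <<- i + 1L
    run_trial(codec, channel, clusterer, payload, x, limits,
              seed = derive_seed(seed, paste0("err", i)))
  }, range, direction = "harder-is-larger")
}

#' @rdname scan_error_rate
#' @export
scan_dropout <- function(codec, payload, clusterer = NULL, copies = 30L,
                         range = c(0.005, 0.99), limits = test_limits(),
                         seed = 1L) {
  i <- 0L
  channel <- function(pool, x, s) {
    run_basic_scenario(pool, basic_scenario_params(
      error_spec(0), copies = copies, dropout = x, seed = s))
  }
  adaptive_scan(function(x) {
    i <<- i + 1L
    run_trial(codec, channel, clusterer, payload, x, limits,
              seed = derive_seed(seed, paste0("drop", i)))
  }, range, direction = "harder-is-larger")
}

#' @rdname scan_error_rate
#' @export
scan_workflow <- function(codec, payload, clusterer = NULL,
                          param = c("redundancy", "depth"),
                          workflow = workflow_params("high_fidelity"),
                          range = c(0.2, 100), limits = test_limits(),
                          seed = 1L) {
  param <- match.arg(param)
  i <- 0L
  channel <- function(pool, x, s) {
    wp <- workflow
    wp[[param]] <- x
    wp$seed <- s
    run_workflow(pool, wp)
  }
  adaptive_scan(function(x) {
    i <<- i + 1L
    run_trial(codec, channel, clusterer, payload, x, limits,
              seed = derive_seed(seed, paste0("wf", i)))
  }, range, direction = "harder-is-smaller")
}
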