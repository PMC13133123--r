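# Replications of the three common literature benchmark protocols:
# serial dilution (iterative 10x dilutions to probe maximum storage
# density), serial amplification (deep re-amplification to demonstrate
# copyability) and read down-sampling (minimum sequencing depth).  Each
# iteration is tested ten times with distinct seeds; the highest
# iteration count at which all ten tests decode successfully is
# reported, stopping at the first failing iteration.

#' Run a literature benchmark protocol
#'
#' @param codec A codec object.
#' @param protocol `"serial_dilution"`, `"serial_amplification"` or
#'   `"downsampling"`.
#' @param payload A [generate_payload()] object.
#' @param clusterer Clusterer function from [make_clusterer()] (or
#'   `NULL` for raw reads).
#' @param base_params A [workflow_params()] giving the workflow before
#'   iteration 1 modifications (defaults to the high-fidelity scenario,
#'   as in the original experiments).
#' @param dilution_factor Per-iteration dilution factor (default 10).
#' @param extra_cycles Per-iteration additional PCR cycles for
#'   `serial_amplification` (default 10).
#' @param depth_grid Decreasing sequencing depths for `downsampling`
#'   (default `c(30, 10, 5, 2, 1)`).
#' @param max_iter Maximum iteration count probed.
#' @param n_rep Tests per iteration (default 10).
#' @param limits A [resource_limits()].
#' @param seed Integer root seed.
#' @return A `protocol_result`: list with `highest_pass` (0 when even
#'   iteration 1 fails), `per_iteration` (successes out of `n_rep`), and
#'   the iteration parameter values.
#' @export
literature_protocol <- function(codec,
                                protocol = c("serial_dilution",
                                             "serial_amplification",
                                             "downsampling"),
                                payload,
                                clusterer = make_clusterer("lsh"),
                                base_params = workflow_params("high_fidelity"),
                                dilution_factor = 10,
                                extra_cycles = 10L,
                                depth_grid = c(30, 10, 5, 2, 1),
                                max_iter = 6L,
                                n_rep = 10L,
                                limits = test_limits(),
                                seed = 1L) {
  protocol <- match.arg(protocol)
  iter_params <- function(i) {
    p <- base_params
    switch(protocol,
      serial_dilution = {
        p$redundancy <- base_params$redundancy / dilution_factor^(i - 1L)
      },
      serial_amplification = {
        p$pcr2_cycles <- base_params$pcr2_cycles + extra_cycles * (i - 1L)
      },
      downsampling = {
        p$depth <- depth_grid[i]
      })
    p
  }
  n_iter <- if (protocol == "downsampling") {
    min(max_iter, length(depth_grid))
  } else max_iter
  per_iter <- integer(0)
  values <- numeric(0)
  highest <- 0L
  for (i in seq_len(n_iter)) {
    p_i <- iter_params(i)
    values[i] <- switch(protocol,
                        serial_dilution = p_i$redundancy,
                        serial_amplification = p_i$pcr2_cycles,
                        downsampling = p_i$depth)
    ok <- 0L
    for (rep in seq_len(n_rep)) {
      out <- run_trial(codec,
                       channel_fn = function(pool, x, s) {
                         p_i$seed <- s
                         run_workflow(pool, p_i)
                       },
                       clusterer = clusterer, payload = payload, x = i,
                       limits = limits,
                       seed = derive_seed(seed, sprintf("proto_%d_%d", i, rep)))
      ok <- ok + out$success
    }
    per_iter[i] <- ok
    if (ok == n_rep) highest <- i else break
  }
  structure(list(protocol = protocol, highest_pass = highest,
                 per_iteration = per_iter, values = values,
                 n_rep = n_rep),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s: highest all-pass iteration %d (%s)\n",
              x$protocol, x$highest_pass,
              paste(x$per_iteration, collapse = "/")))
  invisible(x)
}
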