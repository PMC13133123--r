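# A simplified multi-stage storage workflow channel:
# synthesis -> PCR1 -> dilution -> PCR2 -> sequencing.
# Stage-structured approximation of a full sequencing-workflow simulator,
# calibrated so the presets reproduce the reported end-to-end read error
# rates (high fidelity ~0.1% nt^-1 with minor sequence loss, low fidelity
# ~1.5% nt^-1 with considerable dropout).

#' Parameters of the multi-stage workflow channel
#'
#' @param scenario `"high_fidelity"`, `"low_fidelity"` or `"custom"`.
#'   The named presets model synthesis by material deposition with a
#'   high-fidelity polymerase, and electrochemical synthesis with an
#'   error-prone polymerase, respectively.
#' @param synthesis_rates Named numeric `(sub, del, ins)` per-nt synthesis
#'   error rates.
#' @param sigma_log Standard deviation of the log-normal per-sequence
#'   synthesis abundance weights (coverage bias).
#' @param p_fail Probability that a reference fails synthesis entirely
#'   (zero physical copies).
#' @param pcr1_cycles,pcr2_cycles PCR cycle counts before and after
#'   dilution (defaults 15 and 25).
#' @param e_pol Per-cycle polymerase substitution rate (nt^-1 cycle^-1).
#' @param eta PCR efficiency per cycle, in `(0, 1]`.
#' @param redundancy Mean physical oligo copies per reference after
#'   dilution (R).
#' @param depth Mean sequencing reads per reference (s).
#' @param read_length Maximum read length in nt (longer molecules are
#'   truncated).
#' @param seed Integer seed.
#' @return A `workflow_params` object.
#' @export
#' @examples
#' workflow_params("high_fidelity", redundancy = 1000, depth = 30)
workflow_params <- function(scenario = c("high_fidelity", "low_fidelity",
                                         "custom"),
                            synthesis_rates = NULL, sigma_log = NULL,
                            p_fail = NULL, pcr1_cycles = 15L,
                            pcr2_cycles = 25L, e_pol = NULL, eta = 0.95,
                            redundancy = 1000, depth = 30,
                            read_length = 150L, seed = 1L) {
  scenario <- match.arg(scenario)
  presets <- list(
    high_fidelity = list(
      synthesis_rates = c(sub = 5e-4, del = 4e-4, ins = 1e-4),
      sigma_log = 0.30, p_fail = 0.001, e_pol = 1e-6),
    low_fidelity = list(
      synthesis_rates = c(sub = 9e-3, del = 4.4e-3, ins = 1.0e-3),
      sigma_log = 0.85, p_fail = 0.03, e_pol = 3e-5),
    custom = list(
      synthesis_rates = c(sub = 0, del = 0, ins = 0),
      sigma_log = 0, p_fail = 0, e_pol = 0))
  pre <- presets[[scenario]]
  synthesis_rates <- synthesis_rates %||% pre$synthesis_rates
  sigma_log <- sigma_log %||% pre$sigma_log
  p_fail <- p_fail %||% pre$p_fail
  e_pol <- e_pol %||% pre$e_pol
  stopifnot(length(synthesis_rates) == 3L, all(synthesis_rates >= 0),
            sigma_log >= 0, p_fail >= 0, p_fail < 1,
            pcr1_cycles >= 0, pcr2_cycles >= 0, e_pol >= 0,
            eta > 0, eta <= 1, redundancy > 0, depth > 0, read_length >= 1)
  names(synthesis_rates) <- c("sub", "del", "ins")
  structure(list(scenario = scenario, synthesis_rates = synthesis_rates,
                 sigma_log = sigma_log, p_fail = p_fail,
                 pcr1_cycles = as.integer(pcr1_cycles),
                 pcr2_cycles = as.integer(pcr2_cycles),
                 e_pol = e_pol, eta = eta, redundancy = redundancy,
                 depth = depth, read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "workflow_params")
}

#' Simulate the multi-stage storage workflow
#'
#' Stage model: (1) synthesis assigns each reference a log-normal relative
#' abundance weight (zero with probability `p_fail`) and gives every
#' surviving physical molecule an iid synthesis error pattern;
#' (2) first-round PCR amplifies molecules (Galton-Watson with efficiency
#' `eta`), newly synthesized strands acquiring substitutions at rate
#' `e_pol` per cycle; (3) dilution samples molecule copies so the mean
#' copies per reference equals `redundancy` (multinomial; references drawn
#' zero times drop out); (4) second-round PCR as (2); (5) sequencing
#' samples `depth * N` reads multinomially from the final abundances,
#' truncated to `read_length`.  Sequence dropout emerges from sampling,
#' not from an explicit dropout parameter.
#'
#' Amplification acts on aggregated per-molecule abundances: post-dilution
#' founder molecules receive Gamma-distributed relative weights with the
#' Galton-Watson martingale-limit variance `(1 - eta) / (1 + eta)`, and
#' founder molecules that receive no sequencing read are never
#' materialized.  PCR substitutions accumulated before dilution are shared
#' by all reads of a founder; post-dilution PCR substitutions are drawn
#' per read.
#'
#' @param pool A [reference_pool()].
#' @param params A [workflow_params()].
#' @return A [read_set()] with ground-truth origins.
#' @export
run_workflow <- function(pool, params) {
  stopifnot(inherits(pool, "reference_pool"),
            inherits(params, "workflow_params"))
  N <- length(pool$sequences)
  with_seed(derive_seed(params$seed, "workflow"), {
    # (1) synthesis abundance weights
    w <- rlnorm(N, meanlog = 0, sdlog = params$sigma_log)
    w[runif(N) < params$p_fail] <- 0
    if (all(w == 0)) return(read_set(character(0), pool_size = N))
    # (3) dilution to a mean of R copies per reference
    n_molecules <- round_half_up(params$redundancy * N)
    copies <- as.vector(rmultinom(1, n_molecules, prob = w))
    # (2)+(4) aggregated Galton-Watson growth: per-reference post-PCR2
    # weight is a Gamma(copies * a, a) sum of founder weights,
    # a = (1 + eta)/(1 - eta)
    a <- if (params$eta >= 1) Inf else (1 + params$eta) / (1 - params$eta)
    W <- if (is.finite(a)) {
      ifelse(copies > 0, rgamma(N, shape = copies * a, rate = a), 0)
    } else as.numeric(copies)
    if (all(W == 0)) return(read_set(character(0), pool_size = N))
    # (5) sequencing: allocate reads over references, then over founders
    n_reads <- round_half_up(params$depth * N)
    reads_per_ref <- as.vector(rmultinom(1, n_reads, prob = W))
    active <- which(reads_per_ref > 0)
    syn_spec <- error_spec(min(1, sum(params$synthesis_rates)),
                           if (sum(params$synthesis_rates) > 0)
                             params$synthesis_rates / sum(params$synthesis_rates)
                           else c(1, 0, 0))
    pcr1_spec <- error_spec(min(1, params$e_pol * params$pcr1_cycles),
                            c(1, 0, 0))
    pcr2_spec <- error_spec(min(1, params$e_pol * params$pcr2_cycles),
                            c(1, 0, 0))
    out_seq <- character(0)
    out_origin <- integer(0)
    founder_templates <- character(0)
    founder_origin <- integer(0)
    read_founder <- integer(0)
    for (i in active) {
      k <- copies[i]
      # split this reference's reads over its founder molecules
      fw <- if (is.finite(a)) rgamma(k, shape = a, rate = a) else rep(1, k)
      f_of_read <- sample.int(k, reads_per_ref[i], replace = TRUE, prob = fw)
      used <- sort(unique(f_of_read))
      founder_templates <- c(founder_templates,
                             rep(pool$sequences[i], length(used)))
      founder_origin <- c(founder_origin, rep(i, length(used)))
      read_founder <- c(read_founder,
                        length(founder_origin) - length(used) +
                          match(f_of_read, used))
    }
    # materialize founders: synthesis errors + pre-dilution PCR substitutions
    founders <- inject_errors(founder_templates, syn_spec)
    founders <- inject_errors(founders, pcr1_spec)
    # per-read post-dilution PCR substitutions
    seqs <- inject_errors(founders[read_founder], pcr2_spec)
    seqs <- substr(seqs, 1L, params$read_length)
    keep <- nzchar(seqs)
    read_set(seqs[keep], origins = founder_origin[read_founder][keep],
             pool_size = N)
  })
}
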