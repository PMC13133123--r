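# The basic iid error channel: independent per-position errors at an
# overall rate r, split into substitutions / deletions / insertions at a
# fixed composition (default 53:45:2, resembling experimentally observed
# Illumina-workflow error patterns).

#' Specify an error channel
#'
#' @param rate Overall per-position error probability (errors per nt),
#'   in `[0, 1]`.
#' @param composition Length-3 numeric `(p_sub, p_del, p_ins)` summing to 1.
#' @return An `error_spec` object.
#' @export
#' @examples
#' error_spec(0.01)                      # 53:45:2 mix at 1% nt^-1
#' error_spec(0.05, c(1, 0, 0))          # substitutions only
error_spec <- function(rate, composition = c(0.53, 0.45, 0.02)) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0, rate <= 1,
            is.numeric(composition), length(composition) == 3L,
            all(composition >= 0))
  if (abs(sum(composition) - 1) > 1e-8)
    stop("error composition (p_sub, p_del, p_ins) must sum to 1")
  structure(list(rate = rate,
                 composition = setNames(as.numeric(composition),
                                        c("sub", "del", "ins"))),
            class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf("<error_spec> rate %.4g nt^-1, composition %s (sub:del:ins)\n",
              x$rate, paste(signif(x$composition, 3), collapse = ":")))
  invisible(x)
}

# Draw per-position error events for template positions.
# Returns integer codes: 0 none, 1 substitution, 2 deletion, 3 insertion.
draw_error_events <- function(n_positions, spec) {
  ops <- integer(n_positions)
  if (spec$rate > 0 && n_positions > 0) {
    hit <- which(runif(n_positions) < spec$rate)
    if (length(hit)) {
      ops[hit] <- sample.int(3L, length(hit), replace = TRUE,
                             prob = spec$composition)
    }
  }
  ops
}

# Apply drawn events to a batch of sequences (charwise, vectorized).
apply_error_events <- function(seqs, ops) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  all_chars <- unlist(chars, use.names = FALSE)
  stopifnot(length(all_chars) == length(ops))
  pieces <- all_chars
  sub_i <- which(ops == 1L)
  if (length(sub_i)) {
    # replace with one of the three other bases, uniformly
    shift <- sample.int(3L, length(sub_i), replace = TRUE)
    cur <- match(all_chars[sub_i], DNA_BASES)
    pieces[sub_i] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  del_i <- which(ops == 2L)
  if (length(del_i)) pieces[del_i] <- ""
  ins_i <- which(ops == 3L)
  if (length(ins_i)) {
    # insert one uniform base before the template position
    pieces[ins_i] <- paste0(DNA_BASES[sample.int(4L, length(ins_i),
                                                 replace = TRUE)],
                            all_chars[ins_i])
  }
  grp <- rep.int(seq_along(seqs), lens)
  out <- character(length(seqs))
  touched <- unique(grp[ops != 0L])
  out[] <- seqs
  if (length(touched)) {
    idx <- grp %in% touched
    rebuilt <- vapply(split(pieces[idx], grp[idx]),
                      paste, character(1), collapse = "")
    out[touched] <- rebuilt[as.character(touched)]
  }
  out
}

#' Inject iid errors into DNA sequences
#'
#' At each template position, independently with probability `rate`, an
#' error occurs; its type is drawn from the composition.  Substitutions
#' replace the base with one of the three others uniformly, insertions
#' insert one uniform base before the position, deletions skip the
#' position.  Output lengths vary accordingly.  Vectorized over
#' `sequences`.
#'
#' @param sequences Character vector of DNA sequences (empty input returns
#'   empty output).
#' @param spec An [error_spec()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is consumed.
#' @return Character vector of corrupted sequences.
#' @export
#' @examples
#' inject_errors("ACGTACGT", error_spec(0), seed = 1)  # identity at rate 0
inject_errors <- function(sequences, spec, seed = NULL) {
  stopifnot(inherits(spec, "error_spec"))
  if (length(sequences) == 0L) return(character(0))
  run <- function() {
    ops <- draw_error_events(sum(nchar(sequences)), spec)
    apply_error_events(sequences, ops)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Parameters of the basic error scenario
#'
#' The common synthetic benchmark: a fixed proportion of reference
#' sequences is removed (sequence dropout), then each surviving sequence
#' yields a fixed number of erroneous copies through the iid channel.
#'
#' @param error An [error_spec()].
#' @param copies Reads generated per surviving sequence (default 30).
#' @param dropout Fraction of reference sequences removed before read
#'   generation, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `basic_scenario_params` object.
#' @export
basic_scenario_params <- function(error = error_spec(0.01), copies = 30L,
                                  dropout = 0, seed = 1L) {
  stopifnot(inherits(error, "error_spec"))
  if (!is.numeric(copies) || copies < 1) stop("`copies` must be >= 1")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)")
  structure(list(error = error, copies = as.integer(copies),
                 dropout = dropout, seed = as.integer(seed)),
            class = "basic_scenario_params")
}

#' Run the basic error scenario
#'
#' Exactly `round((1 - dropout) * N)` reference sequences survive (uniform
#' sample without replacement, half-up rounding); each surviving sequence
#' yields exactly `copies` reads through [inject_errors()].  Reads carry
#' ground-truth origin indices.  Deterministic per seed.
#'
#' @param pool A [reference_pool()].
#' @param params A [basic_scenario_params()].
#' @return A [read_set()].
#' @export
run_basic_scenario <- function(pool, params) {
  stopifnot(inherits(pool, "reference_pool"),
            inherits(params, "basic_scenario_params"))
  N <- length(pool$sequences)
  n_survive <- round_half_up((1 - params$dropout) * N)
  with_seed(derive_seed(params$seed, "basic_scenario"), {
    survivors <- sort(sample.int(N, n_survive))
    templates <- rep(survivors, each = params$copies)
    seqs <- inject_errors(pool$sequences[templates], params$error)
    keep <- nzchar(seqs)  # all-deletion reads vanish
    read_set(seqs[keep], origins = templates[keep], pool_size = N)
  })
}

#' Downsample a read set to a target sequencing depth
#'
#' Uniform sample without replacement of `round(depth * pool_size)` reads.
#'
#' @param readset A [read_set()] with known `pool_size`.
#' @param depth Target mean reads per reference sequence.
#' @param seed Integer seed.
#' @return A [read_set()].
#' @export
downsample_reads <- function(readset, depth, seed = 1L) {
  stopifnot(inherits(readset, "read_set"), is.numeric(depth), depth > 0)
  ex <- expand_reads(readset)
  total <- sum(ex$abundance)
  want <- round_half_up(depth * ex$pool_size)
  if (want > total) {
    stop(sprintf("requested %d reads but only %d are available", want, total))
  }
  if (want == total) return(ex)
  with_seed(derive_seed(seed, "downsample"), {
    keep <- sort(sample.int(total, want))
    read_set(ex$sequences[keep], origins = ex$origins[keep],
             pool_size = ex$pool_size, pool_ref = ex$pool_ref)
  })
}

# round half away from zero (half-up for positive counts)
round_half_up <- function(x) floor(x + 0.5)
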