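# Read-set error and coverage profiling against ground truth: per-type
# error rates from minimal-cost alignments, dropout fraction, and the
# coefficient of variation of per-reference coverage.

#' Profile error rates and coverage of a read set
#'
#' Each read is aligned to its reference (ground-truth origin when
#' present, else the nearest reference by Levenshtein distance) with a
#' minimal-cost unit-cost alignment; substitutions, deletions and
#' insertions are counted from the edit transcript and normalized by the
#' total reference positions covered.  Dropout is the fraction of
#' references with zero reads; the coverage CV is the standard deviation
#' over the mean of per-reference read counts.  Alignment-path ties are
#' resolved by the (deterministic) dynamic-programming backtrace.
#'
#' @param readset A [read_set()].
#' @param references A [reference_pool()].
#' @return An `error_profile`: list with `rate_sub`, `rate_del`,
#'   `rate_ins`, `rate_overall`, `dropout`, `coverage_cv`, and
#'   `per_reference_counts`.
#' @export
analyze_error_rates <- function(readset, references) {
  stopifnot(inherits(readset, "read_set"),
            inherits(references, "reference_pool"))
  ex <- expand_reads(readset)
  if (length(ex$sequences) == 0L) stop("empty read set")
  refs <- references$sequences
  origins <- ex$origins
  if (anyNA(origins)) {
    d <- adist(ex$sequences, refs)
    assigned <- apply(d, 1L, which.min)
    origins[is.na(origins)] <- assigned[is.na(origins)]
  }
  n_sub <- 0; n_del <- 0; n_ins <- 0; n_ref_nt <- 0
  for (o in unique(origins)) {
    idx <- which(origins == o)
    al <- adist(refs[o], ex$sequences[idx], counts = TRUE)
    cts <- attr(al, "counts")  # dims: 1 x reads x (ins, del, sub)
    n_ins <- n_ins + sum(cts[1, , "ins"])
    n_del <- n_del + sum(cts[1, , "del"])
    n_sub <- n_sub + sum(cts[1, , "sub"])
    n_ref_nt <- n_ref_nt + length(idx) * nchar(refs[o])
  }
  counts <- tabulate(origins, nbins = length(refs))
  cv <- if (mean(counts) > 0) sd(counts) / mean(counts) else NA_real_
  structure(list(rate_sub = n_sub / n_ref_nt,
                 rate_del = n_del / n_ref_nt,
                 rate_ins = n_ins / n_ref_nt,
                 rate_overall = (n_sub + n_del + n_ins) / n_ref_nt,
                 dropout = mean(counts == 0L),
                 coverage_cv = cv,
                 per_reference_counts = counts),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(paste0("<error_profile> overall %.4g nt^-1 ",
                     "(sub %.4g, del %.4g, ins %.4g); dropout %.3g; ",
                     "coverage CV %.3g\n"),
              x$rate_overall, x$rate_sub, x$rate_del, x$rate_ins,
              x$dropout, x$coverage_cv))
  invisible(x)
}
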