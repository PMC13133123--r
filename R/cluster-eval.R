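# Clustering quality metrics against the reference pool, following the
# standard definitions: each consensus sequence is assigned to the
# reference minimizing Levenshtein distance; sensitivity is the fraction
# of references with at least one assigned consensus; accuracy is the
# mean Levenshtein similarity of the closest match to each reference;
# specificity is the sensitivity numerator divided by the total number
# of consensus sequences.

#' Levenshtein similarity
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))`, vectorized via the full
#' distance matrix.
#'
#' @param a,b Character vectors.
#' @return Numeric matrix `length(a) x length(b)` of similarities.
#' @export
levenshtein_similarity <- function(a, b) {
  d <- adist(a, b)
  mx <- outer(nchar(a), nchar(b), pmax)
  1 - d / mx
}

#' Evaluate a clustering against the reference pool
#'
#' @param consensus A [consensus_set()] (or character vector of consensus
#'   sequences).
#' @param references A [reference_pool()].
#' @return A `cluster_metrics` object: list with `sensitivity`,
#'   `accuracy`, `specificity`, and `assignment` (the consensus-to-
#'   reference index map).
#' @export
#' @examples
#' pool <- reference_pool(c("ACGT", "TTTT"))
#' m <- evaluate_clustering(consensus_set("ACCT", L = 4), pool)
#' c(m$sensitivity, m$accuracy)
evaluate_clustering <- function(consensus, references) {
  if (is.character(consensus)) {
    consensus <- consensus_set(consensus, L = max(nchar(consensus)))
  }
  stopifnot(inherits(consensus, "consensus_set"),
            inherits(references, "reference_pool"))
  cons <- consensus$sequences
  refs <- references$sequences
  if (length(cons) == 0L || length(refs) == 0L) stop("empty input")
  d <- adist(cons, refs)
  # assignment: nearest reference, ties -> lowest reference index
  assignment <- apply(d, 1L, which.min)
  covered <- unique(assignment)
  n_covered <- length(covered)
  sens <- n_covered / length(refs)
  spec <- n_covered / length(cons)
  sim <- 1 - d / outer(nchar(cons), nchar(refs), pmax)
  # accuracy: for every reference, similarity of its closest consensus
  acc <- mean(apply(sim, 2L, max))
  structure(list(sensitivity = sens, accuracy = acc, specificity = spec,
                 assignment = as.integer(assignment)),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(
    "<cluster_metrics> sensitivity %.3f, accuracy %.3f, specificity %.3f\n",
    x$sensitivity, x$accuracy, x$specificity))
  invisible(x)
}
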