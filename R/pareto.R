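# Pareto fronts over pairs of workflow parameters.

#' Filter a point set to its Pareto-efficient members
#'
#' A point dominates another when it is at least as hard on both axes
#' and strictly harder on one.  Direction flags declare what "harder"
#' means per axis: `"harder-is-larger"` (error rate, dropout) or
#' `"harder-is-smaller"` (redundancy, depth).
#'
#' @param points Data frame (or matrix) with columns `x` and `y`.
#' @param directions Character vector of length 2 with the per-axis
#'   direction flags.
#' @return The Pareto-efficient subset, as a data frame in input order.
#' @export
#' @examples
#' pts <- data.frame(x = c(1, 2, 2), y = c(3, 1, 3))
#' pareto_filter(pts, c("harder-is-larger", "harder-is-larger"))
pareto_filter <- function(points,
                          directions = c("harder-is-larger",
                                         "harder-is-larger")) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(points)), length(directions) == 2L,
            all(directions %in% c("harder-is-larger", "harder-is-smaller")))
  if (nrow(points) == 0L) return(points)
  # orient both axes so larger = harder
  hx <- if (directions[1L] == "harder-is-larger") points$x else -points$x
  hy <- if (directions[2L] == "harder-is-larger") points$y else -points$y
  n <- nrow(points)
  dominated <- vapply(seq_len(n), function(i) {
    any(hx >= hx[i] & hy >= hy[i] & (hx > hx[i] | hy > hy[i]))
  }, logical(1))
  points[!dominated, , drop = FALSE]
}

#' Two-parameter Pareto scan
#'
#' Runs two sets of ten one-dimensional [adaptive_scan()]s: in the first
#' set the y-parameter is fixed at each of ten logarithmically spaced
#' values while x is scanned; in the second the roles are swapped.  The
#' resulting feasibility-threshold pairs are filtered to the
#' Pareto-efficient points.
#'
#' @param trial_fn `function(x, y) -> logical` (or list with `success`).
#' @param x_range,y_range Parameter ranges `c(min, max)`.
#' @param directions Per-axis direction flags (x then y), as in
#'   [pareto_filter()].
#' @param p_star Target success probability.
#' @return A `pareto_front`: list with `points` (the efficient pairs
#'   with censoring flags) and `all_points`.
#' @export
pareto_scan <- function(trial_fn, x_range, y_range,
                        directions = c("harder-is-larger",
                                       "harder-is-larger"),
                        p_star = 0.95) {
  fixed_y <- exp(seq(log(y_range[1L]), log(y_range[2L]), length.out = 10L))
  fixed_x <- exp(seq(log(x_range[1L]), log(x_range[2L]), length.out = 10L))
  rows <- list()
  for (y in fixed_y) {
    est <- adaptive_scan(function(x) trial_fn(x, y), x_range,
                         direction = directions[1L], p_star = p_star)
    rows[[length(rows) + 1L]] <- data.frame(
      x = est$threshold, y = y, scanned = "x", censoring = est$censoring)
  }
  for (x in fixed_x) {
    est <- adaptive_scan(function(y) trial_fn(x, y), y_range,
                         direction = directions[2L], p_star = p_star)
    rows[[length(rows) + 1L]] <- data.frame(
      x = x, y = est$threshold, scanned = "y", censoring = est$censoring)
    }
  all_points <- do.call(rbind, rows)
  feasible <- all_points[all_points$censoring != "all_fail", , drop = FALSE]
  front <- pareto_filter(feasible, directions)
  structure(list(points = front, all_points = all_points,
                 directions = directions),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d efficient of %d scanned points\n",
              nrow(x$points), nrow(x$all_points)))
  invisible(x)
}
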