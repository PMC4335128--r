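#' Ensemble standard deviation per datapoint
#'
#' The unweighted sample standard deviation (n-1 denominator) of the member
#' predictions for each row — the spread of the library's opinions, used as
#' an applicability-domain signal.
#'
#' @param member_predictions Numeric matrix (rows = datapoints, columns =
#'   members) or a vector of member predictions for one datapoint.
#' @return Numeric vector of per-row standard deviations.
#' @export
ensemble_std <- function(member_predictions) {
  if (is.null(dim(member_predictions))) {
    member_predictions <- matrix(member_predictions, nrow = 1)
  }
  if (ncol(member_predictions) < 2) {
    abort("ensemble spread needs at least 2 members")
  }
  apply(member_predictions, 1, sd)
}

#' Per-prediction confidence interval from ensemble spread
#'
#' The interval is `y_pred +/- beta * e_std`: symmetric about the point
#' prediction, with width proportional to the ensemble spread.
#'
#' @param y_pred Point predictions.
#' @param e_std Ensemble standard deviations (`>= 0`), aligned.
#' @param beta Positive scaling factor.
#' @return A tibble with `y_pred`, `e_std`, `beta`, `lower`, `upper`.
#' @export
confidence_interval <- function(y_pred, e_std, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    abort("beta must be a single positive number")
  }
  if (any(e_std < 0)) abort("e_std must be >= 0")
  if (length(y_pred) != length(e_std)) abort("y_pred and e_std lengths differ")
  tibble(
    y_pred = y_pred, e_std = e_std, beta = beta,
    lower = y_pred - beta * e_std,
    upper = y_pred + beta * e_std
  )
}

#' Empirical coverage of spread-scaled confidence intervals
#'
#' For each `beta` on the grid, the fraction of datapoints whose observed
#' value lies inside `y_pred +/- beta * e_std` (boundary counts as inside).
#'
#' @param y Observed values.
#' @param y_pred Point predictions, aligned.
#' @param e_std Ensemble spreads, aligned.
#' @param beta_grid Increasing positive grid (default 0.1 to 4 by 0.1).
#' @param context Label stored with the curve (e.g. `"cross-validation"` or
#'   `"test"`).
#' @return A `coverage_curve` tibble with `beta`, `coverage`, `context`.
#' @export
coverage_curve <- function(y, y_pred, e_std,
                           beta_grid = seq(0.1, 4, by = 0.1),
                           context = "test") {
  check_aligned(y, y_pred)
  if (length(e_std) != length(y)) abort("e_std length differs")
  if (any(beta_grid <= 0)) abort("beta grid must be positive")
  resid <- abs(y - y_pred)
  curve <- tibble(
    beta = beta_grid,
    coverage = vapply(beta_grid, function(b) mean(resid <= b * e_std),
                      numeric(1)),
    context = context
  )
  structure(curve, class = c("coverage_curve", class(curve)))
}

#' Smallest beta reaching a requested confidence level
#'
#' @param curve A `coverage_curve`.
#' @param level Requested coverage in (0, 1].
#' @return The smallest grid `beta` whose coverage is `>= level`.
#' @export
beta_for_confidence <- function(curve, level) {
  if (level <= 0 || level > 1) abort("level must be in (0, 1]")
  ok <- which(curve$coverage >= level)
  if (length(ok) == 0) {
    abort(sprintf("level %.2f unattainable on the grid (max coverage %.3f)",
                  level, max(curve$coverage)))
  }
  curve$beta[min(ok)]
}

#' Plot a coverage curve
#'
#' @param object A `coverage_curve` (rows from several contexts may be
#'   bound together).
#' @param ... Unused.
#' @return A ggplot object: coverage percentage against beta.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$beta, y = 100 * .data$coverage,
    colour = .data$context, shape = .data$context
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta),
                  y = "datapoints inside interval (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
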