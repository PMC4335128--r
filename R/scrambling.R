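#' Response-scrambling (y-scrambling) validation curve
#'
#' Retrains a designated model after permuting a seeded random fraction of
#' the training responses and records the test-set metrics, for each
#' requested fraction. Scrambling permutes existing values among the chosen
#' rows, preserving the marginal pIC50 distribution; test responses are
#' never scrambled. A model whose performance survives scrambling is fitting
#' chance correlations.
#'
#' @param x Preprocessed design matrix (all rows).
#' @param y Response aligned to `x`.
#' @param folds A `fold_assignment`; the designated test fold is scored.
#' @param spec A `model_spec` to retrain at each fraction.
#' @param fractions Fractions of training responses to scramble (default
#'   `seq(0, 1, 0.2)`); 0 reproduces the unscrambled model.
#' @param seed Integer seed controlling which rows are permuted.
#' @return A `scrambling_curve` tibble with `fraction`, `rmse`, `q2`,
#'   `r2_zero`, `ccc` on the test fold.
#' @export
y_scrambling_curve <- function(x, y, folds, spec,
                               fractions = seq(0, 1, by = 0.2), seed = 1) {
  if (any(fractions < 0 | fractions > 1)) abort("fractions must be in [0, 1]")
  tr <- folds$train_rows
  te <- folds$test_rows
  rows <- purrr::imap(fractions, function(f, i) {
    y_scr <- y
    if (f > 0) {
      withr::with_seed(seed + i, {
        pick <- sample(tr, size = round(f * length(tr)))
        y_scr[pick] <- y_scr[sample(pick)]
      })
    }
    m <- fit_model(spec, x[tr, , drop = FALSE], y_scr[tr], seed = seed)
    pred <- predict_model(m, x[te, , drop = FALSE])
    bind_cols(tibble(fraction = f),
              select(metrics_report(y[te], pred, context = "test"),
                     "rmse", "q2", "r2_zero", "ccc"))
  })
  curve <- bind_rows(rows)
  structure(curve, class = c("scrambling_curve", class(curve)),
            seed = seed)
}

#' Plot a y-scrambling curve
#'
#' @param object A `scrambling_curve`.
#' @param metric Which metric to draw (default `"q2"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scrambling_curve <- function(object, metric = "q2", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = 100 * .data$fraction, y = .data[[metric]]
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "scrambled training responses (%)", y = metric) +
    ggplot2::theme_minimal()
}
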