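check_aligned <- function(y, y_pred) {
  if (length(y) != length(y_pred)) abort("y and y_pred lengths differ")
  if (length(y) == 0) abort("empty input")
  if (any(!is.finite(y)) || any(!is.finite(y_pred))) {
    abort("y and y_pred must be finite")
  }
}

#' Root mean square error
#'
#' @param y Observed values.
#' @param y_pred Predicted values.
#' @return `sqrt(mean((y - y_pred)^2))`.
#' @export
rmse <- function(y, y_pred) {
  check_aligned(y, y_pred)
  sqrt(mean((y - y_pred)^2))
}

#' Cross-validated / external determination coefficient q2
#'
#' `1 - SS_res / SS_tot`, with the mean taken over the evaluated set itself.
#' Can be negative when predictions are worse than the constant mean.
#'
#' @inheritParams rmse
#' @return A number `<= 1`.
#' @export
q2 <- function(y, y_pred) {
  check_aligned(y, y_pred)
  if (var(y) == 0) abort("q2 undefined for constant y")
  1 - sum((y - y_pred)^2) / sum((y - mean(y))^2)
}

#' Through-origin determination coefficient R2_0
#'
#' Regresses observed on predicted with zero intercept: the slope is
#' `s = sum(y * y_pred) / sum(y_pred^2)` and
#' `R2_0 = 1 - sum((y - s * y_pred)^2) / sum((y - mean(y))^2)`.
#' Asymmetric in its arguments and invariant to positive rescaling of
#' `y_pred`; may be strongly negative for uncorrelated profiles.
#'
#' @inheritParams rmse
#' @return A list with `r2_zero` and `slope`.
#' @export
r2_zero <- function(y, y_pred) {
  check_aligned(y, y_pred)
  if (sum(y_pred^2) == 0) abort("R2_0 undefined for all-zero predictions")
  if (var(y) == 0) abort("R2_0 undefined for constant y")
  s <- sum(y * y_pred) / sum(y_pred^2)
  list(
    r2_zero = 1 - sum((y - s * y_pred)^2) / sum((y - mean(y))^2),
    slope = s
  )
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(y, y_pred) / (var(y) + var(y_pred) + (mean(y) - mean(y_pred))^2)`
#' with population (n-denominator) moments. Penalizes both dispersion and
#' location shifts; bounded by the Pearson correlation in absolute value.
#'
#' @inheritParams rmse
#' @return A number in `[-1, 1]`.
#' @export
ccc <- function(y, y_pred) {
  check_aligned(y, y_pred)
  n <- length(y)
  vy <- var(y) * (n - 1) / n
  vp <- var(y_pred) * (n - 1) / n
  if (vy == 0 || vp == 0) abort("CCC undefined for zero-variance input")
  cv <- mean((y - mean(y)) * (y_pred - mean(y_pred)))
  2 * cv / (vy + vp + (mean(y) - mean(y_pred))^2)
}

#' Full metrics report for one evaluation set
#'
#' @inheritParams rmse
#' @param context Label, e.g. `"internal-cv"` or `"test"`.
#' @return A one-row tibble with `context`, `n`, `rmse`, `q2`, `r2_zero`,
#'   `slope`, `ccc`.
#' @export
metrics_report <- function(y, y_pred, context = "test") {
  r0 <- r2_zero(y, y_pred)
  tibble(
    context = context,
    n = length(y),
    rmse = rmse(y, y_pred),
    q2 = q2(y, y_pred),
    r2_zero = r0$r2_zero,
    slope = r0$slope,
    ccc = ccc(y, y_pred)
  )
}

#' Threshold check for statistical soundness of a regression model
#'
#' Declares a model sound when the internal cross-validated q2 exceeds
#' `q2_int_min` and both the external q2 and through-origin R2_0 exceed
#' `q2_test_min` / `r2_zero_min` (strict inequalities).
#'
#' @param internal,test One-row metric tibbles from [metrics_report()].
#' @param q2_int_min,q2_test_min,r2_zero_min Thresholds (defaults 0.5, 0.6,
#'   0.6).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   failed rules, empty when passing).
#' @export
tropsha_check <- function(internal, test, q2_int_min = 0.5,
                          q2_test_min = 0.6, r2_zero_min = 0.6) {
  reasons <- character()
  if (!(internal$q2 > q2_int_min)) {
    reasons <- c(reasons, sprintf("q2_int %.3f <= %.2f", internal$q2, q2_int_min))
  }
  if (!(test$q2 > q2_test_min)) {
    reasons <- c(reasons, sprintf("q2_test %.3f <= %.2f", test$q2, q2_test_min))
  }
  if (!(test$r2_zero > r2_zero_min)) {
    reasons <- c(reasons, sprintf("r2_zero_test %.3f <= %.2f", test$r2_zero, r2_zero_min))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Bootstrap mean and standard deviation of a metric
#'
#' Resamples (y, y_pred) pairs with replacement, recomputes `metric_fn`, and
#' returns the mean and SD of the replicate distribution.
#'
#' @param metric_fn Function of `(y, y_pred)` returning one number.
#' @param y,y_pred Aligned numeric vectors.
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed reproduces the same replicates.
#' @return A list with `mean`, `sd` and the replicate vector `replicates`.
#' @export
bootstrap_sd <- function(metric_fn, y, y_pred, reps = 1000, seed = 1) {
  check_aligned(y, y_pred)
  if (reps < 2) abort("reps must be >= 2")
  n <- length(y)
  reps_v <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fn(y[idx], y_pred[idx])
    }, numeric(1))
  })
  list(mean = mean(reps_v), sd = sd(reps_v), replicates = reps_v)
}

#' Maximum achievable performance under bioactivity-data noise
#'
#' Estimates the distribution of the best test-set metrics any model could
#' attain given the experimental uncertainty of the response. Per replicate,
#' a sample `A` of size `sample_size` is drawn from the pIC50 pool (without
#' replacement by default), `A_noisy = A + N(0, sigma)` emulates a model
#' whose only error is the experimental one, and the metrics of `A` with
#' respect to `A_noisy` (A observed, A_noisy predicted) are recorded.
#'
#' @param y_pool Numeric pool of pIC50 values to sample from.
#' @param sigma Noise standard deviation in pIC50 units; default 0.68, the
#'   published average experimental uncertainty of public IC50 data.
#' @param sample_size Size of each replicate sample (a test-set size).
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param replace Sample the pool with replacement (default FALSE; required
#'   TRUE when `sample_size > length(y_pool)`).
#' @return A list with `sigma`, `sample_size`, `reps`, per-replicate tibble
#'   `distributions` (columns `rmse`, `q2`, `r2_zero`) and `means`, the
#'   column means: mean minimum RMSE, mean maximum q2 and R2_0.
#' @export
simulate_max_performance <- function(y_pool, sigma = 0.68, sample_size,
                                     reps = 1000, seed = 1,
                                     replace = FALSE) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (!replace && sample_size > length(y_pool)) {
    abort("sample_size exceeds pool; set replace = TRUE to allow")
  }
  if (reps < 1) abort("reps must be >= 1")
  dist <- withr::with_seed(seed, {
    purrr::map(seq_len(reps), function(i) {
      a <- sample(y_pool, sample_size, replace = replace)
      a_noisy <- a + rnorm(sample_size, 0, sigma)
      tibble(
        rmse = rmse(a, a_noisy),
        q2 = q2(a, a_noisy),
        r2_zero = r2_zero(a, a_noisy)$r2_zero
      )
    }) |> bind_rows()
  })
  list(
    sigma = sigma,
    sample_size = sample_size,
    reps = reps,
    distributions = dist,
    means = c(
      rmse = mean(dist$rmse),
      q2 = mean(dist$q2),
      r2_zero = mean(dist$r2_zero)
    )
  )
}
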