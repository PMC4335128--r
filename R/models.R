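#' Stratified fold assignment
#'
#' Splits datapoints into `k` folds by stratified sampling of the response:
#' values are binned into `n_bins` quantile strata and, within each stratum,
#' assigned round-robin to folds after a seeded shuffle. One designated fold
#' is reserved as the test set; the remaining folds drive cross-validation.
#'
#' @param response Numeric response vector.
#' @param k Number of folds (default 6).
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @param n_bins Number of quantile strata (default 10; reduced when the
#'   response has few distinct values).
#' @param test_fold Which fold is the test set (default `k`).
#' @return A `fold_assignment` list with `fold` (integer labels in `1..k`),
#'   `k`, `test_fold`, `seed`, and the convenience indices `train_rows` /
#'   `test_rows`.
#' @export
make_folds <- function(response, k = 6, seed = 1, n_bins = 10,
                       test_fold = k) {
  n <- length(response)
  if (k > n) abort("more folds than datapoints")
  if (!test_fold %in% seq_len(k)) abort("test_fold out of range")
  probs <- seq(0, 1, length.out = n_bins + 1)
  breaks <- unique(quantile(response, probs))
  strata <- if (length(breaks) < 3) {
    rep(1L, n)
  } else {
    as.integer(cut(response, breaks, include.lowest = TRUE))
  }
  fold <- integer(n)
  withr::with_seed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(
    list(fold = fold, k = k, test_fold = test_fold, seed = seed,
         train_rows = which(fold != test_fold),
         test_rows = which(fold == test_fold)),
    class = "fold_assignment"
  )
}

.model_families <- c("gbm", "rf", "svm_linear", "svm_radial", "enet", "lm")

#' Specify one regression model
#'
#' @param family One of `"gbm"` (gradient-boosted trees), `"rf"` (random
#'   forest), `"svm_linear"` / `"svm_radial"` (support-vector regression),
#'   `"enet"` (elastic net) or `"lm"` (ordinary linear).
#' @param ... Hyperparameters for the family: `gbm` takes `nrounds`,
#'   `max_depth`, `eta`; `rf` takes `num_trees`, `mtry_frac`; the SVMs take
#'   `cost`, `epsilon` and (radial) `gamma`; `enet` takes `alpha`,
#'   `lambda`. `lm` has none.
#' @param id Optional label; defaults to family plus parameter values.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family, ..., id = NULL) {
  family <- match.arg(family, .model_families)
  params <- list(...)
  defaults <- switch(family,
    gbm = list(nrounds = 100, max_depth = 4, eta = 0.1),
    rf = list(num_trees = 200, mtry_frac = 1 / 3),
    svm_linear = list(cost = 1, epsilon = 0.1),
    svm_radial = list(cost = 1, epsilon = 0.1, gamma = NA_real_),
    enet = list(alpha = 0.5, lambda = 0.01),
    lm = list()
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("invalid hyperparameter(s) for ", family, ": ",
                 paste(unknown, collapse = ", ")))
  }
  params <- utils::modifyList(defaults, params)
  if (is.null(id)) {
    id <- if (length(params) == 0) family else {
      paste0(family, "[",
             paste(names(params), unlist(params), sep = "=", collapse = ","),
             "]")
    }
  }
  structure(list(family = family, params = params, id = id),
            class = "model_spec")
}

fit_model <- function(spec, x, y, seed = 1) {
  p <- spec$params
  fit <- switch(spec$family,
    gbm = xgboost::xgboost(
      x = x, y = y, nrounds = p$nrounds, max_depth = p$max_depth,
      learning_rate = p$eta, objective = "reg:squarederror",
      nthreads = 1, seed = seed, verbosity = 0
    ),
    rf = ranger::ranger(
      x = x, y = y, num.trees = p$num_trees,
      mtry = max(1, floor(p$mtry_frac * ncol(x))),
      seed = seed, num.threads = 1
    ),
    svm_linear = e1071::svm(
      x = x, y = y, kernel = "linear", cost = p$cost, epsilon = p$epsilon,
      scale = FALSE
    ),
    svm_radial = e1071::svm(
      x = x, y = y, kernel = "radial", cost = p$cost, epsilon = p$epsilon,
      gamma = if (is.na(p$gamma)) 1 / ncol(x) else p$gamma, scale = FALSE
    ),
    enet = glmnet::glmnet(x = x, y = y, alpha = p$alpha),
    lm = {
      qr_fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
      list(coefficients = qr_fit$coefficients)
    }
  )
  structure(list(spec = spec, fit = fit), class = "pcm_model_fit")
}

predict_model <- function(model, x) {
  spec <- model$spec
  fit <- model$fit
  out <- switch(spec$family,
    gbm = predict(fit, x),
    rf = predict(fit, data = x, num.threads = 1)$predictions,
    svm_linear = as.numeric(predict(fit, x)),
    svm_radial = as.numeric(predict(fit, x)),
    enet = as.numeric(predict(fit, newx = x, s = spec$params$lambda)),
    lm = {
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      as.numeric(cbind(1, x) %*% beta)
    }
  )
  if (length(out) != nrow(x)) abort("prediction length mismatch")
  unname(out)
}

#' Grid search with k-fold cross-validation on the training folds
#'
#' For each candidate hyperparameter assignment, fits one model per
#' cross-validation fold (holding that fold out) on the non-test rows and
#' scores the held-out predictions; the assignment with the lowest mean
#' held-out RMSE wins, ties going to the earliest in grid order. The test
#' fold never participates.
#'
#' @param spec_grid List of `model_spec` objects (one family, varying
#'   hyperparameters — mixing families is allowed but unusual).
#' @param x Preprocessed design matrix.
#' @param y Response vector aligned to `x`.
#' @param folds A `fold_assignment`.
#' @param seed Integer seed forwarded to stochastic learners.
#' @return A list with `best_spec` and `results`, a tibble of `id`,
#'   `family`, `cv_rmse` in grid order.
#' @export
grid_search_cv <- function(spec_grid, x, y, folds, seed = 1) {
  if (length(spec_grid) == 0) abort("empty spec grid")
  cv_folds <- setdiff(seq_len(folds$k), folds$test_fold)
  scores <- purrr::imap_dbl(spec_grid, function(spec, i) {
    fold_rmse <- vapply(cv_folds, function(f) {
      tr <- which(!folds$fold %in% c(f, folds$test_fold))
      ho <- which(folds$fold == f)
      m <- fit_model(spec, x[tr, , drop = FALSE], y[tr],
                     seed = seed + 1000L * i)
      rmse(y[ho], predict_model(m, x[ho, , drop = FALSE]))
    }, numeric(1))
    mean(fold_rmse)
  })
  best <- which.min(scores)  # which.min returns the first minimum
  list(
    best_spec = spec_grid[[best]],
    results = tibble(
      id = map_chr(spec_grid, "id"),
      family = map_chr(spec_grid, "family"),
      cv_rmse = scores
    )
  )
}

#' Train a model library with aligned out-of-fold predictions
#'
#' Every spec is fitted once per cross-validation fold (trained without that
#' fold, never touching the test fold) to populate its out-of-fold
#' predictions for all training rows, then refitted on all training folds
#' for test-time prediction. All models share the same fold assignment, so
#' the resulting cross-validation prediction matrix is directly comparable
#' across models and is what the ensemble builders consume.
#'
#' @param spec_list List of `model_spec` objects.
#' @param x Preprocessed design matrix (all rows, training and test).
#' @param y Response aligned to `x`.
#' @param folds A `fold_assignment` over the rows of `x`.
#' @param seed Integer seed for stochastic learners.
#' @return A `model_library` with `models` (refitted on the full training
#'   set), `specs`, `cv_predictions` (training rows x models),
#'   `cv_rmse`, `response` (training-row response), `folds`, `train_rows`.
#' @export
train_library <- function(spec_list, x, y, folds, seed = 1) {
  if (length(spec_list) == 0) abort("empty spec list")
  ids <- map_chr(spec_list, "id")
  if (anyDuplicated(ids)) abort("duplicate model ids in spec list")
  cv_folds <- setdiff(seq_len(folds$k), folds$test_fold)
  train_rows <- folds$train_rows

  cv_pred <- matrix(NA_real_, nrow = length(train_rows),
                    ncol = length(spec_list),
                    dimnames = list(NULL, ids))
  row_of <- match(seq_along(folds$fold), train_rows)  # global -> cv row

  models <- purrr::imap(spec_list, function(spec, i) {
    for (f in cv_folds) {
      tr <- which(!folds$fold %in% c(f, folds$test_fold))
      ho <- which(folds$fold == f)
      m <- fit_model(spec, x[tr, , drop = FALSE], y[tr],
                     seed = seed + 1000L * i + f)
      cv_pred[row_of[ho], i] <<- predict_model(m, x[ho, , drop = FALSE])
    }
    fit_model(spec, x[train_rows, , drop = FALSE], y[train_rows],
              seed = seed + 1000L * i)
  })
  stopifnot(!anyNA(cv_pred))
  y_train <- y[train_rows]
  structure(
    list(
      models = models,
      specs = tibble(id = ids, family = map_chr(spec_list, "family")),
      cv_predictions = cv_pred,
      cv_rmse = apply(cv_pred, 2, rmse, y = y_train),
      response = y_train,
      folds = folds,
      train_rows = train_rows
    ),
    class = "model_library"
  )
}

#' Predict with every library member
#'
#' @param library A `model_library`.
#' @param x Preprocessed design rows.
#' @return Numeric matrix, one row per input row, one column per member.
#' @export
predict_library <- function(library, x) {
  if (nrow(x) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(library$models),
                  dimnames = list(NULL, library$specs$id)))
  }
  vapply(library$models, predict_model, numeric(nrow(x)), x = x) |>
    matrix(nrow = nrow(x), dimnames = list(NULL, library$specs$id))
}

#' Default model grid for a library
#'
#' A ready-made spec list spanning the supported families with varied
#' hyperparameters. `size = "small"` yields 28 models suitable for tests
#' and examples; `size = "full"` a few-hundred-model library for full runs.
#'
#' @param size `"small"` or `"full"`.
#' @return List of `model_spec` objects.
#' @export
default_model_grid <- function(size = c("small", "full")) {
  size <- match.arg(size)
  grids <- if (size == "small") {
    list(
      gbm = tidyr::expand_grid(nrounds = c(50, 150), max_depth = c(2, 4, 6),
                               eta = c(0.05, 0.2)),
      rf = tidyr::expand_grid(num_trees = c(100, 300),
                              mtry_frac = c(0.2, 0.5, 0.9)),
      svm_radial = tidyr::expand_grid(cost = c(0.5, 4), gamma = NA_real_,
                                      epsilon = c(0.1, 0.3)),
      svm_linear = tidyr::expand_grid(cost = c(0.5, 4), epsilon = 0.1),
      enet = tidyr::expand_grid(alpha = c(0.1, 0.95), lambda = c(0.005, 0.1))
    )
  } else {
    list(
      gbm = tidyr::expand_grid(nrounds = c(50, 100, 200, 400),
                               max_depth = c(2, 3, 4, 6, 8),
                               eta = c(0.01, 0.05, 0.1, 0.2, 0.3)),
      rf = tidyr::expand_grid(num_trees = c(100, 200, 500, 1000),
                              mtry_frac = c(0.1, 0.2, 0.33, 0.5, 0.7, 0.9)),
      svm_radial = tidyr::expand_grid(cost = 2^(-2:5), gamma = NA_real_,
                                      epsilon = c(0.05, 0.1, 0.2, 0.4)),
      svm_linear = tidyr::expand_grid(cost = 2^(-2:5),
                                      epsilon = c(0.05, 0.1, 0.2, 0.4)),
      enet = tidyr::expand_grid(alpha = c(0.05, 0.25, 0.5, 0.75, 0.95, 1),
                                lambda = c(0.001, 0.01, 0.05, 0.1, 0.5))
    )
  }
  specs <- purrr::imap(grids, function(grid, fam) {
    purrr::pmap(grid, function(...) {
      rlang::exec(model_spec, family = fam, !!!list(...))
    })
  })
  unname(unlist(specs, recursive = FALSE))
}

#' @export
print.model_library <- function(x, ...) {
  cat(sprintf("<model_library> %d models on %d training rows\n",
              length(x$models), length(x$response)))
  fams <- table(x$specs$family)
  cat("  families:", paste(names(fams), fams, sep = ":", collapse = " "), "\n")
  cat(sprintf("  cv RMSE: best %.3f, median %.3f, worst %.3f\n",
              min(x$cv_rmse), stats::median(x$cv_rmse), max(x$cv_rmse)))
  invisible(x)
}

#' One-row summary of a model library
#'
#' @param x A `model_library`.
#' @param ... Unused.
#' @return A tibble with member and family counts and the cv RMSE range.
#' @export
glance.model_library <- function(x, ...) {
  tibble(
    n_models = length(x$models),
    n_families = dplyr::n_distinct(x$specs$family),
    n_train = length(x$response),
    best_cv_rmse = min(x$cv_rmse),
    worst_cv_rmse = max(x$cv_rmse)
  )
}

#' Tidy per-member summary of a model library
#'
#' @param x A `model_library`.
#' @param ... Unused.
#' @return A tibble with `id`, `family`, `cv_rmse`.
#' @export
tidy.model_library <- function(x, ...) {
  mutate(x$specs, cv_rmse = unname(x$cv_rmse))
}
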