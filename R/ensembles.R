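#' Greedy ensemble weight optimization
#'
#' Caruana-style ensemble selection with replacement over a model library's
#' out-of-fold cross-validation predictions. All integer weights start at
#' zero; at each of up to `n` iterations every member's weight is
#' tentatively incremented by 1 and the RMSE of the normalized weighted
#' average of cross-validation predictions evaluated; the increment with the
#' lowest RMSE is applied when it does not worsen the current fit (ties go
#' to the lowest column index). Once no increment helps, the state is a
#' fixed point and remaining iterations leave it unchanged. Final weights
#' are normalized to sum to one; zero-weight members stay in the manifest so
#' ensemble-spread diagnostics can still see the full library.
#'
#' @param cv_matrix Numeric matrix of out-of-fold predictions (rows =
#'   training datapoints, columns = library members), e.g.
#'   `library$cv_predictions`.
#' @param response Observed response aligned to the rows.
#' @param n Maximum number of increments (default 1000).
#' @return A `greedy_ensemble` with `weights` (normalized, named),
#'   `raw_weights` (integer counts), `n`, `trace` (RMSE after each
#'   iteration, non-increasing) and `cv_rmse` (final ensemble RMSE on the
#'   cross-validation predictions).
#' @export
greedy_optimize <- function(cv_matrix, response, n = 1000) {
  if (is.null(dim(cv_matrix)) || ncol(cv_matrix) == 0) {
    abort("empty model library")
  }
  if (nrow(cv_matrix) != length(response)) {
    abort("cv_matrix rows must align with response")
  }
  m <- ncol(cv_matrix)
  w <- integer(m)
  s <- rep(0, nrow(cv_matrix))  # running weighted sum of predictions
  total <- 0
  cur_rmse <- Inf
  trace <- numeric(n)
  for (it in seq_len(n)) {
    # candidate j has mean prediction (s + p_j) / (total + 1)
    cand <- sweep(cv_matrix, 1, s, "+") / (total + 1)
    cand_rmse <- sqrt(colMeans((response - cand)^2))
    j <- which.min(cand_rmse)
    if (cand_rmse[j] <= cur_rmse) {
      w[j] <- w[j] + 1L
      s <- s + cv_matrix[, j]
      total <- total + 1
      cur_rmse <- unname(cand_rmse[j])
      trace[it] <- cur_rmse
    } else {
      # fixed point: no single increment improves the normalized fit
      trace[it:n] <- cur_rmse
      break
    }
  }
  weights <- w / sum(w)
  names(weights) <- colnames(cv_matrix)
  structure(
    list(weights = weights, raw_weights = setNames(w, colnames(cv_matrix)),
         n = n, trace = trace, cv_rmse = cur_rmse),
    class = "greedy_ensemble"
  )
}

#' Predict with a greedy ensemble
#'
#' The ensemble prediction is the dot product of the normalized weights with
#' the member predictions.
#'
#' @param ensemble A `greedy_ensemble`.
#' @param member_predictions Numeric matrix (rows = datapoints, columns =
#'   members in library order) or a vector for a single datapoint.
#' @return Numeric vector of ensemble predictions.
#' @export
greedy_predict <- function(ensemble, member_predictions) {
  if (is.null(dim(member_predictions))) {
    member_predictions <- matrix(member_predictions, nrow = 1)
  }
  if (ncol(member_predictions) != length(ensemble$weights)) {
    abort("member prediction count does not match library size")
  }
  as.numeric(member_predictions %*% ensemble$weights)
}

.meta_families <- c("lm", "enet", "svm_linear", "svm_radial", "rf")

#' Fit a stacking ensemble (meta-learner over member predictions)
#'
#' Trains a meta-learner whose feature matrix is the library's out-of-fold
#' cross-validation prediction matrix (rows = training datapoints, columns =
#' members) and whose target is the observed response. Meta hyperparameters
#' are tuned by internal cross-validation reusing the library's fold
#' assignment, so no test information leaks into the stack. When the meta
#' family exposes coefficients (`"lm"`, `"enet"`), a member-weight vector is
#' reported.
#'
#' @param cv_matrix Out-of-fold prediction matrix.
#' @param response Observed response aligned to the rows.
#' @param meta_family One of `"lm"`, `"enet"`, `"svm_linear"`,
#'   `"svm_radial"`, `"rf"`.
#' @param folds Optional `fold_assignment` whose non-test folds drive meta
#'   tuning (as produced for the library). Without it the default
#'   hyperparameters are used directly.
#' @param seed Integer seed.
#' @return A `stacking_ensemble` with `meta_family`, `meta_model`,
#'   `member_ids`, `member_weights` (or NULL) and `train_rmse`.
#' @export
stack_fit <- function(cv_matrix, response, meta_family = "lm",
                      folds = NULL, seed = 1) {
  meta_family <- match.arg(meta_family, .meta_families)
  if (is.null(dim(cv_matrix)) || ncol(cv_matrix) == 0) {
    abort("empty model library")
  }
  grid <- switch(meta_family,
    lm = list(model_spec("lm")),
    enet = purrr::pmap(
      tidyr::expand_grid(alpha = c(0.05, 0.5, 0.95),
                         lambda = c(0.001, 0.01, 0.1)),
      function(alpha, lambda) model_spec("enet", alpha = alpha, lambda = lambda)
    ),
    svm_linear = purrr::map(c(0.25, 1, 4), ~ model_spec("svm_linear", cost = .x)),
    svm_radial = purrr::map(c(0.25, 1, 4), ~ model_spec("svm_radial", cost = .x)),
    rf = purrr::map(c(0.33, 0.7), ~ model_spec("rf", mtry_frac = .x))
  )
  spec <- if (length(grid) == 1 || is.null(folds)) {
    grid[[1]]
  } else {
    # tune on the same folds the library used; restrict rows to train_rows
    sub_folds <- list(
      fold = folds$fold[folds$train_rows], k = folds$k,
      test_fold = folds$test_fold,
      train_rows = seq_along(folds$train_rows), test_rows = integer(0)
    )
    class(sub_folds) <- "fold_assignment"
    grid_search_cv(grid, cv_matrix, response, sub_folds, seed = seed)$best_spec
  }
  meta <- fit_model(spec, cv_matrix, response, seed = seed)
  weights <- NULL
  if (meta_family == "lm") {
    beta <- meta$fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    weights <- setNames(as.numeric(beta), colnames(cv_matrix))
  } else if (meta_family == "enet") {
    beta <- as.numeric(stats::coef(meta$fit, s = spec$params$lambda))[-1]
    weights <- setNames(beta, colnames(cv_matrix))
  }
  structure(
    list(
      meta_family = meta_family,
      meta_spec = spec,
      meta_model = meta,
      member_ids = colnames(cv_matrix),
      member_weights = weights,
      train_rmse = rmse(response, predict_model(meta, cv_matrix))
    ),
    class = "stacking_ensemble"
  )
}

#' Predict with a stacking ensemble
#'
#' @param ensemble A `stacking_ensemble`.
#' @param member_predictions Matrix of member predictions (columns in the
#'   member order used at fit time) or a vector for one datapoint.
#' @return Numeric vector of ensemble predictions.
#' @export
stack_predict <- function(ensemble, member_predictions) {
  if (is.null(dim(member_predictions))) {
    member_predictions <- matrix(member_predictions, nrow = 1)
  }
  if (ncol(member_predictions) != length(ensemble$member_ids)) {
    abort("member prediction count does not match the fitted stack")
  }
  if (nrow(member_predictions) == 0) return(numeric(0))
  colnames(member_predictions) <- ensemble$member_ids
  predict_model(ensemble$meta_model, member_predictions)
}

#' Is an ensemble homogeneous or heterogeneous?
#'
#' An ensemble is a homo-ensemble when all members carrying weight come from
#' one algorithm family and a hetero-ensemble when at least two families
#' contribute.
#'
#' @param ensemble A `greedy_ensemble` or `stacking_ensemble`.
#' @param library The `model_library` the ensemble was built from.
#' @return `"homo"` or `"hetero"`.
#' @export
ensemble_kind <- function(ensemble, library) {
  fams <- if (inherits(ensemble, "greedy_ensemble")) {
    library$specs$family[ensemble$weights > 0]
  } else {
    library$specs$family
  }
  if (length(unique(fams)) >= 2) "hetero" else "homo"
}

#' @export
print.greedy_ensemble <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf(
    "<greedy_ensemble> %d members (%d with weight > 0), cv RMSE %.4f\n",
    length(x$weights), nz, x$cv_rmse))
  invisible(x)
}

#' @export
print.stacking_ensemble <- function(x, ...) {
  cat(sprintf("<stacking_ensemble> meta %s over %d members, train RMSE %.4f\n",
              x$meta_family, length(x$member_ids), x$train_rmse))
  invisible(x)
}

#' Tidy member weights of an ensemble
#'
#' @param x A `greedy_ensemble` or `stacking_ensemble`.
#' @param ... Unused.
#' @return A tibble with `id` and `weight` (meta coefficients for stacks
#'   that expose them; an error otherwise).
#' @export
tidy.greedy_ensemble <- function(x, ...) {
  tibble(id = names(x$weights), weight = unname(x$weights))
}

#' @rdname tidy.greedy_ensemble
#' @export
tidy.stacking_ensemble <- function(x, ...) {
  if (is.null(x$member_weights)) {
    abort(paste0("meta family '", x$meta_family, "' exposes no coefficients"))
  }
  tibble(id = x$member_ids, weight = unname(x$member_weights))
}

#' One-line fit summary of an ensemble
#'
#' @param x A `greedy_ensemble` or `stacking_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.greedy_ensemble <- function(x, ...) {
  tibble(n_members = length(x$weights),
         n_active = sum(x$weights > 0),
         cv_rmse = x$cv_rmse)
}

#' @rdname glance.greedy_ensemble
#' @export
glance.stacking_ensemble <- function(x, ...) {
  tibble(meta_family = x$meta_family,
         n_members = length(x$member_ids),
         train_rmse = x$train_rmse)
}
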