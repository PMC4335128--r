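#' Predict with a single model or an ensemble
#'
#' Dispatch helper used by the interpretation and validation tooling: a
#' `pcm_model_fit` predicts directly; a `greedy_ensemble` or
#' `stacking_ensemble` first collects the member predictions of its library.
#'
#' @param object A `pcm_model_fit`, `greedy_ensemble` or
#'   `stacking_ensemble`.
#' @param x Preprocessed design rows.
#' @param library The `model_library` backing an ensemble (ignored for a
#'   single model).
#' @return Numeric predictions, one per row.
#' @export
pcm_predict <- function(object, x, library = NULL) {
  if (inherits(object, "pcm_model_fit")) {
    return(predict_model(object, x))
  }
  if (is.null(library)) abort("ensembles need their model library")
  members <- predict_library(library, x)
  if (inherits(object, "greedy_ensemble")) {
    return(greedy_predict(object, members))
  }
  if (inherits(object, "stacking_ensemble")) {
    return(stack_predict(object, members))
  }
  abort("unsupported predictor object")
}

resolve_substructure_col <- function(raw_x, substructure) {
  col <- if (substructure %in% colnames(raw_x)) {
    substructure
  } else if (paste0("cmpd|", substructure) %in% colnames(raw_x)) {
    paste0("cmpd|", substructure)
  } else {
    abort(paste0("substructure column not found: ", substructure))
  }
  col
}

#' Substructure contribution by count-zeroing (predictive method)
#'
#' Quantifies what a fitted model attributes to one keyed substructure: for
#' every design row whose compound contains it, the substructure count is
#' set to zero in the raw descriptor space, the frozen preprocessing
#' transform is re-applied, and the drop in predicted pIC50 recorded
#' (`delta = prediction(original) - prediction(count zeroed)`). The summary
#' is the count-weighted mean of the deltas (weights = the substructure's
#' count in each compound) with their unweighted SD; a positive mean marks
#' the substructure as beneficial, a negative one as deleterious. Zeroing
#' one column never touches any other column.
#'
#' @param object Model or ensemble (see [pcm_predict()]).
#' @param raw_x Raw (unfiltered, unscaled) design rows.
#' @param prep The fitted `pcm_preprocess` state for those columns.
#' @param substructure Substructure id (bare, or full `cmpd|`-prefixed
#'   column name).
#' @param library Model library backing an ensemble.
#' @param target_id Optional label stored in the result.
#' @return A one-row tibble with `substructure_id`, `target_id`,
#'   `mean_delta`, `sd_delta`, `n_compounds`, `total_count`.
#' @export
predictive_contribution <- function(object, raw_x, prep, substructure,
                                    library = NULL, target_id = NA_character_) {
  col <- resolve_substructure_col(raw_x, substructure)
  counts <- raw_x[, col]
  has <- which(counts > 0)
  if (length(has) == 0) {
    abort(paste0("substructure absent from all rows: ", substructure))
  }
  orig <- raw_x[has, , drop = FALSE]
  zeroed <- orig
  zeroed[, col] <- 0
  pred_orig <- pcm_predict(object, preprocess_apply(prep, orig), library)
  pred_zero <- pcm_predict(object, preprocess_apply(prep, zeroed), library)
  delta <- pred_orig - pred_zero
  w <- counts[has]
  tibble(
    substructure_id = sub("^cmpd\\|", "", col),
    target_id = target_id,
    mean_delta = sum(w * delta) / sum(w),
    sd_delta = if (length(delta) > 1) sd(delta) else 0,
    n_compounds = length(has),
    total_count = sum(w)
  )
}

#' Joint contribution of a set of substructure columns (moiety level)
#'
#' A chemical moiety (e.g. a trifluoromethyl group) manifests as a family of
#' keyed environments — its atoms' environments at every radius, including
#' context variants. Models may spread the moiety's influence across any of
#' these mutually collinear columns, so single-column zeroing can understate
#' it. Here all the family's counts are zeroed jointly, which measures the
#' model's total attribution to the moiety: for a linear model this equals
#' the sum of the family coefficients weighted by counts, independent of how
#' the fit distributed them.
#'
#' @inheritParams predictive_contribution
#' @param substructures Character vector of substructure ids (or full
#'   column names) zeroed together; rows where any of them is present are
#'   evaluated.
#' @return A one-row tibble as in [predictive_contribution()], with
#'   `substructure_id` the concatenated ids and weights taken as each row's
#'   maximum count over the family.
#' @export
moiety_contribution <- function(object, raw_x, prep, substructures,
                                library = NULL, target_id = NA_character_) {
  cols <- vapply(substructures, resolve_substructure_col, character(1),
                 raw_x = raw_x)
  counts <- raw_x[, cols, drop = FALSE]
  w_all <- apply(counts, 1, max)
  has <- which(w_all > 0)
  if (length(has) == 0) abort("moiety absent from all rows")
  orig <- raw_x[has, , drop = FALSE]
  zeroed <- orig
  zeroed[, cols] <- 0
  pred_orig <- pcm_predict(object, preprocess_apply(prep, orig), library)
  pred_zero <- pcm_predict(object, preprocess_apply(prep, zeroed), library)
  delta <- pred_orig - pred_zero
  w <- w_all[has]
  tibble(
    substructure_id = paste(sub("^cmpd\\|", "", cols), collapse = "+"),
    target_id = target_id,
    mean_delta = sum(w * delta) / sum(w),
    sd_delta = if (length(delta) > 1) sd(delta) else 0,
    n_compounds = length(has),
    total_count = sum(w)
  )
}

#' Environments introduced by a generator marker
#'
#' For synthetic studies: the family of vocabulary environments whose
#' supporting compounds are a subset of the compounds carrying a given
#' marker substituent — the keyed columns the marker introduces, including
#' scaffold-context variants. Useful as the `substructures` argument of
#' [moiety_contribution()].
#'
#' @param counts Keyed count matrix (compounds x environments).
#' @param marker_counts Integer vector of marker insertion counts aligned
#'   to the rows of `counts`.
#' @return Character vector of substructure ids.
#' @export
marker_environment_family <- function(counts, marker_counts) {
  if (length(marker_counts) != nrow(counts)) {
    abort("marker_counts must align with count matrix rows")
  }
  carriers <- marker_counts > 0
  if (!any(carriers)) abort("marker absent from all compounds")
  ok <- vapply(seq_len(ncol(counts)), function(j) {
    sup <- counts[, j] > 0
    any(sup) && all(carriers[sup])
  }, logical(1))
  colnames(counts)[ok]
}

#' Contribution map over all substructures present on one target
#'
#' Runs [predictive_contribution()] for every vocabulary substructure
#' occurring in at least one design row of the given target, ordered by
#' absolute mean contribution (ties broken by id). Mapping several targets
#' and binding the results gives the target-by-substructure matrix behind
#' contribution heatmaps.
#'
#' @param object Model or ensemble.
#' @param design A `pcm_design` (raw matrix) from [assemble_pcm_matrix()].
#' @param prep Fitted `pcm_preprocess` for the design columns.
#' @param vocab A `substructure_vocab`.
#' @param target_id Target whose rows are probed.
#' @param library Model library backing an ensemble.
#' @return A tibble, one row per occurring substructure.
#' @export
predictive_contribution_map <- function(object, design, prep, vocab,
                                        target_id, library = NULL) {
  rows <- which(design$meta$target_id == target_id)
  if (length(rows) == 0) abort(paste0("no design rows for target ", target_id))
  raw_x <- design$x[rows, , drop = FALSE]
  cols <- intersect(paste0("cmpd|", vocab$substructure_id), colnames(raw_x))
  present <- cols[colSums(raw_x[, cols, drop = FALSE] > 0) > 0]
  out <- bind_rows(purrr::map(present, function(cl) {
    predictive_contribution(object, raw_x, prep, cl, library, target_id)
  }))
  arrange(out, dplyr::desc(abs(.data$mean_delta)), .data$substructure_id)
}

#' Model-free substructure assessment (Shapiro-gated t-test)
#'
#' Within one bioactivity set (all pIC50 values of one target), splits the
#' compounds into those containing the substructure (distribution A) and
#' those not containing it (distribution B). Both groups are first checked
#' for normality with the Shapiro-Wilk test at `alpha`; only when both pass
#' is a two-tailed independent-samples t-test run (Welch by default). The
#' label follows the significance and the sign of `mean(A) - mean(B)`.
#' Groups smaller than `min_group` are not assessed.
#'
#' @param table A `bioactivity_table`.
#' @param counts Keyed count matrix with compound ids as row names (from
#'   [morgan_count_matrix()]).
#' @param substructure Substructure id (a column of `counts`).
#' @param target_id The bioactivity set to analyse.
#' @param alpha Significance level for both gates (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @param min_group Minimum group size to assess (default 3).
#' @return A one-row tibble with group sizes, Shapiro p-values, `mean_diff`
#'   (present - absent), `t_p`, `assessed` and `label` in
#'   beneficial/deleterious/not significant/not assessed.
#' @export
students_method <- function(table, counts, substructure, target_id,
                            alpha = 0.05, var_equal = FALSE, min_group = 3) {
  if (!target_id %in% table$target_id) {
    abort(paste0("unknown target: ", target_id))
  }
  if (!substructure %in% colnames(counts)) {
    abort(paste0("substructure not in count matrix: ", substructure))
  }
  set <- filter(table, .data$target_id == !!target_id)
  cnt <- counts[set$compound_id, substructure]
  a <- set$pIC50[cnt > 0]
  b <- set$pIC50[cnt == 0]
  res <- tibble(
    substructure_id = substructure, target_id = target_id,
    n_present = length(a), n_absent = length(b),
    shapiro_p_present = NA_real_, shapiro_p_absent = NA_real_,
    mean_diff = if (length(a) > 0 && length(b) > 0) mean(a) - mean(b) else NA_real_,
    t_p = NA_real_, assessed = FALSE, label = "not assessed"
  )
  if (length(a) < min_group || length(b) < min_group) return(res)
  safe_shapiro <- function(v) {
    if (length(unique(v)) < 3 || length(v) > 5000) return(NA_real_)
    shapiro.test(v)$p.value
  }
  res$shapiro_p_present <- safe_shapiro(a)
  res$shapiro_p_absent <- safe_shapiro(b)
  gates <- c(res$shapiro_p_present, res$shapiro_p_absent)
  if (anyNA(gates) || any(gates <= alpha)) return(res)
  tt <- t.test(a, b, alternative = "two.sided", var.equal = var_equal)
  res$t_p <- tt$p.value
  res$assessed <- TRUE
  res$label <- if (tt$p.value > alpha) {
    "not significant"
  } else if (res$mean_diff > 0) "beneficial" else "deleterious"
  res
}

#' Student's-method scan over a vocabulary
#'
#' @inheritParams students_method
#' @param vocab A `substructure_vocab`, or a character vector of
#'   substructure ids.
#' @param p_adjust_method Optional multiple-testing correction applied to
#'   the assessed t-test p-values before labelling (default `"none"`,
#'   matching the uncorrected single-panel analysis; `"BH"` recommended for
#'   large vocabularies).
#' @return A tibble with one row per substructure (see [students_method()]).
#' @export
students_method_map <- function(table, counts, vocab, target_id,
                                alpha = 0.05, var_equal = FALSE,
                                min_group = 3, p_adjust_method = "none") {
  ids <- if (inherits(vocab, "substructure_vocab")) {
    vocab$substructure_id
  } else {
    vocab
  }
  ids <- intersect(ids, colnames(counts))
  out <- bind_rows(purrr::map(ids, function(s) {
    students_method(table, counts, s, target_id, alpha, var_equal, min_group)
  }))
  if (p_adjust_method != "none") {
    adj <- p.adjust(out$t_p, method = p_adjust_method)
    relabel <- out$assessed
    out$t_p <- adj
    out$label[relabel] <- ifelse(
      adj[relabel] > alpha, "not significant",
      ifelse(out$mean_diff[relabel] > 0, "beneficial", "deleterious"))
  }
  structure(out, class = c("student_results", class(out)))
}

#' Classify substructures by isoform effect
#'
#' Combines Student's-method scans over two bioactivity sets (e.g. the two
#' isoforms of an enzyme) and bins each substructure that is significant in
#' at least one set: increase/decrease on set 1 only, on set 2 only, or on
#' both; substructures significant on both sets with opposite signs are
#' labelled `"discordant"`.
#'
#' @param results1,results2 `student_results` tibbles over the same
#'   vocabulary (from [students_method_map()]).
#' @return A tibble with `substructure_id`, the two per-set labels, and
#'   `bin`.
#' @export
classify_substructures <- function(results1, results2) {
  j <- dplyr::full_join(
    select(results1, "substructure_id", label1 = "label",
           diff1 = "mean_diff"),
    select(results2, "substructure_id", label2 = "label",
           diff2 = "mean_diff"),
    by = "substructure_id"
  )
  sig <- function(l) l %in% c("beneficial", "deleterious")
  j |>
    mutate(bin = dplyr::case_when(
      sig(.data$label1) & sig(.data$label2) &
        .data$label1 == .data$label2 & .data$label1 == "beneficial" ~ "increase on both",
      sig(.data$label1) & sig(.data$label2) &
        .data$label1 == .data$label2 ~ "decrease on both",
      sig(.data$label1) & sig(.data$label2) ~ "discordant",
      .data$label1 == "beneficial" ~ "increase on set 1 only",
      .data$label1 == "deleterious" ~ "decrease on set 1 only",
      .data$label2 == "beneficial" ~ "increase on set 2 only",
      .data$label2 == "deleterious" ~ "decrease on set 2 only",
      TRUE ~ "not significant"
    ))
}

#' Heatmap of substructure contributions across targets
#'
#' Draws the target-by-substructure matrix of mean count-zeroing
#' contributions. Bind the outputs of [predictive_contribution_map()] for
#' several targets and pass the result here.
#'
#' @param contributions Tibble with `substructure_id`, `target_id`,
#'   `mean_delta` (rows from one or more contribution maps).
#' @param top_n Keep the `top_n` substructures by maximum absolute
#'   contribution (default 30).
#' @return A ggplot object; red marks beneficial, blue deleterious.
#' @export
plot_contribution_heatmap <- function(contributions, top_n = 30) {
  ranked <- contributions |>
    group_by(.data$substructure_id) |>
    summarise(peak = max(abs(.data$mean_delta)), .groups = "drop") |>
    arrange(dplyr::desc(.data$peak)) |>
    utils::head(top_n)
  dat <- filter(contributions,
                .data$substructure_id %in% ranked$substructure_id)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$substructure_id, y = .data$target_id, fill = .data$mean_delta
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean ΔpIC50") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Volcano plot of Student's-method results
#'
#' Mean pIC50 difference against `-log10` p-value; point size proportional
#' to the number of compounds containing the substructure, significant
#' results highlighted.
#'
#' @param object A `student_results` tibble.
#' @param alpha Significance level for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.student_results <- function(object, alpha = 0.05, ...) {
  dat <- filter(object, .data$assessed)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$mean_diff, y = -log10(.data$t_p),
    size = .data$n_present, colour = .data$t_p <= alpha
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "mean pIC50 difference (present - absent)",
                  y = expression(-log[10](p)), size = "n compounds") +
    ggplot2::theme_minimal()
}
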