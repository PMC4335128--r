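# A transparent linear fit over a raw count design: y = intercept + counts %*% beta.
linear_probe <- function(raw_x, beta, intercept = 6) {
  y <- intercept + as.numeric(raw_x %*% beta)
  prep <- preprocess_fit(raw_x, ratio_cutoff = Inf)
  model <- fit_model(model_spec("lm"), prep$x, y)
  list(model = model, prep = prep, y = y)
}

count_design <- function(counts, prefix = "cmpd|") {
  colnames(counts) <- paste0(prefix, colnames(counts))
  counts
}

test_that("count-zeroing recovers linear coefficients exactly", {
  withr::with_seed(15, {
    raw <- cbind(s1 = rbinom(60, 1, 0.5), s2 = rbinom(60, 2, 0.5) + 1,
                 s3 = rbinom(60, 1, 0.4))
  })
  raw <- count_design(raw)
  lp <- linear_probe(raw, beta = c(2, -1, 0))
  c1 <- predictive_contribution(lp$model, raw, lp$prep, "s1")
  expect_equal(c1$mean_delta, 2, tolerance = 1e-8)
  expect_equal(c1$sd_delta, 0, tolerance = 1e-8)
  # zero-influence substructure
  c3 <- predictive_contribution(lp$model, raw, lp$prep, "s3")
  expect_equal(c3$mean_delta, 0, tolerance = 1e-8)
  expect_error(
    predictive_contribution(lp$model, raw * 0, lp$prep, "s1"),
    "absent"
  )
})

test_that("contributions are count-weighted means of per-compound deltas", {
  # two containing compounds: counts 1 and 3, coefficient +1
  raw <- count_design(cbind(s1 = c(1, 3, 0, 0, 2, 0), cov = c(1, 0, 1, 2, 1, 0)))
  lp <- linear_probe(raw, beta = c(1, 0.5))
  sub <- predictive_contribution(lp$model, raw[1:4, , drop = FALSE], lp$prep, "s1")
  # deltas are 1 and 3; weighted mean = (1*1 + 3*3) / 4 = 2.5
  expect_equal(sub$mean_delta, 2.5, tolerance = 1e-8)
  expect_equal(sub$n_compounds, 2L)
  expect_equal(sub$total_count, 4)
})

test_that("zeroing one substructure never touches other columns", {
  st <- recovery_study()
  raw <- st$design$x[1:20, , drop = FALSE]
  col <- colnames(raw)[which(colSums(raw > 0) > 5)[1]]
  zeroed <- raw
  zeroed[, col] <- 0
  others <- setdiff(colnames(raw), col)
  expect_identical(zeroed[, others], raw[, others])
})

test_that("the contribution map covers occurring substructures in stable order", {
  raw <- count_design(cbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0),
                            c = c(0, 0, 0, 0)))
  lp <- linear_probe(raw, beta = c(1.5, -0.5, 0))
  design <- list(
    x = raw,
    y = lp$y,
    meta = tibble::tibble(compound_id = paste0("C", 1:4), target_id = "T1"),
    compound_cols = colnames(raw), target_cols = character(0)
  )
  vocab <- tibble::tibble(substructure_id = c("a", "b", "c"))
  cm <- predictive_contribution_map(lp$model, design, lp$prep, vocab, "T1")
  expect_equal(nrow(cm), 2)             # only occurring substructures
  expect_equal(cm$substructure_id, c("a", "b"))  # ordered by |mean delta|
  cm2 <- predictive_contribution_map(lp$model, design, lp$prep, vocab, "T1")
  expect_identical(cm, cm2)
  expect_error(
    predictive_contribution_map(lp$model, design, lp$prep, vocab, "T9"),
    "no design rows"
  )
})

make_set_table <- function(y_present, y_absent, target = "T1") {
  n <- length(y_present) + length(y_absent)
  tab <- bioactivity_table(tibble::tibble(
    compound_id = paste0("C", seq_len(n)),
    target_id = target,
    pIC50 = c(y_present, y_absent)
  ))
  counts <- cbind(sub = c(rep(1L, length(y_present)),
                          rep(0L, length(y_absent))))
  rownames(counts) <- tab$compound_id
  list(table = tab, counts = counts)
}

test_that("the Shapiro-gated t-test labels shifted distributions by sign", {
  withr::with_seed(5, {
    same_a <- rnorm(50, 6, 0.5); same_b <- rnorm(50, 6, 0.5)
  })
  withr::with_seed(505, {
    up_a <- rnorm(50, 7, 0.5); up_b <- rnorm(50, 6, 0.5)
  })
  s_same <- make_set_table(same_a, same_b)
  r_same <- students_method(s_same$table, s_same$counts, "sub", "T1")
  expect_true(r_same$assessed)
  expect_equal(r_same$label, "not significant")

  s_up <- make_set_table(up_a, up_b)
  r_up <- students_method(s_up$table, s_up$counts, "sub", "T1")
  expect_equal(r_up$label, "beneficial")
  expect_lt(r_up$t_p, 0.05)
  expect_gt(r_up$mean_diff, 0.5)

  s_down <- make_set_table(up_b, up_a)
  expect_equal(students_method(s_down$table, s_down$counts, "sub", "T1")$label,
               "deleterious")

  # undersized groups are not assessed
  s_tiny <- make_set_table(up_a[1:2], up_b)
  r_tiny <- students_method(s_tiny$table, s_tiny$counts, "sub", "T1")
  expect_false(r_tiny$assessed)
  expect_equal(r_tiny$label, "not assessed")
  expect_error(students_method(s_up$table, s_up$counts, "sub", "T9"),
               "unknown target")
})

test_that("labels are invariant to compound order", {
  withr::with_seed(505, { a <- rnorm(40, 7, 0.5); b <- rnorm(40, 6, 0.5) })
  s <- make_set_table(a, b)
  r1 <- students_method(s$table, s$counts, "sub", "T1")
  perm <- withr::with_seed(6, sample(nrow(s$table)))
  tab_p <- bioactivity_table(s$table[perm, ])
  r2 <- students_method(tab_p, s$counts, "sub", "T1")
  expect_equal(r2$label, r1$label)
  expect_equal(r2$t_p, r1$t_p)
})

test_that("substructures are binned by their effect across two isoform sets", {
  mk <- function(label1, diff1) {
    tibble::tibble(substructure_id = "s", label = label1, mean_diff = diff1,
                   assessed = label1 %in% c("beneficial", "deleterious",
                                            "not significant"), t_p = 0.01)
  }
  expect_equal(classify_substructures(mk("beneficial", 1),
                                      mk("not significant", 0))$bin,
               "increase on set 1 only")
  expect_equal(classify_substructures(mk("beneficial", 1),
                                      mk("beneficial", 1))$bin,
               "increase on both")
  expect_equal(classify_substructures(mk("deleterious", -1),
                                      mk("deleterious", -1))$bin,
               "decrease on both")
  expect_equal(classify_substructures(mk("not assessed", NA),
                                      mk("deleterious", -1))$bin,
               "decrease on set 2 only")
  expect_equal(classify_substructures(mk("beneficial", 1),
                                      mk("deleterious", -1))$bin,
               "discordant")
})

test_that("planted bins are recovered for unit effects at adequate group size", {
  bins <- list(
    list(e1 = 1, e2 = 0, bin = "increase on set 1 only"),
    list(e1 = -1, e2 = 0, bin = "decrease on set 1 only"),
    list(e1 = 0, e2 = 1, bin = "increase on set 2 only"),
    list(e1 = 0, e2 = -1, bin = "decrease on set 2 only"),
    list(e1 = 1, e2 = 1, bin = "increase on both"),
    list(e1 = -1, e2 = -1, bin = "decrease on both")
  )
  for (k in seq_along(bins)) {
    b <- bins[[k]]
    withr::with_seed(900 + k, {
      n <- 45
      present <- rep(c(1L, 0L), each = n)
      y1 <- 6 + b$e1 * present + rnorm(2 * n, 0, 0.3)
      y2 <- 6 + b$e2 * present + rnorm(2 * n, 0, 0.3)
    })
    counts <- cbind(sub = present)
    rownames(counts) <- paste0("C", seq_len(2 * n))
    tab <- bioactivity_table(tibble::tibble(
      compound_id = rep(paste0("C", seq_len(2 * n)), 2),
      target_id = rep(c("T1", "T2"), each = 2 * n),
      pIC50 = c(y1, y2)
    ))
    r1 <- students_method_map(tab, counts, "sub", "T1")
    r2 <- students_method_map(tab, counts, "sub", "T2")
    expect_equal(classify_substructures(r1, r2)$bin, b$bin,
                 label = paste("bin scenario", k))
  }
})

test_that("contribution heatmaps and library summaries render", {
  contrib <- tibble::tibble(
    substructure_id = rep(c("a", "b"), 2),
    target_id = rep(c("T1", "T2"), each = 2),
    mean_delta = c(1, -0.5, -1, 0.5)
  )
  p <- ggplot2::ggplot_build(plot_contribution_heatmap(contrib))
  expect_equal(nrow(p$data[[1]]), 4)
  bench <- ensemble_bench()
  g <- glance(bench$lib)
  expect_equal(g$n_models, length(bench$lib$models))
  expect_equal(g$best_cv_rmse, min(bench$lib$cv_rmse))
})
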