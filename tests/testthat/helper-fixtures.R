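# Heavier synthetic studies are built once per session and shared across
# test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# attribution study: additive effects, low noise, radius-1 vocabulary
recovery_study <- function() {
  fixture("recovery", synthetic_pcm_study(
    n_compounds = 250, n_targets = 3,
    effects = list(cf3 = 1, sulfonamide = -1),
    noise_sd = 0.3, completeness = 0.8, interaction_sd = 0,
    target_offset_sd = 0.5, max_radius = 1, seed = 301
  ))
}

# isoform-flipped effect across the two target clusters
flipped_study <- function() {
  fixture("flipped", synthetic_pcm_study(
    n_compounds = 200, n_targets = 2,
    effects = list(cf3 = c(A = 1, B = -1)),
    noise_sd = 0.3, completeness = 0.8, interaction_sd = 0.1,
    target_offset_sd = 0.5, divergence = 0.4, seed = 401
  ))
}

# general-purpose small study at the default public-data noise level
small_study <- function() {
  fixture("small", synthetic_pcm_study(
    n_compounds = 80, n_targets = 4, completeness = 0.5, seed = 11
  ))
}

# ensemble benchmark study + trained default library
ensemble_bench <- function() {
  fixture("bench", {
    st <- synthetic_pcm_study(
      n_compounds = 200, n_targets = 5,
      effects = list(cf3 = 1, sulfonamide = -1, pyrrolyl = c(A = 0.5, B = -0.5)),
      noise_sd = 0.45, completeness = 0.5, interaction_sd = 0.15,
      target_offset_sd = 0.6, seed = 601
    )
    lib <- train_library(default_model_grid("small"), st$x, st$design$y,
                         st$folds, seed = 601)
    list(study = st, lib = lib)
  })
}

compound_counts <- function(st) {
  st$counts[st$compounds$compound_id, , drop = FALSE]
}

write_bioactivity_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# exhaustive search over integer weight vectors with total weight 1..n
brute_force_simplex <- function(P, y, n) {
  m <- ncol(P)
  best <- list(rmse = Inf, w = NULL)
  grid <- function(prefix, remaining, slots) {
    if (slots == 1) {
      w <- c(prefix, remaining)
      if (sum(w) > 0) {
        wn <- w / sum(w)
        r <- sqrt(mean((y - as.numeric(P %*% wn))^2))
        if (r < best$rmse - 1e-12) best <<- list(rmse = r, w = wn)
      }
      return(invisible())
    }
    for (k in 0:remaining) grid(c(prefix, k), remaining - k, slots - 1)
  }
  for (total in 1:n) grid(integer(0), total, m)
  best
}

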