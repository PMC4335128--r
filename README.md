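# pcmens

Ensemble proteochemometric (PCM) modeling of compound–target bioactivity in R.

## The problem

Inhibitor potency panels — many compounds assayed against a family of related
targets such as the cyclooxygenase isoforms — are sparse: most
compound–target pairs were never measured, and the measured pIC50 values
carry substantial experimental noise. A PCM model regresses bioactivity on
the *concatenation* of compound and target descriptors,

```
pIC50(i, j) ~ f( [ c(i) | t(j) ] )
```

so a single model interpolates and extrapolates in both the chemical and the
target space, predicting the potency of a compound on a target it was never
tested against. `pcmens` is for computational chemists who want that whole
workflow — curation, descriptors, model libraries, ensembles, error bars and
substructure-level interpretation — as composable, pipe-friendly R functions.

What the package provides:

* **Curation** — parse delimited IC50 exports, keep exact-equality nM records
  with assay confidence ≥ 8, convert to pIC50 = 9 − log10(IC50/nM), average
  replicates per compound–target pair (`parse_bioactivity_table()`,
  `apply_quality_filters()`, `to_pic50()`, `deduplicate()`,
  `summarize_bioactivity()`).
* **Descriptors** — keyed (unhashed) circular-substructure count
  fingerprints of maximal diameter four bonds, with portable canonical
  environment identifiers (`build_substructure_vocabulary()`,
  `unhashed_morgan_counts()`); five z-scales over selected binding-site
  alignment columns (`zscale_descriptors()`); near-zero-variance filtering
  at a 30/1 frequency ratio and train-statistics centering/scaling
  (`preprocess_fit()`); design assembly incl. family-QSAR/QSAM ablations
  (`assemble_pcm_matrix()`).
* **Model library** — a stratified 6-fold split with a held-out test fold,
  grid search by 5-fold cross-validation, and a library of GBM, random
  forest, SVR (linear/radial), elastic-net and linear regressors sharing the
  same folds, with aligned out-of-fold predictions (`make_folds()`,
  `grid_search_cv()`, `train_library()`).
* **Ensembles** — greedy weight optimization (Caruana-style selection with
  replacement, n = 1000 increments, weights normalized to sum 1) and model
  stacking (a meta-learner over the out-of-fold prediction matrix)
  (`greedy_optimize()`, `stack_fit()`).
* **Validation** — RMSE, q², through-origin R²₀ (slope s = Σyỹ/Σỹ²), Lin's
  CCC, threshold soundness checks (q²int > 0.5; q²test, R²₀test > 0.6),
  bootstrap SDs, y-scrambling curves, and a noise-injection simulation that
  bounds the best achievable test metrics given an experimental error of
  0.68 pIC50 units (`metrics_report()`, `tropsha_check()`, `bootstrap_sd()`,
  `y_scrambling_curve()`, `simulate_max_performance()`).
* **Applicability domain** — per-prediction confidence intervals
  ỹ ± β·E_std from the spread of ensemble member predictions, with empirical
  coverage curves over 0 < β ≤ 4 (`ensemble_std()`, `coverage_curve()`,
  `beta_for_confidence()`).
* **Interpretation** — substructure attribution by count-zeroing through the
  frozen preprocessing state (`predictive_contribution()`,
  `moiety_contribution()`) and by Shapiro-gated two-tailed t-tests between
  compounds carrying and lacking a substructure (`students_method()`,
  `classify_substructures()`), with volcano-plot and coverage-curve
  `autoplot()` methods.
* **Synthetic data** — a generator of valid SMILES with planted marker
  substituents, two-cluster binding-site alignments and sparse bioactivity
  matrices with known additive ground truth, so the entire pipeline is
  testable offline (`generate_compounds()`, `generate_targets()`,
  `generate_bioactivities()`, `synthetic_pcm_study()`).

## Worked example

```r
library(pcmens)

st <- synthetic_pcm_study(n_compounds = 120, n_targets = 4,
                          effects = list(cf3 = 1, sulfonamide = -1),
                          noise_sd = 0.68, completeness = 0.3, seed = 42)
st$table
#> <bioactivity_table> 144 datapoints, 120 compounds x 4 targets (30.0% complete)

specs <- list(model_spec("gbm", nrounds = 150),
              model_spec("rf", num_trees = 300),
              model_spec("svm_radial", cost = 4),
              model_spec("enet", alpha = 0.5, lambda = 0.01))
lib <- train_library(specs, st$x, st$design$y, st$folds, seed = 42)
tidy(lib)
#>   id                                       family     cv_rmse
#> 1 gbm[nrounds=150,max_depth=4,eta=0.1]     gbm          0.712
#> 2 rf[num_trees=300,mtry_frac=0.33]         rf           0.681
#> 3 svm_radial[cost=4,epsilon=0.1,gamma=NA]  svm_radial   0.759
#> 4 enet[alpha=0.5,lambda=0.01]              enet         0.789

ge <- greedy_optimize(lib$cv_predictions, lib$response, n = 1000)
glance(ge)
#>   n_members n_active cv_rmse
#> 1         4        4   0.679

te <- st$folds$test_rows
members <- predict_library(lib, st$x[te, , drop = FALSE])
metrics_report(st$design$y[te], greedy_predict(ge, members), context = "test")
#>   context  n  rmse    q2 r2_zero slope   ccc
#> 1 test    20 0.635 0.617   0.673 0.963 0.826
```

The greedy ensemble's cross-validated RMSE (0.679) undercuts every single
member (best 0.681), and its test RMSE of 0.635 sits near the noise floor:
with the generator's noise SD of 0.68, the noise-injection bound for this
test-set size is

```r
sim <- simulate_max_performance(st$design$y, sigma = 0.68,
                                sample_size = length(te), reps = 1000, seed = 42)
round(sim$means, 3)
#>    rmse      q2 r2_zero
#>   0.677   0.541   0.569
```

i.e. no model evaluated on 20 points of this panel can be expected to beat
an RMSE of about 0.68 pIC50 units without overfitting — observed metrics
beyond the bound flag an over-optimistic model, not a better one.

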