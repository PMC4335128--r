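---
title: "Ensemble proteochemometric modeling: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble proteochemometric modeling: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pcmens` models sparse compound-by-target potency panels with a single
regression over concatenated compound and target descriptors, combines
libraries of such models into ensembles, and interprets the fitted models at
the level of chemical substructures. This vignette records the scientific
choices behind the implementation: the model and its assumptions, the
parameters that matter, the numerical conventions, and what the synthetic
designs used in the test suite do and do not establish.

## The model

A bioactivity panel is a partially observed matrix of pIC50 values (pIC50 =
−log10 of the IC50 in molar units, so 1 nM ↦ 9.0). Each observed pair
(compound *i*, target *j*) contributes one design row: the horizontal
concatenation of the compound's keyed circular-substructure count vector and
the target's z-scale binding-site descriptor. Any regression family can then
be fitted; the package wires in gradient-boosted trees (xgboost), random
forests (ranger), support-vector regression with linear or radial kernels
(e1071), elastic nets (glmnet) and ordinary least squares.

The concatenation design is additive across the two spaces: a purely linear
model cannot represent compound effects whose *sign* depends on the target.
Tree and kernel families can, which is one reason a diverse model library
outperforms any single family on panels with isoform-selective chemistry.

Two ablations calibrate the value of the joint description: family QSAR
(compound block only) treats all targets as one, family QSAM (target block
only) treats all compounds as one. Both are expressible by passing `NULL`
for the other block in `assemble_pcm_matrix()`; on data with real
compound-by-target structure both collapse, which the test suite asserts as
a q² gap of at least 0.2 in favour of the joint model.

## Compound descriptors

Compounds are standardized to their largest carbon-containing fragment
(counter-ions and solvents stripped; molecules with no carbon rejected as
inorganic; no element, halogen or mass cut-offs). Circular atom environments
of radius 0, 1 and 2 bonds (maximal diameter 4) are enumerated and mapped to
a *keyed* count vector: every distinct environment in the training set gets
a canonical string identifier, and a molecule's fingerprint counts how many
of its atoms realize each identifier. Keyed counts sacrifice nothing in
accuracy relative to hashed fingerprints and keep every column chemically
addressable, which the interpretation machinery depends on.

Conventions worth knowing:

* Atom invariants are element / heavy-atom degree / formal charge /
  bond-order sum computed on the kekulized molecular graph (the SMILES
  round-trip used for parsing does not carry aromatic flags). Identifiers
  are canonical nested strings, not hash integers, so vocabularies are
  portable across runs and platforms. Two different SMILES spellings of the
  same molecule are only guaranteed identical counts if they kekulize
  identically; canonicalize upstream if that matters.
* An environment at radius *r* > 0 enters the vocabulary only if its bond
  ball strictly grows over radius *r* − 1; ethane therefore contributes two
  identifiers (not three), benzene three with count 6 each.
* The vocabulary is closed-world: environments of prediction-time molecules
  absent from the training vocabulary are silently ignored, keeping the
  design width fixed.

## Target descriptors

Each target is described by the five extended principal-property scales
(z1–z5) of the residues at selected binding-site alignment columns,
concatenated in column order (5 numbers per position). Gap characters map to
a five-zero vector: dimensions stay fixed and the gap row is distinct from
every residue row. Non-standard residue letters are an error naming the
sequence and column rather than a silent skip.

## Preprocessing

Descriptors are filtered and scaled on training rows only, and the frozen
transform is applied unchanged to held-out rows:

* Near-zero-variance rule: a column is dropped when constant or when the
  frequency ratio of its two most common values strictly exceeds 30 (the
  30/1 cut-off). The strict inequality keeps a 60:2 column and drops 31:1.
* Centering/scaling uses the sample SD (n − 1). A zero training SD is an
  error; the variance filter precludes it.
* `preprocess_fit(drop_linear_combos = TRUE)` optionally removes columns
  that are exact linear combinations of earlier ones (QR rank pruning).
  Keyed fingerprints are intrinsically redundant — an environment's count
  equals the sum of its refined variants — and exact collinearity makes
  least-squares attribution non-estimable; pruning restores a unique fit.

## Cross-validation discipline

`make_folds()` stratifies the response into 10 quantile bins (the bin count
is a package choice; fewer bins are used automatically when the response has
few distinct values) and deals each bin round-robin across 6 folds after a
seeded shuffle. One fold is the test set; the other five drive both
hyperparameter grid search (5-fold CV, lowest mean held-out RMSE wins, ties
to the first combination in grid order) and the out-of-fold predictions that
ensembles consume. Every library member shares the same fold assignment, so
the out-of-fold prediction matrix is comparable across members, and the test
fold never touches fitting, preprocessing statistics or vocabulary — a
property the test suite checks by deleting the test rows and re-deriving
bit-identical out-of-fold predictions.

## Ensembles

**Greedy weight optimization.** Integer weights start at zero; at each of up
to n = 1000 iterations, each member's weight is tentatively incremented and
the RMSE of the normalized weighted mean of out-of-fold predictions
evaluated; the best increment is applied if it does not worsen the fit (ties
to the lowest member index). Evaluating candidates on *normalized* weights
makes the first iteration select the best single member, so the final
ensemble never trails it, and the RMSE trace is non-increasing by
construction. Once no increment helps, the state is a fixed point and the
search stops early. A consequence worth stating: a stalled search stops
refining its weight resolution, so greedy weights are a local grid optimum;
on small libraries with an exactly representable optimum they coincide with
exhaustive search over the integer-weight simplex, which the tests verify
against a brute-force oracle.

**Model stacking.** A meta-learner (linear, elastic net, SVR linear/radial,
or random forest) is fitted with the out-of-fold prediction matrix as
features. Meta hyperparameters are tuned by cross-validation on the same
fold assignment as the library — the meta-learner must not see information
the members did not have. Linear and elastic-net metas expose a member
weight vector; the others do not.

Members with zero weight stay in the ensemble manifest: the
applicability-domain spread deliberately uses the whole library.

## Error bars and the noise floor

**Per-prediction intervals.** For each datapoint the ensemble standard
deviation E_std is the unweighted sample SD of the member predictions
(unweighted for all ensemble types — the greedy weights are a fit artifact,
not a variance model; the choice is recorded in output metadata). The
interval is ỹ ± β·E_std with β > 0; coverage is the fraction of datapoints
whose observed value falls inside (boundary inclusive, matching the ±
definition). The default β grid is 0.1 to 4.0 in steps of 0.1.
`beta_for_confidence()` returns the smallest grid β reaching a requested
coverage and errors, naming the maximum, when the level is unattainable.
Cross-validation coverage being below test coverage is an empirical
observation, not an invariant, and is not asserted anywhere.

**Noise-bounded maximum performance.** Public IC50 data carry an average
experimental SD of about 0.68 pIC50 units. `simulate_max_performance()`
draws test-set-sized samples from a pIC50 pool (without replacement by
default; with replacement on explicit opt-in), adds N(0, σ) noise and
computes the metrics of the sample against its noisy copy — the sample is
the observed vector and the noisy copy plays the predictions, an orientation
that matters for the asymmetric R²₀. The mean of the minimum-RMSE
distribution converges to σ; the q² ceiling approaches 1 − σ²/Var(pool), so
a narrow bioactivity range caps q² well below 1 no matter how good the
model. Observed metrics *better* than these bounds indicate an
over-optimistic model.

**y-scrambling.** A seeded fraction of the *training* responses is permuted
(permutation, not resampling, preserves the marginal distribution), the
designated model retrained, and the untouched test fold scored. Fraction 0
must reproduce the unscrambled metrics exactly; at fraction 1 external q²
drops to or below zero in expectation.

## Substructure interpretation

**Predictive (count-zeroing) method.** For every compound containing a
substructure, its count is set to zero in raw descriptor space, the frozen
preprocessing transform re-applied, and the prediction drop Δ recorded. The
summary is the count-weighted mean of Δ (weights = the substructure's count
per compound; the SD of Δ is reported unweighted and labelled as such). A
positive mean marks the substructure beneficial. Because a chemical moiety
manifests as a *family* of mutually collinear environment columns, a model
may spread its influence across the family; `moiety_contribution()` zeroes
the family jointly and measures the model's total attribution, which for a
linear model is independent of how the fit distributed the coefficients.

**Student's method.** Model-free: within one bioactivity set (one target),
the pIC50 distributions of compounds with and without the substructure are
compared. Both groups must pass the Shapiro–Wilk normality gate at α = 0.05
— groups that fail are reported "not assessed", never silently routed to a
nonparametric test — and then a two-tailed independent-samples t-test at
α = 0.05 labels the substructure by the sign of the mean difference. Welch's
variant is the default (a pooled-variance switch exists); groups under 3
members are not assessed. No multiple-testing correction is applied by
default, matching the single-panel scale of the analysis; a
Benjamini–Hochberg switch (`p_adjust_method = "BH"`) is provided for larger
vocabularies.

The two methods answer different questions and may legitimately disagree:
a substructure that always co-occurs with a potent one is flagged by the
group comparison but receives no credit from the model-based zeroing. The
test suite constructs exactly this scenario and asserts the disagreement
rather than reconciling it.

## The synthetic-data generator

The generator exists so that every stage has a testable ground truth. It
emulates the statistical structure of a curated public panel — a sparse
pIC50 matrix (default completeness 0.14), per-target offsets, a small
compound-by-target interaction, and Gaussian noise at the public-data SD of
0.68 — on top of an additive substructure signal:

pIC50(i, j) = base + Σₘ effect(m, cluster(j))·count(i, m) + offset(j) +
interaction(i, j) + noise.

Compounds are seeded decorations of ~12 embedded scaffolds (aromatic rings,
pyrrole, thiazole, furanone, carbonyl, sulfonyl and indole motifs); marker
substituents (trifluoromethyl, sulfonamide, 2-pyrrolyl) are inserted with
controlled probability, at most once per compound so that attribution
weights stay interpretable. Decoration fragments deliberately avoid atoms
whose environments would be shared with the markers (bare F, primary-amine
N, methylsulfonyl S): marker environments remain unique to marker-carrying
compounds and the planted effects stay identifiable — with shared channels,
a least-squares fit can lawfully reassign part of an effect to a correlated
column and no attribution method can recover it exactly. Targets form two
"isoform clusters" diverging at a controlled fraction of positions, so
cluster-flipped effects emulate isoform-selective chemistry.

Additive linear truth was chosen deliberately: closed-form oracles exist for
every attribution test. What the generator does **not** emulate: real
structure–activity cliffs, correlated substructure co-occurrence beyond what
the scaffolds impose, assay heterogeneity, censored values at detection
limits, and realistic ChEMBL value distributions beyond range and sparsity.
Passing tests therefore demonstrate the machinery is correct under known
ground truth, not that real panels meet the model's assumptions.

Two test-design choices deserve a note. First, attribution-recovery studies
use a radius-1 vocabulary and a lasso PCM model: the reduced redundancy and
the sparsity preference concentrate each planted effect onto its marker's
environment family, which joint zeroing then recovers within the asserted
±0.25. Second, the Student's-method recovery plants the effect
isoform-flipped across the two target clusters (one marker signal per
bioactivity set): two independent ±1 effects inside one set would make both
groups bimodal mixtures that the Shapiro gate rightly refuses, so the
flipped design is the one under which the gate-then-test pipeline is
meaningfully exercised — and it mirrors the two-isoform structure the method
was designed for.

## Numerical conventions and degenerate inputs

* pIC50 conversion is fixed to the molar convention (9 − log10 nM); values
  must be strictly positive.
* Replicate aggregation is the arithmetic mean; the per-pair SD is kept for
  diagnostics.
* Relationship symbols are compared after whitespace trimming; the unit
  match is case-insensitive `nm`. Unparseable activity values are skipped
  with a warning, not fatal.
* Soundness thresholds (q²int > 0.5; q²test, R²₀test > 0.6) are strict
  inequalities and configurable.
* Ties break to the first candidate in declared order everywhere (grid
  search, greedy increments), for reproducibility.
* q² and R²₀ error on constant observed vectors; R²₀ errors on all-zero
  predictions; CCC errors on zero variance. These are domain errors, not
  NaNs.
* All stochastic operations (folds, library training, bootstrap,
  simulations, generators) are reproducible from an integer seed.

## Problem sizes in the test suite

The shipped tests run scaled-down studies — 80 to 250 compounds, 2 to 6
targets, libraries of up to 28 models with completeness 0.3–0.8 — sizes at
which every assertion, including the ensemble-versus-best-member comparisons
and the ±0.25 attribution recovery, is stable across seeds while the whole
suite stays fast. The same code paths scale to panels of thousands of
compounds and model libraries in the hundreds; `default_model_grid("full")`
ships a few-hundred-model grid for such runs.

## Known limitations

* Environment identifiers are invariant-string based, not full canonical
  graph codes; colliding non-isomorphic environments are theoretically
  possible though not observed in practice.
* Stereochemistry is ignored (heavy-atom graph only).
* The additive pIC50 model behind the generator cannot produce activity
  cliffs; attribution accuracy on real data is bounded by model quality, as
  the count-zeroing method sees only what the model learned.
* Confidence intervals from ensemble spread are calibration-free: β must be
  chosen from an empirical coverage curve, and transfers across chemical
  series only as far as the applicability domain does.
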