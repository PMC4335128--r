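Package: pcmens
Title: Ensemble Proteochemometric Modeling of Compound-Target Bioactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteochemometric (PCM) regression toolkit for sparse
    compound-by-target bioactivity panels. Curates IC50 exports into
    deduplicated pIC50 tables; describes compounds with keyed (unhashed)
    circular-substructure count fingerprints and binding sites with
    five-component z-scale descriptors; trains libraries of gradient-boosted
    tree, random-forest, support-vector and penalized linear regressors under
    a shared stratified cross-validation split; combines them by greedy
    weight optimization and model stacking; bounds achievable performance
    given bioactivity-data noise; derives per-prediction confidence
    intervals from ensemble spread; and attributes potency and selectivity
    to compound substructures by count-zeroing and by Shapiro-gated t-tests.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stringr,
    readr,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    glmnet,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
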