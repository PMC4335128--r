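# Embedded scaffold/substituent sets for the synthetic compound generator.
# Templates carry {R} slots; substituent fragments are written so that
# "(" + fragment + ")" is a valid branch (ring labels 2+ to avoid clashes
# with the scaffold's ring 1).
.synth_scaffolds <- c(
  "c1ccc{R}cc1",
  "c1cc{R}ccc1{R}",
  "c1ccc{R}c{R}c1",
  "c1cc{R}[nH]c1",
  "c1csc{R}n1",
  "c1cc{R}on1",
  "c1cc{R}oc1",
  "O=C{R}c1ccc{R}cc1",
  "O=C1OC{R}C1{R}",
  "c1cnc{R}cn1",
  "C1CCN{R}CC1",
  "c1ccc2[nH]c{R}cc2c1"
)

# Decorations avoid atoms in environments that would be shared with the
# marker substituents (bare F, primary amine N, methylsulfonyl S), so each
# marker's keyed environments stay unique to marker-carrying compounds and
# planted effects remain identifiable.
.synth_substituents <- c(
  "C", "CC", "CCC", "C(C)C", "CC(C)C", "O", "OC", "OCC", "NC", "N(C)C",
  "Cl", "Br", "C=C", "CO", "C#N", "CC=O", "c2ccccc2", "c2ccncc2"
)

.default_markers <- c(
  cf3 = "C(F)(F)F",
  sulfonamide = "S(N)(=O)=O",
  pyrrolyl = "c2ccc[nH]2"
)

fill_template <- function(template, frags) {
  for (f in frags) {
    template <- sub("{R}", if (is.na(f)) "" else paste0("(", f, ")"),
                    template, fixed = TRUE)
  }
  template
}

#' Generate synthetic drug-like compounds
#'
#' Builds SMILES by seeded decoration of a small embedded scaffold set
#' (aromatic rings, pyrrole, thiazole, furanone, carbonyl and sulfonyl
#' motifs). Designated marker substituents (trifluoromethyl, sulfonamide
#' and 2-pyrrolyl by default) are inserted with controlled probability and
#' at most once per compound, and their realized counts are reported, so
#' downstream attribution tests know the ground truth.
#'
#' @param n Number of compounds.
#' @param seed Integer seed; the same seed reproduces the same list.
#' @param markers Named character vector of marker substituent fragments.
#' @param marker_probs Named numeric insertion probabilities aligned to
#'   `markers` (default 0.35 each).
#' @return A tibble with `compound_id`, `smiles` and one integer count
#'   column per marker name.
#' @export
generate_compounds <- function(n, seed = 1, markers = .default_markers,
                               marker_probs = NULL) {
  if (n < 1) abort("n must be >= 1")
  marker_probs <- marker_probs %||%
    setNames(rep(0.35, length(markers)), names(markers))
  stopifnot(all(names(markers) %in% names(marker_probs)))
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      template <- sample(.synth_scaffolds, 1)
      n_slots <- stringr::str_count(template, stringr::fixed("{R}"))
      slots <- rep(NA_character_, n_slots)
      m_counts <- setNames(integer(length(markers)), names(markers))
      for (m in sample(names(markers))) {
        empty <- which(is.na(slots))
        if (length(empty) == 0) break
        if (runif(1) < marker_probs[[m]]) {
          slots[sample(c(empty, empty), 1)] <- markers[[m]]
          m_counts[m] <- 1L
        }
      }
      for (j in which(is.na(slots))) {
        # leave some slots bare to vary substitution patterns
        slots[j] <- if (runif(1) < 0.25) NA_character_ else
          sample(.synth_substituents, 1)
      }
      bind_cols(
        tibble(compound_id = sprintf("SYN%04d", i),
               smiles = fill_template(template, slots)),
        as_tibble(as.list(m_counts))
      )
    })
    bind_rows(rows)
  })
}

#' Generate aligned synthetic binding-site sequences
#'
#' Produces two "isoform clusters" of aligned residue strings: a shared
#' random consensus, a controlled fraction of positions at which the two
#' clusters differ, and light within-cluster variation so sequences are
#' distinct. All positions are selected.
#'
#' @param n_targets Number of sequences (>= 2); the first half form cluster
#'   A, the rest cluster B.
#' @param n_positions Alignment length (default 25).
#' @param divergence Fraction of positions at which the clusters differ
#'   (default 0.3).
#' @param seed Integer seed.
#' @param within_variation Per-sequence fraction of positions mutated
#'   within each cluster (default 0.05).
#' @return A list with `sequences` (named character vector, ids `T01`...),
#'   `cluster` (named `"A"`/`"B"`), and `selected_columns`.
#' @export
generate_targets <- function(n_targets, n_positions = 25, divergence = 0.3,
                             seed = 1, within_variation = 0.05) {
  if (n_targets < 2) abort("need at least 2 targets")
  aas <- rownames(zscale_matrix())
  withr::with_seed(seed, {
    consensus_a <- sample(aas, n_positions, replace = TRUE)
    consensus_b <- consensus_a
    n_div <- round(divergence * n_positions)
    if (n_div > 0) {
      pos <- sample.int(n_positions, n_div)
      consensus_b[pos] <- vapply(consensus_a[pos], function(a) {
        sample(setdiff(aas, a), 1)
      }, character(1))
    }
    cluster <- rep(c("A", "B"), c(ceiling(n_targets / 2),
                                  floor(n_targets / 2)))
    seqs <- vapply(seq_len(n_targets), function(i) {
      s <- if (cluster[i] == "A") consensus_a else consensus_b
      n_mut <- round(within_variation * n_positions)
      if (n_mut > 0) {
        pos <- sample.int(n_positions, n_mut)
        s[pos] <- vapply(s[pos], function(a) sample(setdiff(aas, a), 1),
                         character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    ids <- sprintf("T%02d", seq_len(n_targets))
    list(sequences = setNames(seqs, ids),
         cluster = setNames(cluster, ids),
         selected_columns = seq_len(n_positions))
  })
}

#' Generate sparse bioactivities with known additive ground truth
#'
#' pIC50 for compound i on target j is
#' `base + sum_m effect(m, cluster(j)) * count_i(m) + offset(j) +
#' interaction(i, j) + noise`, with marker counts from
#' [generate_compounds()], per-target offsets, a compound-by-target
#' interaction term and Gaussian noise. A seeded subset of pairs is kept to
#' emulate the sparsity of public bioactivity matrices.
#'
#' @param compounds Tibble from [generate_compounds()].
#' @param targets List from [generate_targets()].
#' @param effects Named list (by marker name): either a single number
#'   (cluster-independent effect in pIC50 units) or a vector
#'   `c(A = ..., B = ...)` for isoform-flipped effects. Markers absent from
#'   the list have no effect.
#' @param base Baseline pIC50 (default 6.5).
#' @param target_offset_sd SD of per-target offsets (default 0.5).
#' @param interaction_sd SD of the compound-target interaction (default
#'   0.1).
#' @param noise_sd Gaussian noise SD in pIC50 units (default 0.68, the
#'   experimental uncertainty of public IC50 data).
#' @param completeness Fraction of the compound-target matrix retained
#'   (default 0.14).
#' @param seed Integer seed.
#' @return A list with `table` (a `bioactivity_table` including SMILES) and
#'   `truth` (all generating parameters plus the realized per-target
#'   offsets).
#' @export
generate_bioactivities <- function(compounds, targets, effects = list(),
                                   base = 6.5, target_offset_sd = 0.5,
                                   interaction_sd = 0.1, noise_sd = 0.68,
                                   completeness = 0.14, seed = 1) {
  if (completeness <= 0 || completeness > 1) {
    abort("completeness must be in (0, 1]")
  }
  tids <- names(targets$sequences)
  cids <- compounds$compound_id
  n_c <- length(cids)
  n_t <- length(tids)
  effect_of <- function(m, cl) {
    e <- effects[[m]]
    if (is.null(e)) return(0)
    if (length(e) == 1 && is.null(names(e))) return(unname(e))
    unname(e[[cl]])
  }
  withr::with_seed(seed, {
    offsets <- setNames(rnorm(n_t, 0, target_offset_sd), tids)
    grid <- tidyr::expand_grid(compound_id = cids, target_id = tids)
    cl <- targets$cluster[grid$target_id]
    marker_effect <- rep(0, nrow(grid))
    for (m in intersect(names(effects), names(compounds))) {
      cnt <- compounds[[m]][match(grid$compound_id, cids)]
      marker_effect <- marker_effect +
        cnt * vapply(cl, effect_of, numeric(1), m = m)
    }
    pic50 <- unname(base + marker_effect + offsets[grid$target_id] +
      rnorm(nrow(grid), 0, interaction_sd) +
      rnorm(nrow(grid), 0, noise_sd))
    keep <- sample.int(nrow(grid), size = max(2, round(completeness * nrow(grid))))
    entries <- grid[sort(keep), ] |>
      mutate(pIC50 = pic50[sort(keep)],
             smiles = compounds$smiles[match(.data$compound_id, cids)])
    table <- bioactivity_table(entries, compounds = cids, targets = tids)
    list(
      table = table,
      truth = list(effects = effects, base = base,
                   target_offsets = offsets,
                   interaction_sd = interaction_sd, noise_sd = noise_sd,
                   completeness = completeness, seed = seed,
                   cluster = targets$cluster)
    )
  })
}

#' One-call synthetic proteochemometric study
#'
#' Convenience wrapper chaining compound generation, target generation,
#' bioactivity simulation, structure standardization, vocabulary and count
#' fingerprints, z-scale descriptors, design assembly, preprocessing and
#' fold assignment — everything needed to exercise the modeling pipeline on
#' data with known ground truth.
#'
#' @param n_compounds,n_targets Study size.
#' @param effects,noise_sd,completeness,interaction_sd,target_offset_sd
#'   Passed to [generate_bioactivities()].
#' @param divergence Cluster divergence for [generate_targets()].
#' @param marker_probs Passed to [generate_compounds()].
#' @param max_radius Fingerprint radius (default 2; use 1 for low-redundancy
#'   vocabularies in attribution studies).
#' @param drop_linear_combos Passed to [preprocess_fit()]; TRUE makes the
#'   design full rank for least-squares attribution studies.
#' @param seed Integer seed driving every stage.
#' @return A list with `compounds`, `targets`, `table`, `truth`, `vocab`,
#'   `counts` (compound count matrix), `zblock`, `design` (raw
#'   `pcm_design`), `prep` (fitted on training rows), `x` (preprocessed
#'   matrix), `folds`.
#' @export
synthetic_pcm_study <- function(n_compounds = 150, n_targets = 4,
                                effects = list(cf3 = 1, sulfonamide = -1),
                                noise_sd = 0.68, completeness = 0.14,
                                interaction_sd = 0.1, target_offset_sd = 0.5,
                                divergence = 0.3, marker_probs = NULL,
                                max_radius = 2, drop_linear_combos = FALSE,
                                seed = 1) {
  compounds <- generate_compounds(n_compounds, seed = seed,
                                  marker_probs = marker_probs)
  targets <- generate_targets(n_targets, seed = seed + 1,
                              divergence = divergence)
  sim <- generate_bioactivities(compounds, targets, effects = effects,
                                noise_sd = noise_sd,
                                completeness = completeness,
                                interaction_sd = interaction_sd,
                                target_offset_sd = target_offset_sd,
                                seed = seed + 2)
  smiles <- setNames(compounds$smiles, compounds$compound_id)
  vocab <- build_substructure_vocabulary(smiles, max_radius = max_radius)
  counts <- morgan_count_matrix(smiles, vocab)
  zblock <- zscale_descriptors(targets$sequences, targets$selected_columns)
  design <- assemble_pcm_matrix(counts, zblock, sim$table)
  folds <- make_folds(design$y, k = 6, seed = seed + 3)
  prep <- preprocess_fit(design$x, fit_rows = folds$train_rows,
                         drop_linear_combos = drop_linear_combos)
  list(
    compounds = compounds, targets = targets, table = sim$table,
    truth = sim$truth, vocab = vocab, counts = counts, zblock = zblock,
    design = design, prep = prep, x = preprocess_apply(prep, design$x),
    folds = folds
  )
}
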