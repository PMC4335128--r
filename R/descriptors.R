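#' Standardize compound structures
#'
#' Reduces each SMILES to its largest organic fragment: the input is split at
#' the fragment separator, each fragment parsed, and the carbon-containing
#' fragment with the most heavy atoms kept (counter-ions and solvents are
#' thereby stripped). Molecules with no carbon-containing fragment are
#' rejected as inorganic; unparseable inputs are rejected with the parser
#' reason. No element, halogen-count or molecular-mass restriction is
#' applied.
#'
#' @param smiles_list Character vector of SMILES; names (compound ids) are
#'   carried through when present.
#' @return A tibble with `compound_id` (names or index), `input_smiles`,
#'   `standardized_smiles` (NA when rejected), `kept` and `reason`.
#' @export
#' @examples
#' \donttest{
#' standardize_structures(c("CCO", "CC(=O)O.[Na+]", "[Na+].[Cl-]"))
#' }
standardize_structures <- function(smiles_list) {
  ids <- names(smiles_list) %||% as.character(seq_along(smiles_list))
  rows <- purrr::map2(smiles_list, ids, function(smi, id) {
    frags <- stringr::str_split_1(smi, stringr::fixed("."))
    parsed <- purrr::map(frags, function(f) {
      tryCatch(smiles_to_graph(f), error = function(e) NULL)
    })
    ok <- !vapply(parsed, is.null, logical(1))
    if (!any(ok)) {
      return(tibble(compound_id = id, input_smiles = smi,
                    standardized_smiles = NA_character_,
                    kept = FALSE, reason = "unparseable"))
    }
    has_c <- vapply(parsed, function(g) {
      !is.null(g) && any(g$elements == "C")
    }, logical(1))
    if (!any(has_c)) {
      return(tibble(compound_id = id, input_smiles = smi,
                    standardized_smiles = NA_character_,
                    kept = FALSE, reason = "inorganic"))
    }
    sizes <- ifelse(has_c, vapply(parsed, function(g) {
      if (is.null(g)) 0L else g$n_atoms
    }, integer(1)), -1L)
    best <- which.max(sizes)
    tibble(compound_id = id, input_smiles = smi,
           standardized_smiles = frags[best], kept = TRUE, reason = NA_character_)
  })
  bind_rows(rows)
}

#' Build the keyed circular-substructure vocabulary
#'
#' Enumerates every circular atom environment of radius 0 to `max_radius`
#' bonds (maximal diameter `2 * max_radius` bonds) occurring in at least one
#' training compound and assigns each a stable canonical identifier. The
#' vocabulary row order (sorted by identifier) defines the fingerprint
#' column order and is stable across saves and platforms.
#'
#' @param smiles_list Standardized SMILES character vector.
#' @param max_radius Maximum environment radius in bonds (default 2).
#' @return A `substructure_vocab` tibble with columns `substructure_id`,
#'   `radius`, `example_smiles` (a molecule containing the environment),
#'   `example_atom` (its center atom index) and `n_compounds`.
#' @export
build_substructure_vocabulary <- function(smiles_list, max_radius = 2) {
  if (length(smiles_list) == 0) abort("empty SMILES list")
  envs <- purrr::map(smiles_list, function(smi) {
    g <- smiles_to_graph(smi)
    mutate(atom_environments(g, max_radius), smiles = smi)
  }) |> bind_rows()
  vocab <- envs |>
    group_by(substructure_id = .data$id) |>
    summarise(
      radius = .data$radius[1],
      example_smiles = .data$smiles[1],
      example_atom = .data$atom[1],
      n_compounds = dplyr::n_distinct(.data$smiles),
      .groups = "drop"
    ) |>
    arrange(.data$substructure_id)
  structure(vocab, class = c("substructure_vocab", class(vocab)))
}

#' Keyed circular-substructure counts for one molecule
#'
#' Counts, for every vocabulary entry, the atoms of the molecule whose
#' circular environment at the entry's radius carries that identifier.
#' Environments absent from the vocabulary are ignored: the keyed array is
#' closed-world, so prediction-time molecules cannot widen the design
#' matrix.
#'
#' @param smiles A single SMILES string.
#' @param vocab A `substructure_vocab` from [build_substructure_vocabulary()].
#' @return An integer vector of length `nrow(vocab)` named by
#'   `substructure_id`.
#' @export
unhashed_morgan_counts <- function(smiles, vocab) {
  g <- smiles_to_graph(smiles)
  envs <- atom_environments(g, max_radius = max(vocab$radius))
  counts <- table(factor(envs$id, levels = vocab$substructure_id))
  setNames(as.integer(counts), vocab$substructure_id)
}

#' Keyed count matrix for a set of molecules
#'
#' @param smiles_list Character vector of SMILES; names become row names.
#' @inheritParams unhashed_morgan_counts
#' @return Integer matrix, one row per molecule, columns keyed by
#'   `substructure_id`.
#' @export
morgan_count_matrix <- function(smiles_list, vocab) {
  ids <- names(smiles_list) %||% as.character(seq_along(smiles_list))
  m <- t(vapply(smiles_list, unhashed_morgan_counts,
                integer(nrow(vocab)), vocab = vocab))
  rownames(m) <- ids
  m
}

#' Serialize and restore vocabularies and preprocessing state as JSON
#'
#' Keyed vocabularies and fitted preprocessing transforms are plain data;
#' JSON keeps them portable across runs and platforms. Round-tripping
#' restores a bit-identical transform.
#'
#' @param vocab A `substructure_vocab`.
#' @param prep A `pcm_preprocess` from [preprocess_fit()].
#' @param path Output/input file path.
#' @return The file path (writers) or the restored object (readers).
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as_tibble(vocab), path, digits = NA)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocab <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  vocab <- arrange(vocab, .data$substructure_id)
  structure(vocab, class = c("substructure_vocab", class(vocab)))
}

#' @rdname write_vocabulary
#' @export
write_preprocess <- function(prep, path) {
  jsonlite::write_json(
    list(kept = as.list(prep$kept), center = as.list(prep$center),
         scale = as.list(prep$scale)),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_preprocess <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(kept = unlist(raw$kept), center = unlist(raw$center),
         scale = unlist(raw$scale)),
    class = "pcm_preprocess"
  )
}

#' Z-scale descriptors for aligned binding-site sequences
#'
#' Describes each target by the concatenation of the five extended
#' principal-property scales (z1..z5) of the residues at the selected
#' alignment columns, in column order. Gap characters map to a 5-zero
#' vector, which keeps the block width fixed while remaining distinct from
#' every residue row.
#'
#' @param alignment Either a path to an aligned FASTA file or a named
#'   character vector of equal-length aligned sequences.
#' @param selected_columns 1-based alignment column indices (default: all
#'   columns).
#' @return Numeric matrix with one row per sequence and `5 *
#'   length(selected_columns)` columns named `p<col>_z<k>`.
#' @export
zscale_descriptors <- function(alignment, selected_columns = NULL) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    aa <- Biostrings::readAAStringSet(alignment)
    seqs <- setNames(as.character(aa), names(aa))
  } else {
    seqs <- alignment
  }
  if (length(seqs) == 0) abort("empty alignment")
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) abort("aligned sequences differ in length")
  width <- widths[1]
  selected_columns <- selected_columns %||% seq_len(width)
  if (any(selected_columns < 1 | selected_columns > width)) {
    abort("selected columns out of alignment bounds")
  }
  zs <- zscale_matrix()
  gap_chars <- c("-", ".")
  out <- matrix(0, nrow = length(seqs), ncol = 5 * length(selected_columns))
  rownames(out) <- names(seqs)
  colnames(out) <- as.vector(vapply(selected_columns, function(p) {
    paste0("p", p, "_z", 1:5)
  }, character(5)))
  for (i in seq_along(seqs)) {
    letters_i <- stringr::str_split_1(seqs[[i]], "")[selected_columns]
    for (j in seq_along(letters_i)) {
      ch <- toupper(letters_i[j])
      if (ch %in% gap_chars) next
      if (!ch %in% rownames(zs)) {
        abort(sprintf("non-standard residue '%s' in sequence '%s', alignment column %d",
                      ch, names(seqs)[i], selected_columns[j]))
      }
      out[i, (5 * (j - 1) + 1):(5 * j)] <- zs[ch, ]
    }
  }
  out
}

#' Remove near-zero-variance columns
#'
#' A column is removed when it is constant over the fitted rows or when the
#' frequency ratio of its most common to its second most common value
#' strictly exceeds `ratio_cutoff` (default 30, i.e. a 30/1 cut-off). The
#' fitted mask must be reapplied unchanged to held-out rows.
#'
#' @param x Numeric matrix.
#' @param ratio_cutoff Frequency-ratio cut-off (default 30).
#' @param fit_rows Row indices to fit on (default: all rows). Held-out rows
#'   never influence the mask.
#' @return A list with `x` (the reduced matrix) and `kept` (named logical
#'   mask over the input columns).
#' @export
remove_near_zero_variance <- function(x, ratio_cutoff = 30,
                                      fit_rows = seq_len(nrow(x))) {
  if (ncol(x) == 0) abort("no columns to filter")
  xf <- x[fit_rows, , drop = FALSE]
  kept <- vapply(seq_len(ncol(xf)), function(j) {
    tab <- sort(table(xf[, j]), decreasing = TRUE)
    if (length(tab) < 2) return(FALSE)
    !(tab[1] / tab[2] > ratio_cutoff)
  }, logical(1))
  names(kept) <- colnames(x)
  if (!any(kept)) abort("all columns removed by near-zero-variance filter")
  list(x = x[, kept, drop = FALSE], kept = kept)
}

#' Center and scale columns using training-row statistics
#'
#' Subtracts the per-column mean and divides by the per-column sample
#' standard deviation (n-1 denominator), both computed on `fit_rows` only;
#' the identical affine transform is applied to all rows. Run the
#' near-zero-variance filter first so no training SD is zero.
#'
#' @inheritParams remove_near_zero_variance
#' @return A list with `x` (scaled matrix), `center` and `scale` (named
#'   numeric vectors).
#' @export
center_scale <- function(x, fit_rows = seq_len(nrow(x))) {
  xf <- x[fit_rows, , drop = FALSE]
  ctr <- colMeans(xf)
  scl <- apply(xf, 2, sd)
  if (any(scl == 0)) {
    abort(paste0("zero training SD in column(s): ",
                 paste(colnames(x)[scl == 0], collapse = ", ")))
  }
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Fit the full preprocessing transform on training rows
#'
#' Convenience wrapper chaining [remove_near_zero_variance()] and
#' [center_scale()], fitted on `fit_rows` only.
#'
#' @inheritParams remove_near_zero_variance
#' @param drop_linear_combos Also drop columns that are exact linear
#'   combinations of earlier columns on the fitted rows (QR rank pruning),
#'   making the design full rank. Default FALSE; useful before
#'   ordinary-least-squares fits and count-zeroing attribution, where exact
#'   collinearity leaves coefficients unidentifiable.
#' @return A `pcm_preprocess` object with `kept`, `center`, `scale` and the
#'   transformed matrix in `x`.
#' @export
preprocess_fit <- function(x, fit_rows = seq_len(nrow(x)), ratio_cutoff = 30,
                           drop_linear_combos = FALSE) {
  nzv <- remove_near_zero_variance(x, ratio_cutoff, fit_rows)
  kept <- nzv$kept
  xr <- nzv$x
  if (drop_linear_combos) {
    qr_d <- qr(cbind(1, xr[fit_rows, , drop = FALSE]))
    if (qr_d$rank < ncol(xr) + 1) {
      dep <- qr_d$pivot[-seq_len(qr_d$rank)] - 1  # shift past intercept
      dep <- dep[dep > 0]
      kept[colnames(xr)[dep]] <- FALSE
      xr <- xr[, setdiff(colnames(xr), colnames(xr)[dep]), drop = FALSE]
    }
  }
  cs <- center_scale(xr, fit_rows)
  structure(
    list(kept = kept, center = cs$center, scale = cs$scale, x = cs$x),
    class = "pcm_preprocess"
  )
}

#' Apply a fitted preprocessing transform to new rows
#'
#' @param prep A `pcm_preprocess` object from [preprocess_fit()].
#' @param x Numeric matrix over the original (unfiltered) columns.
#' @return The filtered, centered and scaled matrix.
#' @export
preprocess_apply <- function(prep, x) {
  if (ncol(x) != length(prep$kept)) {
    abort("column count does not match the fitted preprocessing state")
  }
  xr <- x[, prep$kept, drop = FALSE]
  sweep(sweep(xr, 2, prep$center), 2, prep$scale, "/")
}

#' Assemble the proteochemometric design matrix
#'
#' One design row per bioactivity entry: the horizontal concatenation of the
#' compound descriptor row and the target descriptor row, with the pIC50 as
#' aligned response. Passing `NULL` for either block yields the family-QSAR
#' (compound block only) or family-QSAM (target block only) ablation.
#'
#' @param compound_block Numeric matrix with compound ids as row names, or
#'   `NULL`.
#' @param target_block Numeric matrix with target ids as row names, or
#'   `NULL`.
#' @param table A `bioactivity_table`.
#' @return A `pcm_design` list with `x` (raw design matrix), `y` (response),
#'   `meta` (tibble of `compound_id`, `target_id`), and the column name
#'   vectors `compound_cols`, `target_cols`.
#' @export
assemble_pcm_matrix <- function(compound_block, target_block, table) {
  if (nrow(table) == 0) abort("empty bioactivity table")
  if (is.null(compound_block) && is.null(target_block)) {
    abort("at least one descriptor block is required")
  }
  check_block <- function(block, ids, what) {
    missing <- setdiff(ids, rownames(block))
    if (length(missing) > 0) {
      abort(paste0("missing ", what, " descriptor row(s): ",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  parts <- list()
  if (!is.null(compound_block)) {
    check_block(compound_block, unique(table$compound_id), "compound")
    parts$compound <- compound_block[table$compound_id, , drop = FALSE]
    colnames(parts$compound) <- paste0("cmpd|", colnames(compound_block))
  }
  if (!is.null(target_block)) {
    check_block(target_block, unique(table$target_id), "target")
    parts$target <- target_block[table$target_id, , drop = FALSE]
    colnames(parts$target) <- paste0("tgt|", colnames(target_block))
  }
  x <- do.call(cbind, unname(parts))
  rownames(x) <- paste(table$compound_id, table$target_id, sep = "@")
  structure(
    list(
      x = x,
      y = table$pIC50,
      meta = tibble(compound_id = table$compound_id,
                    target_id = table$target_id),
      compound_cols = if (is.null(parts$compound)) character(0) else colnames(parts$compound),
      target_cols = if (is.null(parts$target)) character(0) else colnames(parts$target)
    ),
    class = "pcm_design"
  )
}
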