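#' Read a raw bioactivity export
#'
#' Parses a delimited text export of IC50 measurements (one row per assay
#' record) into a tibble of bioactivity records. The delimiter (comma or tab)
#' is auto-detected from the header line. Columns are located through
#' `column_map`, so exports with arbitrary headers can be ingested without
#' renaming files.
#'
#' Rows whose activity value does not parse as a number are dropped with a
#' warning rather than aborting the import; large public exports routinely
#' contain a few unusable rows.
#'
#' @param path Path to a delimited text file with a header line.
#' @param column_map Named character vector (or list) mapping the canonical
#'   field names `compound_id`, `smiles`, `target_id`, `value`,
#'   `relationship`, `unit`, `assay_confidence` to the column names used in
#'   the file. Defaults to the identity mapping.
#' @return A tibble with the seven canonical columns; `value` is numeric and
#'   `assay_confidence` integer.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "cid,smi,tid,val,rel,u,conf",
#'   "CHEMBL1,CCO,COX1,100,=,nM,9"
#' ), f)
#' parse_bioactivity_table(f, c(
#'   compound_id = "cid", smiles = "smi", target_id = "tid", value = "val",
#'   relationship = "rel", unit = "u", assay_confidence = "conf"
#' ))
parse_bioactivity_table <- function(path, column_map = NULL) {
  fields <- c("compound_id", "smiles", "target_id", "value",
              "relationship", "unit", "assay_confidence")
  column_map <- as.list(column_map %||% setNames(as.list(fields), fields))
  missing_map <- setdiff(fields, names(column_map))
  if (length(missing_map) > 0) {
    abort(paste0("column_map lacks entries for: ",
                 paste(missing_map, collapse = ", ")))
  }

  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_count(header, "\t") >
               stringr::str_count(header, ",")) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  absent <- setdiff(unlist(column_map[fields]), names(raw))
  if (length(absent) > 0) {
    abort(paste0("mapped column(s) not present in file: ",
                 paste(absent, collapse = ", ")))
  }

  out <- tibble(
    compound_id      = raw[[column_map$compound_id]],
    smiles           = raw[[column_map$smiles]],
    target_id        = raw[[column_map$target_id]],
    value            = suppressWarnings(as.numeric(raw[[column_map$value]])),
    relationship     = raw[[column_map$relationship]],
    unit             = raw[[column_map$unit]],
    assay_confidence = suppressWarnings(
      as.integer(raw[[column_map$assay_confidence]]))
  )

  bad <- !is.finite(out$value)
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) with unparseable activity value skipped"))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Quality-filter bioactivity records
#'
#' Keeps only records that can be pooled into a homogeneous pIC50 response:
#' exact-equality activity relationship, assay score confidence of at least
#' `min_confidence`, and activities reported in nanomolar. Relationship
#' symbols are compared after trimming whitespace; the unit match is
#' case-insensitive.
#'
#' @param records Tibble from [parse_bioactivity_table()].
#' @param min_confidence Minimum assay score confidence (default 8).
#' @return The filtered tibble, with an attribute `"rejections"` holding a
#'   tibble of per-rule rejection counts (a record failing several rules is
#'   counted under each).
#' @export
apply_quality_filters <- function(records, min_confidence = 8) {
  rel_ok  <- stringr::str_trim(records$relationship) == "="
  conf_ok <- !is.na(records$assay_confidence) &
    records$assay_confidence >= min_confidence
  unit_ok <- tolower(stringr::str_trim(records$unit)) == "nm"
  pos_ok  <- is.finite(records$value) & records$value > 0

  keep <- rel_ok & conf_ok & unit_ok & pos_ok
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- tibble(
    rule = c("relationship_not_equality", "confidence_below_threshold",
             "unit_not_nM", "value_not_positive"),
    n_rejected = c(sum(!rel_ok), sum(!conf_ok), sum(!unit_ok), sum(!pos_ok))
  )
  out
}

#' Convert IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in molar
#' units, so an input in nanomolar maps to `9 - log10(ic50_nM)`.
#'
#' @param ic50_nM Positive numeric vector of IC50 values in nM.
#' @return Numeric vector of pIC50 values.
#' @export
#' @examples
#' to_pic50(c(1, 50, 1000)) # 9, 7.30103, 6
to_pic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM)) abort("ic50_nM must be numeric")
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    abort("ic50_nM must be positive and finite")
  }
  9 - log10(ic50_nM)
}

#' Collapse replicate measurements into a bioactivity table
#'
#' Converts filtered records to pIC50 and averages replicates annotated on
#' the same (compound, target) combination, keeping the replicate count and
#' the replicate standard deviation for diagnostics. The arithmetic mean is
#' used rather than the median: replicate spreads in public IC50 data are
#' overwhelmingly small, so outlier resistance is not worth the efficiency
#' loss.
#'
#' @param records Filtered record tibble (see [apply_quality_filters()]).
#' @return A `bioactivity_table`: a tibble with columns `compound_id`,
#'   `target_id`, `pIC50`, `n_source_records`, `pIC50_sd` (NA for single
#'   records) and, when the input carried SMILES, a representative `smiles`
#'   per compound. Attributes `compounds` and `targets` hold the ordered id
#'   lists (first-appearance order).
#' @export
deduplicate <- function(records) {
  has_smiles <- "smiles" %in% names(records)
  recs <- mutate(records, .pic50 = to_pic50(.data$value))
  out <- recs |>
    group_by(.data$compound_id, .data$target_id) |>
    summarise(
      pIC50 = mean(.data$.pic50),
      n_source_records = dplyr::n(),
      pIC50_sd = if (dplyr::n() > 1) sd(.data$.pic50) else NA_real_,
      .groups = "drop"
    )
  if (has_smiles) {
    smi <- recs |>
      group_by(.data$compound_id) |>
      summarise(smiles = .data$smiles[1], .groups = "drop")
    out <- left_join(out, smi, by = "compound_id")
  }
  new_bioactivity_table(out,
                        compounds = unique(records$compound_id),
                        targets = unique(records$target_id))
}

new_bioactivity_table <- function(entries, compounds, targets) {
  stopifnot(!anyDuplicated(paste(entries$compound_id, entries$target_id)))
  structure(
    as_tibble(entries),
    compounds = compounds,
    targets = targets,
    class = c("bioactivity_table", class(as_tibble(entries)))
  )
}

#' Build a bioactivity table directly from (compound, target, pIC50) triples
#'
#' Convenience constructor used by the synthetic-data generator and by tests;
#' entries must already be unique per (compound, target) pair.
#'
#' @param entries Tibble with columns `compound_id`, `target_id`, `pIC50`
#'   and optionally `n_source_records` and `smiles`.
#' @param compounds,targets Ordered id vectors; default to first-appearance
#'   order in `entries`.
#' @return A `bioactivity_table`.
#' @export
bioactivity_table <- function(entries,
                              compounds = unique(entries$compound_id),
                              targets = unique(entries$target_id)) {
  if (!"n_source_records" %in% names(entries)) {
    entries$n_source_records <- 1L
  }
  new_bioactivity_table(entries, compounds, targets)
}

#' Summary counts for a bioactivity table
#'
#' @param table A `bioactivity_table`.
#' @return A list with `n_compounds`, `n_targets`, `n_datapoints`,
#'   `completeness_pct` (= 100 * datapoints / (compounds x targets)) and
#'   `per_target`, a tibble with per-target datapoint counts and the
#'   percentage of all distinct compounds annotated on each target.
#' @export
summarize_bioactivity <- function(table) {
  if (nrow(table) == 0) abort("empty bioactivity table")
  compounds <- attr(table, "compounds") %||% unique(table$compound_id)
  targets <- attr(table, "targets") %||% unique(table$target_id)
  n_c <- length(compounds)
  n_t <- length(targets)
  per_target <- table |>
    group_by(.data$target_id) |>
    summarise(
      n_datapoints = dplyr::n(),
      n_compounds = dplyr::n_distinct(.data$compound_id),
      .groups = "drop"
    ) |>
    mutate(pct_compounds_annotated = 100 * .data$n_compounds / n_c)
  list(
    n_compounds = n_c,
    n_targets = n_t,
    n_datapoints = nrow(table),
    completeness_pct = 100 * nrow(table) / (n_c * n_t),
    per_target = per_target
  )
}

#' Compare bioactivity profiles between two targets
#'
#' For compounds annotated on both targets, treats the pIC50 on `target_y`
#' as "observed" and on `target_x` as "predicted" and reports RMSE and the
#' through-origin determination coefficient. Uncorrelated selectivity
#' profiles yield large RMSE and low (possibly negative) R2_0.
#'
#' @param table A `bioactivity_table`.
#' @param target_x,target_y Target ids to compare.
#' @return A list with `n_shared`, `rmse`, `r2_zero`, `slope` and the paired
#'   tibble in `pairs`.
#' @export
selectivity_comparison <- function(table, target_x, target_y) {
  known <- unique(table$target_id)
  for (tg in c(target_x, target_y)) {
    if (!tg %in% known) abort(paste0("unknown target: ", tg))
  }
  a <- filter(table, .data$target_id == target_x)
  b <- filter(table, .data$target_id == target_y)
  pairs <- dplyr::inner_join(
    select(a, "compound_id", x = "pIC50"),
    select(b, "compound_id", y = "pIC50"),
    by = "compound_id"
  )
  if (nrow(pairs) < 2) abort("fewer than 2 dual-annotated compounds")
  r0 <- r2_zero(pairs$y, pairs$x)
  list(
    n_shared = nrow(pairs),
    rmse = rmse(pairs$y, pairs$x),
    r2_zero = r0$r2_zero,
    slope = r0$slope,
    pairs = pairs
  )
}

#' @export
print.bioactivity_table <- function(x, ...) {
  s <- summarize_bioactivity(x)
  cat(sprintf(
    "<bioactivity_table> %d datapoints, %d compounds x %d targets (%.1f%% complete)\n",
    s$n_datapoints, s$n_compounds, s$n_targets, s$completeness_pct))
  NextMethod()
}
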