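#' Read a sample-by-feature dosage table
#'
#' Reads a delimited text file with a header into a validated cohort tibble.
#' The `schema` maps the fixed roles (`sample_id`, `label`, `aao`, `pc1`,
#' `pc2`) to column names in the file; all remaining numeric columns are
#' taken to be allele-dosage features in \[0,2\]. Row order is preserved.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param schema Named character vector mapping roles to file column names.
#'   Defaults assume the columns are already named by role.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @return A validated cohort tibble (roles first, then features).
#' @export
read_dosage_table <- function(path,
                              schema = c(sample_id = "sample_id", label = "label",
                                         aao = "aao", pc1 = "pc1", pc2 = "pc2"),
                              delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0)
    stopf("schema column(s) not in file: %s", paste(missing_cols, collapse = ", "))
  ren <- setNames(names(schema), unname(schema))
  names(raw)[match(names(ren), names(raw))] <- unname(ren)
  feats <- setdiff(names(raw), RESERVED_COLS)
  out <- dplyr::select(raw, dplyr::all_of(c(RESERVED_COLS, feats)))
  out$sample_id <- as.character(out$sample_id)
  validate_dosage_tbl(out)
}

#' Validate a cohort tibble
#'
#' Checks the invariants every pipeline stage relies on: unique sample ids
#' and feature names, no missing values, dosages within \[0,2\], binary
#' 0/1 labels.
#'
#' @param data A cohort tibble.
#' @return The input, invisibly unchanged, if valid; otherwise an error
#'   naming the offending cell or column.
#' @export
validate_dosage_tbl <- function(data) {
  miss <- setdiff(RESERVED_COLS, names(data))
  if (length(miss) > 0) stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  if (nrow(data) == 0) stopf("cohort table has no rows")
  if (anyDuplicated(data$sample_id)) {
    dup <- data$sample_id[duplicated(data$sample_id)][1]
    stopf("duplicated sample_id: '%s'", dup)
  }
  feats <- dosage_features(data)
  if (anyDuplicated(feats)) stopf("duplicated feature names")
  for (col in c(feats, "label", "aao", "pc1", "pc2")) {
    x <- data[[col]]
    if (!is.numeric(x)) stopf("column '%s' is not numeric", col)
    if (anyNA(x)) stopf("missing value in column '%s', row %d", col, which(is.na(x))[1])
  }
  for (f in feats) {
    bad <- which(data[[f]] < 0 | data[[f]] > 2)
    if (length(bad) > 0)
      stopf("dosage outside [0,2]: column '%s', row %d (value %g)",
            f, bad[1], data[[f]][bad[1]])
  }
  if (!all(data$label %in% c(0, 1))) {
    bad <- which(!data$label %in% c(0, 1))[1]
    stopf("non-binary label in row %d (value %g)", bad, data$label[bad])
  }
  if (any(data$aao < 0)) stopf("negative age at onset in row %d", which(data$aao < 0)[1])
  data$label <- as.integer(data$label)
  invisible(data)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_dosage_table()]: writes one row per sample with a header,
#' roles first then features, in a stable column order.
#'
#' @param data A cohort tibble.
#' @param path Output path; `.csv` extension selects comma delimiter,
#'   otherwise tab.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(data, path) {
  if (nrow(data) == 0) stopf("refusing to write an empty cohort table")
  out <- dplyr::select(data, dplyr::all_of(c(RESERVED_COLS, dosage_features(data))))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Write and read evaluation records
#'
#' Evaluation records (one row per model x criterion x n_features x phase x
#' metric) are written in long form with a stable column order so result
#' tables from identical runs are byte-identical.
#'
#' @param records A tibble of evaluation records with columns `model`,
#'   `criterion`, `n_features`, `phase`, `metric`, `value`.
#' @param path Output CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) stopf("no records to write")
  cols <- c("model", "criterion", "n_features", "phase", "metric", "value")
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  out <- dplyr::arrange(dplyr::select(records, dplyr::all_of(cols)),
                        .data$model, .data$criterion, .data$n_features,
                        .data$phase, .data$metric)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline: the binning scheme, bootstrap
#' count B, top-K per bootstrap, the feature-count grid, the criterion and
#' model lists, CV fold counts, hold-out fraction, the MIFS beta, and the
#' master seed from which all stage seeds are derived.
#'
#' @param scheme A [bin_scheme()].
#' @param b Number of bootstrap resamples (default 100).
#' @param k Features kept per bootstrap (default 10).
#' @param n_features_grid Feature-subset sizes evaluated by [run_grid()];
#'   default `c(1, 10, 20, 30, 40, 50, 60, 70)` capped at p downstream.
#' @param criteria Criterion names; default all seven.
#' @param models Model names; default all seven.
#' @param outer_folds,inner_folds Nested-CV folds (default 5 and 2).
#' @param holdout_frac Hold-out fraction (default 0.2).
#' @param mifs_beta Redundancy weight of the MIFS criterion (default 1).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scheme = bin_scheme(), b = 100L, k = 10L,
                       n_features_grid = c(1L, 10L, 20L, 30L, 40L, 50L, 60L, 70L),
                       criteria = fs_criteria(), models = model_names(),
                       outer_folds = 5L, inner_folds = 2L,
                       holdout_frac = 0.2, mifs_beta = 1, seed = 1L) {
  if (b < 1) stopf("b must be >= 1")
  if (k < 1) stopf("k must be >= 1")
  if (holdout_frac <= 0 || holdout_frac >= 1) stopf("holdout_frac must be in (0,1)")
  if (outer_folds < 2 || inner_folds < 2) stopf("folds must be >= 2")
  structure(list(scheme = scheme, b = as.integer(b), k = as.integer(k),
                 n_features_grid = as.integer(n_features_grid),
                 criteria = match.arg(criteria, fs_criteria(), several.ok = TRUE),
                 models = match.arg(models, model_names(), several.ok = TRUE),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 holdout_frac = holdout_frac, mifs_beta = mifs_beta,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments (`bin_scheme:` may hold `dosage_cut`, `pc_cut`, `aao_edges`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- if (!is.null(y$bin_scheme)) do.call(bin_scheme, y$bin_scheme) else bin_scheme()
  y$bin_scheme <- NULL
  do.call(run_config, c(list(scheme = scheme), y))
}
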