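#' Class-stratified hold-out split
#'
#' @param data A cohort tibble with both classes.
#' @param frac Hold-out fraction in (0,1) (default 0.2).
#' @param seed Seed for the shuffle.
#' @return A list with disjoint tibbles `train` and `holdout` whose union
#'   is the input; class ratios are preserved to within one sample.
#' @export
split_holdout <- function(data, frac = 0.2, seed = 1L) {
  if (frac <= 0 || frac >= 1) stopf("frac must be in (0,1)")
  withr::local_seed(seed)
  hold_idx <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
    n_h <- round(length(idx) * frac)
    idx[sample.int(length(idx), n_h)]
  }), use.names = FALSE)
  if (length(hold_idx) == 0 || length(hold_idx) == nrow(data))
    stopf("split leaves one side empty; adjust frac")
  train <- data[-sort(hold_idx), , drop = FALSE]
  holdout <- data[sort(hold_idx), , drop = FALSE]
  attr(train, "ground_truth") <- attr(data, "ground_truth")
  list(train = train, holdout = holdout)
}

# Stratified fold ids (1..k) for labels y under a seed.
make_folds <- function(y, k, seed) {
  withr::local_seed(seed)
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Classification metrics from scores
#'
#' AUC by the rank (Mann-Whitney) statistic with midranks for ties;
#' accuracy, precision (PPV), recall (sensitivity) and F1 at classification
#' threshold 0.5, with the 0-convention when a denominator vanishes.
#'
#' @param scores Predicted probabilities of class 1.
#' @param labels 0/1 labels with both classes present.
#' @param threshold Classification threshold (default 0.5).
#' @return A one-row tibble with columns `auc`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stopf("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("labels contain a single class")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(auc = auc, accuracy = mean(pred == labels),
                 precision = precision, recall = recall, f1 = f1)
}

# Inner grid search: best hyperparameter row by mean inner-fold AUC.
grid_search <- function(x, y, model, grid, inner, seed) {
  if (nrow(grid) == 0) stopf("empty hyperparameter grid")
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  fold <- make_folds(y, inner, seed)
  mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(inner), function(f) {
      tr <- fold != f; te <- fold == f
      fit <- fit_classifier(model, grid[g, , drop = FALSE],
                            x[tr, , drop = FALSE], y[tr],
                            seed = derive_seed(seed, paste0("fit", g, f)))
      compute_metrics(predict_scores(fit, x[te, , drop = FALSE]), y[te])$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  grid[which.max(mean_auc), , drop = FALSE]   # ties: first grid row
}

#' Nested cross-validation of one model on one feature subset
#'
#' Stratified outer folds estimate generalisation; within each outer
#' training set a stratified inner-fold grid search picks the
#' hyperparameters maximising mean inner AUC, the model is refitted on the
#' outer training set and scored on the outer test fold.
#'
#' @param data A cohort (training) tibble.
#' @param features Feature columns to use.
#' @param model One of [model_names()].
#' @param grid Hyperparameter grid; default [model_grid()].
#' @param outer,inner Fold counts (default 5 and 2).
#' @param seed Seed for fold assignment and fits.
#' @return A tibble with one row per outer fold (fold, chosen
#'   hyperparameters as a list column, auc, accuracy, precision, recall,
#'   f1); means over folds via [glance()][generics::glance].
#' @export
nested_cv <- function(data, features, model, grid = NULL,
                      outer = 5L, inner = 2L, seed = 1L) {
  model <- match.arg(model, model_names())
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) stopf("features not in data: %s", paste(miss, collapse = ", "))
  grid <- grid %||% model_grid(model, p = length(features))
  x <- as.matrix(data[, features, drop = FALSE])
  y <- data$label
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  fold <- make_folds(y, outer, derive_seed(seed, "outer"))
  rows <- purrr::map_dfr(seq_len(outer), function(f) {
    tr <- fold != f; te <- fold == f
    best <- grid_search(x[tr, , drop = FALSE], y[tr], model, grid, inner,
                        derive_seed(seed, paste0("inner", f)))
    fit <- fit_classifier(model, best, x[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, paste0("refit", f)))
    m <- compute_metrics(predict_scores(fit, x[te, , drop = FALSE]), y[te])
    dplyr::bind_cols(tibble::tibble(fold = f, params = list(best)), m)
  })
  structure(rows, class = c("stratifs_cv", class(rows)),
            model = model, features = features)
}

#' Tune on the full training set and refit
#'
#' Runs the inner-CV grid-search protocol on the entire training set and
#' returns the refitted model, ready to score hold-out or external data.
#'
#' @inheritParams nested_cv
#' @return A `stratifs_model` with elements `fit`, `model`, `params`,
#'   `features`; supports [predict()], [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
tune_final <- function(data, features, model, grid = NULL, inner = 2L, seed = 1L) {
  model <- match.arg(model, model_names())
  grid <- grid %||% model_grid(model, p = length(features))
  x <- as.matrix(data[, features, drop = FALSE])
  y <- data$label
  best <- grid_search(x, y, model, grid, inner, derive_seed(seed, "tune"))
  fit <- fit_classifier(model, best, x, y, seed = derive_seed(seed, "final"))
  structure(list(fit = fit, model = model, params = best, features = features),
            class = "stratifs_model")
}

#' @export
predict.stratifs_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0)
    stopf("features missing from data: %s", paste(miss, collapse = ", "))
  predict_scores(object$fit, as.matrix(newdata[, object$features, drop = FALSE]))
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit of acting on predictions at threshold probability p_t,
#' NB(p_t) = TP/N - (FP/N) p_t/(1 - p_t), classifying positive when
#' score >= p_t, together with the treat-all and treat-none references.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param thresholds Threshold grid in (0,1); default 0.25 to 0.75 by 0.05.
#' @param name Strategy label for the model curve.
#' @return A `decision_curve` tibble (`threshold`, `strategy`,
#'   `net_benefit`); see [autoplot.decision_curve()].
#' @export
net_benefit <- function(scores, labels, thresholds = seq(0.25, 0.75, by = 0.05),
                        name = "model") {
  if (any(thresholds <= 0 | thresholds >= 1)) stopf("thresholds must lie in (0,1)")
  n <- length(labels)
  prev <- mean(labels == 1)
  rows <- purrr::map_dfr(thresholds, function(pt) {
    pos <- scores >= pt
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    tibble::tibble(
      threshold = pt,
      strategy = c(name, "treat_all", "treat_none"),
      net_benefit = c(tp / n - (fp / n) * pt / (1 - pt),
                      prev - (1 - prev) * pt / (1 - pt),
                      0))
  })
  structure(rows, class = c("decision_curve", class(rows)))
}

#' Evaluate the full criterion x feature-count x model grid
#'
#' For every combination of selection criterion (via its feature ranking),
#' feature-subset size and model, runs nested CV on the training data; per
#' model type the best cell (maximal mean nested-CV AUC, ties broken by
#' fewer features then criterion name) is tuned on the full training set
#' and scored on the hold-out and, when given, external data.
#'
#' @param train Training cohort tibble (post-mitigation).
#' @param holdout Hold-out cohort tibble.
#' @param rankings Named list of ranking tibbles (one per criterion, e.g.
#'   from [bootstrap_votes()]); names are the criterion labels.
#' @param config A [run_config()].
#' @param external Optional external-validation cohort; must contain every
#'   ranked feature (an error lists any missing ones).
#' @param grids Optional named list overriding [model_grid()] per model.
#' @param include_all_features If `TRUE`, adds a no-selection arm ("none")
#'   evaluating all features.
#' @return A list: `records` (long tibble for [write_results()]), `cells`
#'   (one row per grid cell with mean CV metrics), `best` (per-model best
#'   cell with hold-out/external metrics), `overall_best` (model name),
#'   `fits` (per-model `stratifs_model`), `dca` (hold-out decision curves
#'   of the best models).
#' @export
run_grid <- function(train, holdout, rankings, config = run_config(),
                     external = NULL, grids = NULL,
                     include_all_features = FALSE) {
  p <- length(dosage_features(train))
  nf_grid <- sort(unique(pmin(config$n_features_grid, p)))
  if (include_all_features)
    rankings <- c(rankings, list(none = tibble::tibble(feature = dosage_features(train))))
  if (!is.null(external)) {
    ranked <- unique(unlist(lapply(rankings, function(r) r$feature)))
    miss <- setdiff(ranked, names(external))
    if (length(miss) > 0)
      stopf("external data lacks feature(s): %s", paste(miss, collapse = ", "))
  }
  cells <- tidyr::expand_grid(criterion = names(rankings), n_features = nf_grid,
                              model = config$models)
  cell_rows <- purrr::pmap_dfr(cells, function(criterion, n_features, model) {
    feats <- top_subset(rankings[[criterion]], n_features)
    grid <- (grids %||% list())[[model]] %||% model_grid(model, p = n_features)
    cv <- nested_cv(train, feats, model, grid = grid,
                    outer = config$outer_folds, inner = config$inner_folds,
                    seed = derive_seed(config$seed,
                                       paste("cv", criterion, n_features, model)))
    mm <- dplyr::summarise(cv, dplyr::across(c("auc", "accuracy", "precision",
                                               "recall", "f1"), mean))
    dplyr::bind_cols(tibble::tibble(model = model, criterion = criterion,
                                    n_features = n_features), mm)
  })
  best <- dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(cell_rows, .data$model),
                   dplyr::desc(.data$auc), .data$n_features, .data$criterion),
    n = 1)
  best <- dplyr::ungroup(best)
  best$holdout_auc <- NA_real_
  if (!is.null(external)) best$external_auc <- NA_real_
  fits <- list(); dca <- list(); recs <- list()
  for (i in seq_len(nrow(best))) {
    b <- best[i, ]
    feats <- top_subset(rankings[[b$criterion]], b$n_features)
    grid <- (grids %||% list())[[b$model]] %||% model_grid(b$model, p = b$n_features)
    fit <- tune_final(train, feats, b$model, grid = grid,
                      inner = config$inner_folds,
                      seed = derive_seed(config$seed, paste("final", b$model)))
    fits[[b$model]] <- fit
    phase_metrics <- list(cv = b[, c("auc", "accuracy", "precision", "recall", "f1")])
    sc_h <- predict(fit, holdout)
    phase_metrics$holdout <- compute_metrics(sc_h, holdout$label)
    dca[[b$model]] <- dplyr::mutate(
      net_benefit(sc_h, holdout$label, name = b$model), phase = "holdout")
    if (!is.null(external)) {
      sc_e <- predict(fit, external)
      phase_metrics$external <- compute_metrics(sc_e, external$label)
      dca[[paste0(b$model, ".ext")]] <- dplyr::mutate(
        net_benefit(sc_e, external$label, name = b$model), phase = "external")
    }
    recs[[i]] <- purrr::imap_dfr(phase_metrics, function(m, phase) {
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble::tibble(model = b$model, criterion = b$criterion,
                                        n_features = b$n_features, phase = phase), m),
        c("auc", "accuracy", "precision", "recall", "f1"),
        names_to = "metric", values_to = "value")
    })
    best$holdout_auc[i] <- phase_metrics$holdout$auc
    if (!is.null(external)) best$external_auc[i] <- phase_metrics$external$auc
  }
  overall <- best[order(-best$auc, best$n_features, best$criterion), ]$model[1]
  list(records = dplyr::bind_rows(recs), cells = cell_rows, best = best,
       overall_best = overall, fits = fits, dca = dplyr::bind_rows(dca))
}
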