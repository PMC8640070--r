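# Small shared fixtures: a separable cohort and tiny hyperparameter grids
# so nested CV stays fast.
tiny_grids <- list(
  LR = data.frame(C = 1),
  AdaBoost = data.frame(n_estimators = 20, learning_rate = 0.5),
  XGBoost = data.frame(n_estimators = 20, learning_rate = 0.3,
                       max_depth = 2, min_child_weight = 1),
  RF = data.frame(n_estimators = 50, max_depth = 2, max_features = 2,
                  min_samples_leaf = 2, min_samples_split = 2),
  KNNC = data.frame(k = 3),
  DT = data.frame(max_depth = 2, min_samples_split = 2, min_samples_leaf = 2),
  NB = data.frame(.none = 1)[, 0, drop = FALSE])

separable_cohort <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    tibble::tibble(
      sample_id = sprintf("s%03d", 1:n), label = y,
      aao = runif(n, 20, 60), pc1 = rnorm(n), pc2 = rnorm(n),
      SIG = y * 2,                       # perfectly separating dosage
      N1 = runif(n, 0, 2), N2 = runif(n, 0, 2))
  })
}

test_that("hold-out split is stratified, disjoint and deterministic", {
  co <- toy_cohort(n = 100, p = 4, seed = 3)
  sp <- split_holdout(co, frac = 0.2, seed = 5)
  expect_identical(nrow(sp$train) + nrow(sp$holdout), nrow(co))
  expect_length(intersect(sp$train$sample_id, sp$holdout$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$holdout$sample_id), co$sample_id)
  # class ratio preserved to within one sample
  for (cls in 0:1) {
    expect_lte(abs(sum(sp$holdout$label == cls) - 0.2 * sum(co$label == cls)), 1)
  }
  sp2 <- split_holdout(co, frac = 0.2, seed = 5)
  expect_identical(sp$holdout$sample_id, sp2$holdout$sample_id)
  expect_error(split_holdout(co, frac = 0), "frac")
})

test_that("metrics match a longhand confusion-matrix computation", {
  # perfect scores
  m <- compute_metrics(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_equal(unlist(m), c(auc = 1, accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all-negative predictions: precision and recall 0 by convention
  m <- compute_metrics(rep(0.1, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(m$precision, 0); expect_equal(m$recall, 0); expect_equal(m$f1, 0)
  # 6-sample worked example: scores (.9,.8,.4,.7,.3,.2), labels (1,1,1,0,0,0)
  # ranks of positives 6,5,3 -> U = 14-6 = 8 of 9; threshold .5:
  # TP=2 FP=1 FN=1 TN=2 -> acc 4/6, prec 2/3, rec 2/3, f1 2/3
  m <- compute_metrics(c(.9, .8, .4, .7, .3, .2), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$auc, 8 / 9)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # midrank handling of ties: all scores equal -> AUC .5
  expect_equal(compute_metrics(rep(0.7, 8), rep(0:1, 4))$auc, 0.5)
  expect_error(compute_metrics(1:4 / 4, rep(1, 4)), "single class")
})

test_that("nested CV is near-perfect on separable data and deterministic", {
  co <- separable_cohort()
  for (model in c("LR", "DT", "NB")) {
    cv <- nested_cv(co, c("SIG", "N1"), model, grid = tiny_grids[[model]],
                    outer = 5, inner = 2, seed = 9)
    expect_gte(mean(cv$auc), 0.99)
  }
  cv1 <- nested_cv(co, c("SIG", "N1"), "RF", grid = tiny_grids$RF, seed = 4)
  cv2 <- nested_cv(co, c("SIG", "N1"), "RF", grid = tiny_grids$RF, seed = 4)
  expect_identical(cv1$auc, cv2$auc)
  g <- glance(cv1)
  expect_identical(g$n_features, 2L)
  expect_true(all(unlist(g[, c("auc", "accuracy", "precision", "recall", "f1")]) >= 0))
})

test_that("every model type trains, predicts in [0,1], and beats chance on signal", {
  co <- separable_cohort(n = 160, seed = 2)
  sp <- split_holdout(co, 0.25, seed = 1)
  for (model in model_names()) {
    fit <- tune_final(sp$train, c("SIG", "N1", "N2"), model,
                      grid = tiny_grids[[model]], seed = 3)
    sc <- predict(fit, sp$holdout)
    expect_true(all(sc >= 0 & sc <= 1), label = model)
    expect_gte(compute_metrics(sc, sp$holdout$label)$auc, 0.9)
    expect_s3_class(tidy(fit), "tbl_df")
    expect_identical(glance(fit)$model, model)
  }
})

test_that("grid search picks the single point of a one-point grid", {
  co <- separable_cohort()
  fit <- tune_final(co, c("SIG", "N1"), "KNNC", grid = data.frame(k = 5), seed = 2)
  expect_identical(fit$params$k, 5)
  expect_error(tune_final(co, "SIG", "LR", grid = data.frame()[0, 0], seed = 1),
               "empty")
})

test_that("label permutation drives the pipeline AUC to chance", {
  aucs <- vapply(1:6, function(s) {
    co <- simulate_cohort(synthetic_config(n_case = 150, n_control = 150,
                                           p = 10, seed = 600 + s))
    co$label <- withr::with_seed(s, sample(co$label))
    sel <- select_features(co, "MIM", k = 3)
    mean(nested_cv(co, sel$feature, "LR", grid = tiny_grids$LR,
                   seed = s)$auc)
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("net benefit reproduces its closed forms", {
  withr::with_seed(5, {
    labels <- rep(c(1, 0), c(30, 70))
    scores <- runif(100)
    dc <- net_benefit(scores, labels, thresholds = c(0.25, 0.5, 0.75))
    tn <- dc[dc$strategy == "treat_none", ]
    expect_true(all(tn$net_benefit == 0))
    ta <- dc[dc$strategy == "treat_all", ]
    expect_equal(ta$net_benefit, 0.3 - 0.7 * ta$threshold / (1 - ta$threshold))
    # TP=30, FP=20, N=100 at p_t = 0.25
    sc <- c(rep(0.9, 30), rep(0.9, 20), rep(0.1, 50))
    dc2 <- net_benefit(sc, labels, thresholds = 0.25)
    expect_equal(dc2$net_benefit[dc2$strategy == "model"], 0.30 - 0.20 * (1 / 3))
    expect_error(net_benefit(scores, labels, thresholds = c(0, 0.5)), "thresholds")
    expect_s3_class(ggplot2::autoplot(dc), "ggplot")
  })
})

test_that("run_grid evaluates the grid, picks the best cell, and validates externally", {
  co <- separable_cohort(n = 140, seed = 8)
  sp <- split_holdout(co, 0.2, seed = 2)
  ext <- separable_cohort(n = 60, seed = 9)
  cfg <- run_config(b = 2, k = 2, n_features_grid = c(1L, 3L),
                    models = c("LR", "NB"), criteria = c("MIM", "mRMR"), seed = 7)
  rankings <- list(MIM = bootstrap_votes(sp$train, "MIM", k = 2, b = 2, seed = 1),
                   mRMR = bootstrap_votes(sp$train, "mRMR", k = 2, b = 2, seed = 1))
  res <- run_grid(sp$train, sp$holdout, rankings, cfg, external = ext,
                  grids = tiny_grids)
  expect_identical(nrow(res$cells), 2L * 2L * 2L)
  expect_identical(nrow(res$best), 2L)
  expect_true(all(res$best$auc >= 0.99))         # SIG is rank 1 everywhere
  expect_true(all(c("cv", "holdout", "external") %in% res$records$phase))
  expect_identical(nrow(res$records), 2L * 3L * 5L)
  expect_true(res$overall_best %in% c("LR", "NB"))
  expect_s3_class(res$dca, "decision_curve")
  # external data missing a ranked feature errors with its name
  expect_error(run_grid(sp$train, sp$holdout, rankings, cfg,
                        external = dplyr::select(ext, -"SIG"), grids = tiny_grids),
               "SIG")
})

test_that("single-cell grid is trivially best; record counts multiply out", {
  co <- separable_cohort(n = 100, seed = 3)
  sp <- split_holdout(co, 0.2, seed = 1)
  cfg <- run_config(b = 1, k = 1, n_features_grid = 2L, models = "DT",
                    criteria = "MIM", seed = 5)
  rk <- list(MIM = bootstrap_votes(sp$train, "MIM", k = 1, b = 1, seed = 2))
  res <- run_grid(sp$train, sp$holdout, rk, cfg, grids = tiny_grids)
  expect_identical(nrow(res$cells), 1L)
  expect_identical(res$best$model, "DT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res$records, path)
  expect_identical(nrow(read_results(path)), nrow(res$records))
})

test_that("using all features never loses much AUC relative to the top-1 subset", {
  withr::with_seed(17, {
    n <- 300
    y <- rep(0:1, each = n / 2)
    co <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:n), label = y,
      aao = runif(n, 20, 60), pc1 = rnorm(n), pc2 = rnorm(n),
      S1 = pmin(pmax(y + rnorm(n, sd = 0.8), 0), 2),
      S2 = pmin(pmax(y + rnorm(n, sd = 0.8), 0), 2),
      N1 = runif(n, 0, 2), N2 = runif(n, 0, 2), N3 = runif(n, 0, 2))
    rk <- select_features(co, "MIM", k = 5)
    auc1 <- mean(nested_cv(co, rk$feature[1], "LR", grid = data.frame(C = 1),
                           seed = 4)$auc)
    auc_all <- mean(nested_cv(co, dosage_features(co), "LR",
                              grid = data.frame(C = 1), seed = 4)$auc)
    expect_gte(auc_all, auc1 - 0.02)
  })
})
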