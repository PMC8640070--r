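#' Supported risk-prediction models
#'
#' Seven supervised classifiers benchmarked by the pipeline: penalised
#' logistic regression (LR), AdaBoost, gradient-boosted trees (XGBoost),
#' random forest (RF), k-nearest neighbours (KNNC), a single decision tree
#' (DT) and Gaussian naive Bayes (NB).
#'
#' @return Character vector of model names.
#' @export
model_names <- function() c("LR", "AdaBoost", "XGBoost", "RF", "KNNC", "DT", "NB")

#' Default hyperparameter grid for a model
#'
#' Grids follow the benchmarking defaults: LR over the inverse
#' regularisation C; AdaBoost over rounds and learning rate; XGBoost over
#' rounds, learning rate, depth and min child weight (with gamma 2,
#' lambda 0.5, alpha 0.5 fixed); RF over trees, depth, mtry and leaf size;
#' KNNC over k; DT over depth, min split and min leaf; NB has no tunable
#' (the grid is a single empty point). Every grid can be overridden via
#' the `grids` argument of [nested_cv()] / [run_grid()].
#'
#' @param model One of [model_names()].
#' @param p Number of features available (caps `max_features`/`mtry`).
#' @return A data frame with one row per hyperparameter combination.
#' @export
model_grid <- function(model, p = 70L) {
  model <- match.arg(model, model_names())
  cap <- function(v) unique(pmin(v, p))
  switch(model,
    LR = expand.grid(C = c(0.01, 0.1, 1, 10)),
    AdaBoost = expand.grid(n_estimators = c(100, 200, 300, 400),
                           learning_rate = c(0.1, 0.5, 1.0)),
    XGBoost = expand.grid(n_estimators = c(100, 200, 300, 400),
                          learning_rate = c(0.1, 0.5, 1.0),
                          max_depth = c(1, 2), min_child_weight = c(1, 3)),
    RF = expand.grid(n_estimators = c(100, 200, 300, 400), max_depth = c(1, 2),
                     max_features = cap(c(1, 10, 20, 30, 40, 50, 60, 70)),
                     min_samples_leaf = c(2, 3, 4, 5),
                     min_samples_split = c(2, 5, 10)),
    KNNC = expand.grid(k = c(1, 3, 5)),
    DT = expand.grid(max_depth = c(1, 2), min_samples_split = c(2, 5, 10),
                     min_samples_leaf = c(2, 3, 4, 5)),
    NB = data.frame(.none = 1)[, 0, drop = FALSE])
}

# Fit one classifier on a numeric feature matrix and 0/1 labels.
# Returns an object predict_scores() can turn into P(label = 1).
fit_classifier <- function(model, params, x, y, seed = 1L) {
  model <- match.arg(model, model_names())
  x <- as.matrix(x)
  fit <- switch(model,
    LR = {
      xx <- if (ncol(x) < 2) cbind(x, `.pad` = 0) else x
      glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                     lambda = 1 / (nrow(xx) * params$C), standardize = TRUE)
    },
    AdaBoost = fit_adaboost(x, y, n_estimators = params$n_estimators,
                            learning_rate = params$learning_rate, seed = seed),
    XGBoost = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$learning_rate, max_depth = params$max_depth,
                      min_child_weight = params$min_child_weight,
                      gamma = 2, lambda = 0.5, alpha = 0.5,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = params$n_estimators,
        verbose = 0)
    },
    RF = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = params$n_estimators, max.depth = params$max_depth,
      mtry = min(params$max_features, ncol(x)),
      min.node.size = params$min_samples_leaf,
      probability = TRUE, seed = seed, num.threads = 1),
    KNNC = list(x = x, y = y, k = params$k),
    DT = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$max_depth, minsplit = params$min_samples_split,
                     minbucket = params$min_samples_leaf, cp = 0, xval = 0))
    },
    NB = {
      keep <- apply(x, 2, function(col) stats::sd(col) > 0)
      if (!any(keep)) list(prior = mean(y))
      else list(nb = e1071::naiveBayes(x[, keep, drop = FALSE],
                                       factor(y, levels = c(0, 1))),
                keep = which(keep))
    })
  structure(list(model = model, params = params, fit = fit,
                 features = colnames(x)), class = "stratifs_fit")
}

# Discrete AdaBoost (SAMME with two classes) over depth-1 CART stumps.
fit_adaboost <- function(x, y, n_estimators, learning_rate, seed = 1L) {
  withr::local_seed(seed)
  n <- length(y)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2, xval = 0))
    pred <- ifelse(predict(st, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err <= 1e-10) { used <- used + 1L; stumps[[used]] <- st
                        alphas[used] <- learning_rate * 10; break }
    if (err >= 0.5) break
    a <- learning_rate * 0.5 * log((1 - err) / err)
    used <- used + 1L; stumps[[used]] <- st; alphas[used] <- a
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (used == 0L) {
    # no stump beats chance: fall back to the empirical prevalence
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

# Predicted probability of class 1 for each row of x.
predict_scores <- function(object, x) {
  x <- as.matrix(x)
  f <- object$fit
  switch(object$model,
    LR = {
      xx <- if (ncol(x) < 2) cbind(x, `.pad` = 0) else x
      as.numeric(predict(f, xx, type = "response"))
    },
    AdaBoost = {
      if (length(f$stumps) == 0) return(rep(f$prior, nrow(x)))
      df <- as.data.frame(x)
      s <- rowSums(vapply(seq_along(f$stumps), function(i) {
        f$alphas[i] * ifelse(predict(f$stumps[[i]], df, type = "class") == "1", 1, -1)
      }, numeric(nrow(x))))
      plogis(2 * s)
    },
    XGBoost = as.numeric(predict(f, xgboost::xgb.DMatrix(x))),
    RF = predict(f, as.data.frame(x), num.threads = 1)$predictions[, "1"],
    KNNC = {
      pr <- class::knn(f$x, x, factor(f$y, levels = c(0, 1)), k = f$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    DT = predict(f, as.data.frame(x), type = "prob")[, "1"],
    NB = {
      if (!is.null(f$prior)) rep(f$prior, nrow(x))
      else as.numeric(predict(f$nb, x[, f$keep, drop = FALSE], type = "raw")[, "1"])
    })
}
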