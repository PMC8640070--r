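test_that("empty-set conventions reduce every criterion to univariate relevance", {
  tb <- fixture_table()
  none <- data.frame()[seq_along(tb$y), , drop = FALSE]
  for (cr in setdiff(fs_criteria(), "DISR")) {
    expect_equal(score_candidate(tb$x[, "F1"], tb$y, none, cr),
                 mutual_info(tb$x[, "F1"], tb$y), tolerance = 1e-12,
                 label = cr)
  }
  expect_equal(score_candidate(tb$x[, "F1"], tb$y, none, "DISR"),
               mutual_info(tb$x[, "F1"], tb$y) /
                 shannon_entropy(tb$x[, "F1"], tb$y), tolerance = 1e-12)
})

test_that("mRMR with a selected exact copy scores I(X;Y) - H(X)", {
  tb <- fixture_table()
  xk <- tb$x[, "F1"]
  expect_equal(score_candidate(xk, tb$y, data.frame(F1b = xk), "mRMR"),
               mutual_info(xk, tb$y) - shannon_entropy(xk), tolerance = 1e-12)
})

test_that("all seven criteria match the term-by-term longhand oracle", {
  tb <- fixture_table()
  for (s_size in 0:2) {
    sel_names <- head(c("F2", "F6"), s_size)
    sel_cols <- lapply(sel_names, function(f) tb$x[, f])
    sel_df <- as.data.frame(setNames(sel_cols, sel_names))
    if (s_size == 0) sel_df <- data.frame()[seq_along(tb$y), , drop = FALSE]
    for (cr in fs_criteria()) {
      for (cand in c("F1", "F4", "F5")) {
        expect_equal(
          score_candidate(tb$x[, cand], tb$y, sel_df, cr, beta = 1),
          oracle_score(cr, tb$x[, cand], tb$y, sel_cols, beta = 1),
          tolerance = 1e-12, label = sprintf("%s |S|=%d cand=%s", cr, s_size, cand))
      }
    }
  }
})

test_that("cached greedy scoring agrees with the direct estimator path", {
  tb <- fixture_table()
  cache <- build_info_cache(tb$x, tb$y)
  sel <- c("F2", "F6")
  sel_df <- as.data.frame(tb$x[, sel])
  for (cr in fs_criteria()) {
    for (cand in c("F1", "F4", "F5")) {
      expect_equal(score_from_cache(cache, cr, cand, sel),
                   score_candidate(tb$x[, cand], tb$y, sel_df, cr),
                   tolerance = 1e-10, label = paste(cr, cand))
    }
  }
})

test_that("greedy selection matches a brute-force from-scratch re-scorer", {
  tb <- fixture_table()
  disc <- tibble::as_tibble(as.data.frame(tb$x))
  disc$label <- tb$y
  for (cr in c("CMIM", "JMI", "mRMR")) {
    got <- select_features(disc, cr, k = 3, features = colnames(tb$x),
                           discretized = TRUE)
    expect_identical(got$feature, head(oracle_greedy(cr, tb$x, tb$y, 3), 3),
                     label = cr)
  }
})

test_that("MIM ranks features by descending univariate MI with name tie-break", {
  tb <- fixture_table()
  disc <- tibble::as_tibble(as.data.frame(tb$x))
  disc$label <- tb$y
  got <- select_features(disc, "MIM", k = 6, features = colnames(tb$x),
                         discretized = TRUE)
  mis <- vapply(colnames(tb$x), function(f) mutual_info(tb$x[, f], tb$y), numeric(1))
  expect_identical(got$feature, colnames(tb$x)[order(-mis, colnames(tb$x))])
  # K = p is a permutation
  expect_setequal(got$feature, colnames(tb$x))
})

test_that("k out of range is rejected", {
  tb <- fixture_table()
  disc <- tibble::as_tibble(as.data.frame(tb$x)); disc$label <- tb$y
  expect_error(select_features(disc, "MIM", k = 7, features = colnames(tb$x),
                               discretized = TRUE), "exceeds")
  expect_error(select_features(disc, "MIM", k = 0, features = colnames(tb$x),
                               discretized = TRUE), ">= 1")
})

test_that("redundancy-penalising criteria never pick a duplicate of a selected feature early", {
  withr::with_seed(314, {
    for (rep in 1:10) {
      n <- 80
      y <- sample(0:1, n, replace = TRUE)
      x1 <- ifelse(runif(n) < 0.85, y, 1L - y)
      x2 <- ifelse(runif(n) < 0.7, y, 1L - y)   # weaker but non-redundant
      disc <- tibble::tibble(A_strong = x1, B_weak = x2, C_copy = x1, label = y)
      for (cr in c("mRMR", "MIFS", "CMIM", "ICAP")) {
        got <- select_features(disc, cr, k = 2,
                               features = c("A_strong", "B_weak", "C_copy"),
                               discretized = TRUE)
        expect_identical(sort(got$feature), c("A_strong", "B_weak"), label = cr)
      }
    }
  })
})

test_that("score_candidate is pure", {
  tb <- fixture_table()
  sel <- as.data.frame(tb$x[, c("F2", "F6")])
  a <- score_candidate(tb$x[, "F1"], tb$y, sel, "CMIM")
  b <- score_candidate(tb$x[, "F1"], tb$y, sel, "CMIM")
  expect_identical(a, b)
})
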