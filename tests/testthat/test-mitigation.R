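test_that("stratum assignment follows the confounder bins", {
  co <- toy_cohort(p = 2)
  co$aao[1] <- 35; co$pc1[1] <- -0.2; co$pc2[1] <- 0.4
  st <- assign_strata(co)
  expect_identical(st$aao_bin[1], 1L)
  expect_identical(st$pc1_bin[1], 0L)
  expect_identical(st$pc2_bin[1], 1L)
  expect_match(st$stratum[1], "aao21-40\\|pc1:0\\|pc2:1")
  # 20 vs 21 years fall in different bins
  co$aao[2] <- 20; co$aao[3] <- 21
  st <- assign_strata(co)
  expect_false(st$aao_bin[2] == st$aao_bin[3])
  # identical confounders collapse to one stratum
  co$aao <- 30; co$pc1 <- 0.5; co$pc2 <- -0.5
  expect_identical(length(unique(assign_strata(co)$stratum)), 1L)
  co$pc1[4] <- Inf
  expect_error(assign_strata(co), "non-finite")
})

test_that("balancing equalises class counts exactly and keeps originals", {
  co <- toy_cohort(n = 200, p = 3, seed = 17)
  mit <- suppressWarnings(mitigate_cohort(co, seed = 5))
  audit <- mitigation_audit(mit)
  kept <- audit[audit$retained, ]
  expect_true(all(kept$post_n0 == kept$post_n1))
  # all original rows of retained strata preserved, duplicates map to sources
  st <- assign_strata(co)
  orig_kept <- co$sample_id[st$stratum %in% kept$stratum]
  expect_true(all(orig_kept %in% mit$sample_id))
  prov <- attr(mit, "provenance")
  if (nrow(prov) > 0) {
    src <- match(prov$source_id, co$sample_id)
    dup <- match(prov$duplicate_id, mit$sample_id)
    f <- dosage_features(co)[1]
    expect_equal(mit[[f]][dup], co[[f]][src], tolerance = 0)
  }
})

test_that("a stratum short by 10 in one class gains exactly 10 resampled rows", {
  # one stratum, 10 cases vs 0 extra needed, controls short by 10
  n1 <- 20; n0 <- 10
  co <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:(n1 + n0)),
    label = c(rep(1L, n1), rep(0L, n0)),
    aao = 70, pc1 = 0.5, pc2 = 0.5,
    F1 = runif(n1 + n0, 0, 2), F2 = runif(n1 + n0, 0, 2))
  mit <- mitigate_cohort(co, seed = 9)
  expect_identical(nrow(mit), 40L)
  expect_identical(sum(mit$label == 0), 20L)
  added <- attr(mit, "provenance")
  expect_identical(nrow(added), 10L)
  expect_true(all(added$source_id %in% co$sample_id[co$label == 0]))
})

test_that("already-balanced strata are a fixed point; degenerate inputs error", {
  co <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                       label = c(0L, 1L, 0L, 1L), aao = 30, pc1 = 1, pc2 = 1,
                       F1 = c(0, 1, 2, 1))
  mit <- mitigate_cohort(co, seed = 1)
  expect_identical(nrow(mit), 4L)
  expect_identical(nrow(attr(mit, "provenance")), 0L)
  one_class <- dplyr::mutate(co, label = 1L)
  expect_error(mitigate_cohort(one_class), "single class")
  # both classes exist globally but never share a stratum
  split_cls <- dplyr::mutate(co, aao = ifelse(label == 1, 10, 70))
  expect_error(suppressWarnings(mitigate_cohort(split_cls)), "single-class")
})

test_that("mitigation removes the binned-confounder association with the label", {
  mis <- vapply(1:10, function(s) {
    co <- simulate_cohort(synthetic_config(n_case = 400, n_control = 400,
                                           p = 10, seed = 300 + s))
    mit <- suppressWarnings(mitigate_cohort(co, seed = s))
    d <- discretize_dosage(mit)
    mutual_info(d$aao, d$label)
  }, numeric(1))
  expect_true(all(mis < 0.01))
})

test_that("mitigation suppresses the confounded allele but not the causal one", {
  res <- vapply(1:10, function(s) {
    co <- simulate_cohort(synthetic_config(seed = 400 + s))
    gt <- ground_truth(co)
    d <- discretize_dosage(co)
    mit <- suppressWarnings(mitigate_cohort(co, seed = s))
    dm <- discretize_dosage(mit)
    c(conf_pre = mutual_info(d[[gt$confounded_feature]], d$label),
      conf_post = mutual_info(dm[[gt$confounded_feature]], dm$label),
      causal_pre = mutual_info(d[[gt$causal_feature]], d$label),
      causal_post = mutual_info(dm[[gt$causal_feature]], dm$label))
  }, numeric(4))
  # medians over the 10 seeds: the confounded signal collapses by >= 50%,
  # the causal signal moves by < 20%
  expect_gte(1 - median(res["conf_post", ]) / median(res["conf_pre", ]), 0.5)
  expect_lt(abs(median(res["causal_post", ]) / median(res["causal_pre", ]) - 1), 0.2)
})

test_that("sequential mode balances each confounder in turn", {
  co <- toy_cohort(n = 200, p = 3, seed = 23)
  mit <- suppressWarnings(mitigate_cohort(co, seed = 2, sequential = TRUE))
  d <- discretize_dosage(mit)
  # the last-balanced confounder is exactly balanced within its bins
  tab <- table(d$pc2, d$label)
  expect_true(all(tab[, 1] == tab[, 2]))
  expect_silent(validate_dosage_tbl(mit))
})
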