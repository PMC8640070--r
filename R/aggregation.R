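#' Bootstrap stability votes for one selection criterion
#'
#' Repeats greedy selection on `b` class-stratified bootstrap resamples
#' (rows drawn with replacement within each class, preserving the class
#' counts) and accumulates, per feature, the vote V — the number of
#' bootstraps in which it entered the top-K — and the mean rank R over
#' exactly those bootstraps. Vote mass is conserved: the votes of all
#' features sum to B x K.
#'
#' @param data A cohort tibble.
#' @param criterion One of [fs_criteria()].
#' @param k Top-K per bootstrap (default 10).
#' @param b Bootstrap count (default 100).
#' @param seed Seed for the resampling.
#' @param scheme A [bin_scheme()].
#' @param beta MIFS redundancy weight.
#' @param include_confounders If `TRUE`, the binned confounders `aao`,
#'   `pc1`, `pc2` compete as candidate features (used for the
#'   pre-mitigation arm, where a confounder can out-vote every allele).
#' @return A tibble (`feature`, `vote`, `mean_rank`) sorted by vote
#'   descending, mean rank ascending, name ascending; features never
#'   selected have vote 0 and `NA` mean rank. Attributes: `criterion`,
#'   `b`, `k`.
#' @export
bootstrap_votes <- function(data, criterion, k = 10L, b = 100L, seed = 1L,
                            scheme = bin_scheme(), beta = 1,
                            include_confounders = FALSE) {
  criterion <- match.arg(criterion, fs_criteria())
  if (b < 1) stopf("b must be >= 1")
  feats <- dosage_features(data)
  if (include_confounders) feats <- c(feats, "aao", "pc1", "pc2")
  if (k > length(feats)) stopf("k exceeds the number of candidate features")
  disc <- discretize_dosage(data, scheme)
  m <- as.matrix(disc[, feats, drop = FALSE])
  y <- disc$label
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  votes <- setNames(integer(length(feats)), feats)
  rank_sum <- setNames(numeric(length(feats)), feats)
  withr::local_seed(seed)
  for (rep in seq_len(b)) {
    rows <- c(idx0[sample.int(length(idx0), length(idx0), replace = TRUE)],
              idx1[sample.int(length(idx1), length(idx1), replace = TRUE)])
    cache <- build_info_cache(m[rows, , drop = FALSE], y[rows])
    sel <- greedy_from_cache(cache, criterion, k, beta)
    votes[sel$feature] <- votes[sel$feature] + 1L
    rank_sum[sel$feature] <- rank_sum[sel$feature] + sel$rank
  }
  out <- tibble::tibble(feature = feats, vote = unname(votes),
                        mean_rank = unname(ifelse(votes > 0, rank_sum / votes, NA_real_)))
  out <- dplyr::arrange(out, dplyr::desc(.data$vote), .data$mean_rank, .data$feature)
  structure(out, criterion = criterion, b = as.integer(b), k = as.integer(k))
}

#' Bootstrap votes for several criteria on shared resamples
#'
#' Equivalent to calling [bootstrap_votes()] once per criterion with the
#' same seed — every criterion sees the identical resample sequence — but
#' the pairwise-information cache of each bootstrap is built once and
#' shared by all criteria, which is what makes the 7 x B sweep tractable.
#'
#' @inheritParams bootstrap_votes
#' @param criteria Criterion names (default all seven).
#' @return A named list of [bootstrap_votes()] tables, one per criterion.
#' @export
bootstrap_votes_all <- function(data, criteria = fs_criteria(), k = 10L,
                                b = 100L, seed = 1L, scheme = bin_scheme(),
                                beta = 1, include_confounders = FALSE) {
  criteria <- match.arg(criteria, fs_criteria(), several.ok = TRUE)
  if (b < 1) stopf("b must be >= 1")
  feats <- dosage_features(data)
  if (include_confounders) feats <- c(feats, "aao", "pc1", "pc2")
  if (k > length(feats)) stopf("k exceeds the number of candidate features")
  disc <- discretize_dosage(data, scheme)
  m <- as.matrix(disc[, feats, drop = FALSE])
  y <- disc$label
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  votes <- lapply(criteria, function(cr) setNames(integer(length(feats)), feats))
  rank_sum <- lapply(criteria, function(cr) setNames(numeric(length(feats)), feats))
  names(votes) <- names(rank_sum) <- criteria
  withr::local_seed(seed)
  for (rep in seq_len(b)) {
    rows <- c(idx0[sample.int(length(idx0), length(idx0), replace = TRUE)],
              idx1[sample.int(length(idx1), length(idx1), replace = TRUE)])
    cache <- build_info_cache(m[rows, , drop = FALSE], y[rows])
    for (cr in criteria) {
      sel <- greedy_from_cache(cache, cr, k, beta)
      votes[[cr]][sel$feature] <- votes[[cr]][sel$feature] + 1L
      rank_sum[[cr]][sel$feature] <- rank_sum[[cr]][sel$feature] + sel$rank
    }
  }
  lapply(setNames(criteria, criteria), function(cr) {
    v <- votes[[cr]]
    out <- tibble::tibble(feature = feats, vote = unname(v),
                          mean_rank = unname(ifelse(v > 0, rank_sum[[cr]] / v, NA_real_)))
    out <- dplyr::arrange(out, dplyr::desc(.data$vote), .data$mean_rank, .data$feature)
    structure(out, criterion = cr, b = as.integer(b), k = as.integer(k))
  })
}

#' Aggregate bootstrap votes across criteria
#'
#' Combines one [bootstrap_votes()] table per criterion into the overall
#' ranking: per feature, the Technique Vote (number of criteria whose
#' aggregate top-K contains it), the Average Bootstrap Vote
#' ABV = sum of votes across criteria / number of criteria, and the
#' Average Bootstrap Rank ABR = mean of the per-criterion mean ranks over
#' the criteria where the feature was ever selected. Sorted by Technique
#' Vote desc, ABV desc, ABR asc, name asc.
#'
#' @param aggregates A (possibly named) list of [bootstrap_votes()] tables,
#'   one per criterion, sharing `b`, `k` and the candidate feature set.
#' @return A tibble (`feature`, `technique_vote`, `abv`, `abr`) with
#'   attributes `b`, `k`, `criteria`.
#' @export
aggregate_techniques <- function(aggregates) {
  if (length(aggregates) == 0) stopf("no aggregates supplied")
  bs <- unique(vapply(aggregates, function(a) attr(a, "b"), integer(1)))
  ks <- unique(vapply(aggregates, function(a) attr(a, "k"), integer(1)))
  if (length(bs) != 1 || length(ks) != 1) stopf("aggregates disagree on B or K")
  universes <- lapply(aggregates, function(a) sort(a$feature))
  if (!all(vapply(universes, identical, logical(1), universes[[1]])))
    stopf("aggregates disagree on the feature universe")
  crits <- vapply(aggregates, function(a) attr(a, "criterion"), character(1))
  n_crit <- length(aggregates)
  k <- ks
  long <- purrr::map_dfr(aggregates, function(a) {
    topk <- head(a$feature, k)   # a is already sorted (V desc, R asc, name)
    dplyr::mutate(a, criterion = attr(a, "criterion"),
                  in_topk = .data$feature %in% topk)
  })
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$feature),
    technique_vote = sum(.data$in_topk),
    abv = sum(.data$vote) / n_crit,
    abr = ifelse(any(.data$vote > 0),
                 mean(.data$mean_rank[.data$vote > 0]), NA_real_),
    .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$technique_vote),
                        dplyr::desc(.data$abv), .data$abr, .data$feature)
  structure(out, b = bs, k = k, criteria = unname(crits))
}

#' Top-n prefix of a ranking
#'
#' Works on both a per-criterion [bootstrap_votes()] table and the overall
#' [aggregate_techniques()] ranking; `top_subset(n)` is always a prefix of
#' `top_subset(n')` for n < n'.
#'
#' @param ranking A sorted ranking tibble.
#' @param n Number of features.
#' @return Character vector of the first `n` features.
#' @export
top_subset <- function(ranking, n) {
  if (n > nrow(ranking)) stopf("n = %d exceeds the %d ranked features", n, nrow(ranking))
  head(ranking$feature, n)
}
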