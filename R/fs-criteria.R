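#' The seven filter feature-selection criteria
#'
#' @return Character vector of supported criterion names.
#' @export
fs_criteria <- function() c("MIM", "MIFS", "JMI", "mRMR", "CMIM", "ICAP", "DISR")

# --- pairwise information cache ------------------------------------------
#
# Every criterion score is a combination of univariate quantities
# I(Xi;Y), H(Xi,Y) and pairwise quantities I(Xi;Xj), I(Xi;Xj|Y),
# I(XiXj;Y), H(Xi,Xj,Y). All joint counts are obtained at once from
# crossproducts of one-hot indicator matrices (overall and per label
# stratum), which keeps B x 7 greedy selections tractable. Caching is an
# implementation detail: score_candidate() recomputes from the raw
# estimators and the two paths must agree to numerical precision.

ent_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

one_hot <- function(x) {
  lev <- sort(unique(x))
  m <- matrix(0L, length(x), length(lev))
  m[cbind(seq_along(x), match(x, lev))] <- 1L
  m
}

build_info_cache <- function(disc, y) {
  p <- ncol(disc)
  feats <- colnames(disc)
  n <- length(y)
  hots <- lapply(seq_len(p), function(j) one_hot(disc[, j]))
  ncat <- vapply(hots, ncol, integer(1))
  M <- do.call(cbind, hots)
  col_idx <- split(seq_len(sum(ncat)), rep(seq_len(p), ncat))
  ylev <- sort(unique(y))
  C_all <- crossprod(M)
  C_y <- lapply(ylev, function(l) crossprod(M[y == l, , drop = FALSE]))
  ny <- vapply(ylev, function(l) sum(y == l), numeric(1))
  Hy <- ent_from_counts(ny)
  # univariate: counts of Xi overall and per stratum
  Hx <- numeric(p); Ixy <- numeric(p); Hxy <- numeric(p)
  for (i in seq_len(p)) {
    ci <- diag(C_all)[col_idx[[i]]]
    Hx[i] <- ent_from_counts(ci)
    cxy <- vapply(C_y, function(m) diag(m)[col_idx[[i]]], numeric(length(col_idx[[i]])))
    Hxy[i] <- ent_from_counts(as.vector(cxy))
    Ixy[i] <- Hx[i] + Hy - Hxy[i]
  }
  MI <- matrix(0, p, p); CMI <- matrix(0, p, p)
  JMIY <- matrix(0, p, p); HXXY <- matrix(0, p, p)
  for (i in seq_len(p)) {
    diag_set <- if (i < p) (i + 1L):p else integer(0)
    for (j in diag_set) {
      nij <- C_all[col_idx[[i]], col_idx[[j]], drop = FALSE]
      Hij <- ent_from_counts(nij)
      MI[i, j] <- Hx[i] + Hx[j] - Hij
      trip <- vapply(C_y, function(m) m[col_idx[[i]], col_idx[[j]], drop = FALSE],
                     matrix(0, length(col_idx[[i]]), length(col_idx[[j]])))
      Hijy <- ent_from_counts(as.vector(trip))
      # I(Xi;Xj|Y) = H(Xi,Y) + H(Xj,Y) - H(Xi,Xj,Y) - H(Y)
      CMI[i, j] <- Hxy[i] + Hxy[j] - Hijy - Hy
      JMIY[i, j] <- Hij + Hy - Hijy
      HXXY[i, j] <- Hijy
      MI[j, i] <- MI[i, j]; CMI[j, i] <- CMI[i, j]
      JMIY[j, i] <- JMIY[i, j]; HXXY[j, i] <- HXXY[i, j]
    }
    MI[i, i] <- Hx[i]
    CMI[i, i] <- Hxy[i] - Hy          # H(Xi|Y)
    JMIY[i, i] <- Ixy[i]
    HXXY[i, i] <- Hxy[i]
  }
  dimnames(MI) <- dimnames(CMI) <- dimnames(JMIY) <- dimnames(HXXY) <-
    list(feats, feats)
  list(features = feats, Ixy = setNames(Ixy, feats), Hxy = setNames(Hxy, feats),
       MI = MI, CMI = CMI, JMIY = JMIY, HXXY = HXXY)
}

score_from_cache <- function(cache, criterion, k, sel, beta = 1) {
  Ixy <- cache$Ixy[k]
  if (length(sel) == 0) {
    return(switch(criterion,
      MIM = , MIFS = , JMI = , mRMR = , CMIM = , ICAP = unname(Ixy),
      DISR = unname(Ixy / cache$Hxy[k])))
  }
  switch(criterion,
    MIM  = unname(Ixy),
    MIFS = unname(Ixy - beta * sum(cache$MI[k, sel])),
    mRMR = unname(Ixy - mean(cache$MI[k, sel])),
    CMIM = unname(Ixy - max(cache$MI[k, sel] - cache$CMI[k, sel])),
    ICAP = unname(Ixy - sum(pmax(0, cache$MI[k, sel] - cache$CMI[k, sel]))),
    JMI  = unname(sum(cache$JMIY[k, sel])),
    DISR = unname(sum(cache$JMIY[k, sel] / cache$HXXY[k, sel])),
    stopf("unknown criterion '%s'", criterion))
}

#' Score one candidate feature under a selection criterion
#'
#' Evaluates the scoring function of a filter criterion for a candidate
#' column given the already-selected set, using the plug-in information
#' estimators directly:
#' \itemize{
#'   \item MIM: I(Xk;Y)
#'   \item MIFS: I(Xk;Y) - beta * sum_j I(Xk;Xj)
#'   \item mRMR: I(Xk;Y) - mean_j I(Xk;Xj)
#'   \item CMIM: I(Xk;Y) - max_j \[I(Xk;Xj) - I(Xk;Xj|Y)\]
#'   \item ICAP: I(Xk;Y) - sum_j max(0, I(Xk;Xj) - I(Xk;Xj|Y))
#'   \item JMI: sum_j I(XkXj;Y)
#'   \item DISR: sum_j I(XkXj;Y) / H(Xk,Xj,Y)
#' }
#' Empty-set conventions: sums over the selected set are 0 and the CMIM max
#' is 0, so every criterion except DISR reduces to I(Xk;Y) at the first
#' step; DISR falls back to the normalised univariate score
#' I(Xk;Y) / H(Xk,Y).
#'
#' @param xk Discrete candidate column.
#' @param y Discrete label column.
#' @param selected A data frame / matrix of already-selected discrete
#'   columns (possibly zero columns).
#' @param criterion One of [fs_criteria()].
#' @param beta MIFS redundancy weight.
#' @return The criterion score (bits, except DISR which is a ratio).
#' @export
score_candidate <- function(xk, y, selected, criterion, beta = 1) {
  criterion <- match.arg(criterion, fs_criteria())
  selected <- as.data.frame(selected)
  Ixy <- mutual_info(xk, y)
  if (ncol(selected) == 0) {
    if (criterion == "DISR") return(Ixy / shannon_entropy(xk, y))
    return(Ixy)
  }
  per_j <- function(f) vapply(selected, f, numeric(1))
  switch(criterion,
    MIM  = Ixy,
    MIFS = Ixy - beta * sum(per_j(function(xj) mutual_info(xk, xj))),
    mRMR = Ixy - mean(per_j(function(xj) mutual_info(xk, xj))),
    CMIM = Ixy - max(per_j(function(xj) mutual_info(xk, xj) - cond_mutual_info(xk, xj, y))),
    ICAP = Ixy - sum(pmax(0, per_j(function(xj)
             mutual_info(xk, xj) - cond_mutual_info(xk, xj, y)))),
    JMI  = sum(per_j(function(xj) joint_mutual_info(xk, xj, y))),
    DISR = sum(per_j(function(xj)
             joint_mutual_info(xk, xj, y) / shannon_entropy(xk, xj, y))))
}

#' Greedy forward feature selection under one criterion
#'
#' Iteratively adds the highest-scoring unselected feature until `k`
#' features are ranked. Ties are broken deterministically by ascending
#' feature name; MIM reduces to sorting features by univariate mutual
#' information with the label.
#'
#' @param data A cohort tibble (discretised internally with `scheme`) or an
#'   already-discretised tibble if `discretized = TRUE`.
#' @param criterion One of [fs_criteria()].
#' @param k Number of features to select (1 <= k <= p).
#' @param scheme A [bin_scheme()] applied when `discretized = FALSE`.
#' @param beta MIFS redundancy weight.
#' @param features Candidate feature columns; defaults to
#'   [dosage_features()]. Confounder columns (`aao`, `pc1`, `pc2`) may be
#'   included explicitly to let them compete as candidates.
#' @param discretized Set `TRUE` when `data` already holds category codes.
#' @return A tibble with columns `rank`, `feature`, `score` (the selection
#'   score at the step the feature was added), plus attribute `criterion`.
#' @export
select_features <- function(data, criterion, k, scheme = bin_scheme(), beta = 1,
                            features = NULL, discretized = FALSE) {
  criterion <- match.arg(criterion, fs_criteria())
  features <- features %||% dosage_features(data)
  if (k > length(features)) stopf("k = %d exceeds the %d candidate features",
                                  k, length(features))
  if (k < 1) stopf("k must be >= 1")
  disc <- if (discretized) data else discretize_dosage(data, scheme)
  m <- as.matrix(disc[, features, drop = FALSE])
  cache <- build_info_cache(m, disc$label)
  greedy_from_cache(cache, criterion, k, beta)
}

greedy_from_cache <- function(cache, criterion, k, beta = 1) {
  feats <- cache$features
  sel <- character(0); scores <- numeric(0)
  # order candidates by name once so which.max resolves ties lexicographically
  cand_order <- order(feats)
  for (step in seq_len(k)) {
    cand <- setdiff(feats[cand_order], sel)
    s <- vapply(cand, function(f) score_from_cache(cache, criterion, f, sel, beta),
                numeric(1))
    best <- cand[which.max(s)]
    sel <- c(sel, best); scores <- c(scores, max(s))
  }
  structure(tibble::tibble(rank = seq_len(k), feature = sel, score = scores),
            criterion = criterion)
}
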