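# Independent longhand oracles. These deliberately share no code with the
# package: entropies come from base table() proportions and every criterion
# is evaluated term-by-term from its formula.

oracle_entropy <- function(...) {
  tab <- table(...)
  p <- tab[tab > 0] / sum(tab)
  as.numeric(-sum(p * log2(p)))
}

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    pxy <- tab[i, j] / n
    if (pxy > 0) s <- s + pxy * log2(pxy / (px[i] * py[j]))
  }
  as.numeric(s)
}

oracle_cmi <- function(x, z, y) {
  s <- 0
  for (l in unique(y)) {
    w <- y == l
    s <- s + mean(w) * oracle_mi(x[w], z[w])
  }
  as.numeric(s)
}

oracle_jmi_pair <- function(x1, x2, y) {
  oracle_mi(interaction(x1, x2, drop = TRUE), y)
}

# Term-by-term evaluation of the seven criterion scores.
oracle_score <- function(criterion, xk, y, sel_cols, beta = 1) {
  rel <- oracle_mi(xk, y)
  if (length(sel_cols) == 0) {
    if (criterion == "DISR") return(rel / oracle_entropy(xk, y))
    return(rel)
  }
  red <- vapply(sel_cols, function(xj) oracle_mi(xk, xj), numeric(1))
  cred <- vapply(sel_cols, function(xj) oracle_cmi(xk, xj, y), numeric(1))
  switch(criterion,
    MIM = rel,
    MIFS = rel - beta * sum(red),
    mRMR = rel - mean(red),
    CMIM = rel - max(red - cred),
    ICAP = rel - sum(pmax(0, red - cred)),
    JMI = sum(vapply(sel_cols, function(xj) oracle_jmi_pair(xk, xj, y), numeric(1))),
    DISR = sum(vapply(sel_cols, function(xj)
      oracle_jmi_pair(xk, xj, y) / oracle_entropy(xk, xj, y), numeric(1))))
}

# Brute-force greedy selection: re-scores every unselected feature at every
# step from scratch via oracle_score, ties by feature name.
oracle_greedy <- function(criterion, disc, y, k, beta = 1) {
  feats <- sort(colnames(disc))
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(feats, sel)
    s <- vapply(cand, function(f)
      oracle_score(criterion, disc[, f], y, lapply(sel, function(g) disc[, g]), beta),
      numeric(1))
    sel <- c(sel, cand[which.max(s)])
  }
  sel
}

# Fixed 6-feature, n = 64 discrete table used by the criterion oracle suite:
# a deterministic mix of informative, redundant and noisy binary columns.
fixture_table <- function() {
  withr::with_seed(20240101, {
    n <- 64
    y <- rep(c(0L, 1L), each = n / 2)
    x1 <- ifelse(runif(n) < 0.8, y, 1L - y)        # informative
    x2 <- x1; flip <- sample(n, 6); x2[flip] <- 1L - x2[flip]  # redundant with x1
    x3 <- sample(0:1, n, replace = TRUE)           # noise
    x4 <- ifelse(runif(n) < 0.65, y, 1L - y)       # weakly informative
    x5 <- as.integer(xor(x1, x3))                  # interaction
    x6 <- sample(0:2, n, replace = TRUE)           # 3-level noise
    m <- cbind(F1 = x1, F2 = x2, F3 = x3, F4 = x4, F5 = x5, F6 = x6)
    list(x = m, y = y)
  })
}

# Small random discrete table for property-style tests.
random_table <- function(n = 40, p = 4, max_cat = 3) {
  m <- vapply(seq_len(p), function(j)
    sample(0:(sample(2:max_cat, 1) - 1), n, replace = TRUE), integer(n))
  colnames(m) <- sprintf("G%02d", seq_len(p))
  list(x = m, y = sample(0:1, n, replace = TRUE))
}

# Tiny ready-made cohort for io/mitigation unit tests.
toy_cohort <- function(n = 60, p = 4, seed = 99) {
  simulate_cohort(synthetic_config(n_case = max(20, n %/% 2),
                                   n_control = max(20, n %/% 2),
                                   p = p, seed = seed))
}
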