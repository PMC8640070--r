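#' Assign each sample to a confounder stratum
#'
#' Strata are the cross-product of the binned confounders: the 20-year age
#' at onset bin and the sign bins of the two principal components. The
#' assignment is deterministic given the binning scheme.
#'
#' @param data A cohort tibble.
#' @param scheme A [bin_scheme()].
#' @return A tibble with columns `sample_id`, `aao_bin`, `pc1_bin`,
#'   `pc2_bin`, `stratum` (a readable id string), in input row order.
#' @export
assign_strata <- function(data, scheme = bin_scheme()) {
  for (col in c("aao", "pc1", "pc2")) {
    if (any(!is.finite(data[[col]])))
      stopf("non-finite %s in row %d", col, which(!is.finite(data[[col]]))[1])
  }
  aao_bin <- bin_aao(data$aao, scheme)
  edges <- scheme$aao_edges
  lower <- c(0, edges[-length(edges)] + 1)
  lab <- sprintf("%d-%d", lower, edges)
  tibble::tibble(
    sample_id = data$sample_id,
    aao_bin = aao_bin,
    pc1_bin = bin_pc(data$pc1, scheme),
    pc2_bin = bin_pc(data$pc2, scheme),
    stratum = sprintf("aao%s|pc1:%d|pc2:%d", lab[aao_bin + 1],
                      bin_pc(data$pc1, scheme), bin_pc(data$pc2, scheme)))
}

#' Per-stratum class counts
#'
#' @param data A cohort tibble.
#' @param scheme A [bin_scheme()].
#' @return A tibble with one row per stratum: class-0 and class-1 counts.
#' @export
stratum_table <- function(data, scheme = bin_scheme()) {
  st <- assign_strata(data, scheme)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(stratum = st$stratum, label = data$label),
                    .data$stratum),
    n0 = sum(.data$label == 0L), n1 = sum(.data$label == 1L), .groups = "drop")
}

#' Mitigate confounding by within-stratum class balancing
#'
#' Implements the stratification procedure: samples are divided into strata
#' over the joint confounder bins (age-at-onset bin x PC1 sign x PC2 sign)
#' and, within every stratum containing both classes, the minority class is
#' upsampled with replacement (uniformly over its rows in that stratum)
#' until the two class counts are equal. After balancing, the class label
#' is independent of each binned confounder by construction, so a
#' confounder can no longer transmit a marginal association to any allele.
#' Strata containing a single class are dropped with a warning; all
#' original rows of retained strata are kept.
#'
#' @param data A cohort tibble with both classes present.
#' @param scheme A [bin_scheme()].
#' @param seed Seed for the resampling.
#' @param sequential If `TRUE`, balance one confounder at a time (age bins,
#'   then PC1 sign, then PC2 sign, rebalancing after each) instead of the
#'   default single pass over the joint cross-product strata. The joint
#'   pass controls all three confounders simultaneously and is
#'   order-invariant; the sequential mode exists for fidelity experiments.
#' @return A cohort tibble (original retained rows first, then duplicates
#'   with suffixed sample ids), with attributes `audit` (per-stratum counts
#'   before/after), `provenance` (duplicate id -> source id) and `seed`,
#'   retrievable with [mitigation_audit()].
#' @export
mitigate_cohort <- function(data, scheme = bin_scheme(), seed = 1L,
                            sequential = FALSE) {
  if (length(unique(data$label)) < 2) stopf("dataset contains a single class")
  if (sequential) {
    out <- data
    for (i in seq_along(c("aao", "pc1", "pc2"))) {
      conf <- c("aao", "pc1", "pc2")[i]
      out <- balance_on(out, conf, scheme, derive_seed(seed, conf))
    }
    attr(out, "audit") <- stratum_table(out, scheme)
    attr(out, "seed") <- seed
    attr(out, "ground_truth") <- attr(data, "ground_truth")
    return(out)
  }
  st <- assign_strata(data, scheme)
  counts <- stratum_table(data, scheme)
  retained <- counts$stratum[counts$n0 > 0 & counts$n1 > 0]
  dropped <- setdiff(counts$stratum, retained)
  if (length(retained) == 0) stopf("every stratum is single-class; nothing retainable")
  if (length(dropped) > 0)
    warn(sprintf("dropping %d single-class stratum/strata: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  keep <- st$stratum %in% retained
  base <- data[keep, , drop = FALSE]
  base_strat <- st$stratum[keep]
  withr::local_seed(seed)
  dup_rows <- integer(0)
  # strata processed in sorted order so the draw sequence is reproducible
  for (s in sort(retained)) {
    in_s <- which(base_strat == s)
    lab <- base$label[in_s]
    n0 <- sum(lab == 0L); n1 <- sum(lab == 1L)
    if (n0 == n1) next
    minority <- if (n0 < n1) 0L else 1L
    pool <- in_s[lab == minority]
    extra <- abs(n1 - n0)
    dup_rows <- c(dup_rows, pool[sample.int(length(pool), extra, replace = TRUE)])
  }
  dup <- base[dup_rows, , drop = FALSE]
  prov <- tibble::tibble(duplicate_id = character(0), source_id = character(0))
  if (nrow(dup) > 0) {
    dup_ids <- sprintf("%s.dup%03d", dup$sample_id,
                       stats::ave(seq_len(nrow(dup)), dup$sample_id, FUN = seq_along))
    prov <- tibble::tibble(duplicate_id = dup_ids, source_id = dup$sample_id)
    dup$sample_id <- dup_ids
  }
  out <- dplyr::bind_rows(base, dup)
  post <- stratum_table(out, scheme)
  audit <- dplyr::left_join(
    dplyr::rename(counts, pre_n0 = "n0", pre_n1 = "n1"),
    dplyr::rename(post, post_n0 = "n0", post_n1 = "n1"),
    by = "stratum")
  audit$retained <- audit$stratum %in% retained
  audit$post_n0[is.na(audit$post_n0)] <- 0L
  audit$post_n1[is.na(audit$post_n1)] <- 0L
  attr(out, "audit") <- audit
  attr(out, "provenance") <- prov
  attr(out, "seed") <- seed
  attr(out, "ground_truth") <- attr(data, "ground_truth")
  out
}

# One sequential balancing pass on a single binned confounder.
balance_on <- function(data, conf, scheme, seed) {
  bins <- switch(conf, aao = bin_aao(data$aao, scheme),
                 pc1 = bin_pc(data$pc1, scheme), pc2 = bin_pc(data$pc2, scheme))
  both <- tapply(data$label, bins, function(l) length(unique(l)) == 2)
  keep <- bins %in% as.integer(names(both)[both])
  base <- data[keep, , drop = FALSE]
  bb <- bins[keep]
  withr::local_seed(seed)
  dup_rows <- integer(0)
  for (b in sort(unique(bb))) {
    in_b <- which(bb == b)
    lab <- base$label[in_b]
    n0 <- sum(lab == 0L); n1 <- sum(lab == 1L)
    if (n0 == n1) next
    minority <- if (n0 < n1) 0L else 1L
    pool <- in_b[lab == minority]
    dup_rows <- c(dup_rows, pool[sample.int(length(pool), abs(n1 - n0), replace = TRUE)])
  }
  dup <- base[dup_rows, , drop = FALSE]
  if (nrow(dup) > 0)
    dup$sample_id <- sprintf("%s.%s%03d", dup$sample_id, conf,
                             stats::ave(seq_len(nrow(dup)), dup$sample_id, FUN = seq_along))
  dplyr::bind_rows(base, dup)
}

#' Audit table of a mitigated cohort
#'
#' @param mitigated A tibble returned by [mitigate_cohort()].
#' @return The per-stratum pre/post class-count audit tibble.
#' @export
mitigation_audit <- function(mitigated) {
  a <- attr(mitigated, "audit")
  if (is.null(a)) stopf("no audit attribute; not a mitigated cohort?")
  a
}
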