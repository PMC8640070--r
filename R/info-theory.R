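#' Binning scheme for dosages, principal components and age at onset
#'
#' All information-theoretic quantities in this package are plug-in
#' (histogram) estimates on independently discretised columns. Dosages in
#' \[0,2\] are split at `dosage_cut` into two categories (\[0,1) vs \[1,2\]);
#' principal components are split at `pc_cut` (negative vs non-negative);
#' age at onset is mapped to 20-year bins on integer-rounded years
#' (0-20, 21-40, 41-60, 61-80, 81-100), with out-of-range values clipped
#' to the nearest bin.
#'
#' @param dosage_cut Dosage cutpoint, default 1.
#' @param pc_cut Principal-component cutpoint, default 0.
#' @param aao_edges Upper edges of the age-at-onset bins (years), strictly
#'   increasing; the default `c(20, 40, 60, 80, 100)` gives five 20-year bins.
#' @return A `bin_scheme` list.
#' @export
bin_scheme <- function(dosage_cut = 1, pc_cut = 0, aao_edges = c(20, 40, 60, 80, 100)) {
  if (any(diff(aao_edges) <= 0)) stopf("`aao_edges` must be strictly increasing")
  structure(list(dosage_cut = dosage_cut, pc_cut = pc_cut, aao_edges = aao_edges),
            class = "bin_scheme")
}

bin_dosage <- function(x, scheme) as.integer(x >= scheme$dosage_cut)
bin_pc <- function(x, scheme) as.integer(x >= scheme$pc_cut)
bin_aao <- function(x, scheme) {
  # closed integer ranges [0,20], [21,40], ...: round to whole years first,
  # clip out-of-range values to the nearest bin
  e <- scheme$aao_edges
  idx <- findInterval(round(x), c(-Inf, e[-length(e)] + 1L))
  pmin(pmax(idx, 1L), length(e)) - 1L
}

#' Discretise a cohort table
#'
#' Applies the binning scheme column-wise: dosage features become 0/1 codes,
#' `pc1`/`pc2` become 0/1 codes, `aao` becomes its 20-year bin index, and
#' `label`/`sample_id` pass through unchanged.
#'
#' @param data A cohort tibble (see [read_dosage_table()]).
#' @param scheme A [bin_scheme()].
#' @return A tibble of the same shape with integer category codes.
#' @export
discretize_dosage <- function(data, scheme = bin_scheme()) {
  feats <- dosage_features(data)
  bad <- vapply(data[c(feats, intersect(RESERVED_COLS[-1], names(data)))],
                function(x) any(!is.finite(x)), logical(1))
  if (any(bad)) stopf("non-finite values in column(s): %s",
                      paste(names(bad)[bad], collapse = ", "))
  out <- data
  for (f in feats) out[[f]] <- bin_dosage(data[[f]], scheme)
  for (p in intersect(c("pc1", "pc2"), names(data))) out[[p]] <- bin_pc(data[[p]], scheme)
  if ("aao" %in% names(data)) out$aao <- bin_aao(data$aao, scheme)
  out
}

#' Plug-in Shannon entropy (bits)
#'
#' Entropy of the empirical (joint) distribution of one or more discrete
#' columns, base-2 logarithm, with the convention 0 log 0 = 0. Multiple
#' columns are treated as one variable over the product alphabet.
#'
#' @param ... One or more equal-length discrete vectors.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(...) {
  cols <- list(...)
  n <- unique(lengths(cols))
  if (length(n) != 1L) stopf("columns must have equal length")
  if (n == 0L) stopf("empty input")
  counts <- as.vector(table(interaction(cols, drop = TRUE)))
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Mutual information between two discrete columns (bits)
#'
#' Plug-in estimate I(X;Y) = sum p(x,y) log2 p(x,y) / (p(x) p(y)) over the
#' empirical joint distribution; non-negative and symmetric.
#'
#' @param x,y Equal-length discrete vectors.
#' @return Mutual information in bits.
#' @export
mutual_info <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  shannon_entropy(x) + shannon_entropy(y) - shannon_entropy(x, y)
}

#' Conditional mutual information I(X;Z|Y) (bits)
#'
#' Weighted per-stratum plug-in estimate: sum over y of p(y) I(X;Z | Y=y).
#'
#' @param x,z,y Equal-length discrete vectors.
#' @return Conditional mutual information in bits.
#' @export
cond_mutual_info <- function(x, z, y) {
  if (length(x) != length(z) || length(x) != length(y)) stopf("length mismatch")
  shannon_entropy(x, y) + shannon_entropy(z, y) -
    shannon_entropy(x, z, y) - shannon_entropy(y)
}

#' Joint mutual information I(X1X2;Y) (bits)
#'
#' The information between the target and the joint variable obtained by
#' pairing two columns over their product alphabet.
#'
#' @param x1,x2,y Equal-length discrete vectors.
#' @return Joint mutual information in bits.
#' @export
joint_mutual_info <- function(x1, x2, y) {
  if (length(x1) != length(x2) || length(x1) != length(y)) stopf("length mismatch")
  shannon_entropy(x1, x2) + shannon_entropy(y) - shannon_entropy(x1, x2, y)
}
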