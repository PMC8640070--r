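#' @importFrom rlang .data abort warn
#' @importFrom stats predict qnorm rnorm runif rbinom plogis qlogis setNames
#' @importFrom utils head
NULL

# Column names with a fixed role in a cohort table; everything else is a
# dosage feature.
RESERVED_COLS <- c("sample_id", "label", "aao", "pc1", "pc2")

#' Feature columns of a cohort table
#'
#' A cohort table is an ordinary tibble with the reserved columns
#' `sample_id`, `label`, `aao`, `pc1`, `pc2`; every other column is treated
#' as an allele-dosage feature.
#'
#' @param data A cohort tibble.
#' @return Character vector of feature column names, in table order.
#' @export
dosage_features <- function(data) {
  setdiff(names(data), RESERVED_COLS)
}

# Deterministically derive a 31-bit child seed from a master seed and a
# stage tag, so each pipeline stage is individually reproducible.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(master) * 48271 + h * 16807) %% 2147483563L) + 1L
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a
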