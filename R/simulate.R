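#' Configuration for the synthetic case-control cohort generator
#'
#' The generator emulates the statistical structure of a post-imputation
#' HLA-dosage case-control study of psoriatic arthritis (PsA, label 1)
#' versus cutaneous-only psoriasis (PsC, label 0): ~70 partially correlated
#' allele-dosage features in LD blocks, one allele with a direct effect on
#' case status (an HLA-B*27 analogue), one allele whose association with
#' the label is induced purely by ascertainment on age of onset (an
#' HLA-C*06 analogue, strongly associated with early-onset psoriasis), and
#' mild population structure captured by two principal components.
#'
#' @param n_case,n_control Target cohort sizes (each >= 20).
#' @param p Number of dosage features (default 70).
#' @param allele_freqs Per-feature allele frequencies in (0.01, 0.5);
#'   default evenly spread over \[0.05, 0.45\], except the causal allele at
#'   0.25 and the confounded allele at 0.35 — common alleles, as both HLA
#'   analogues are in real psoriasis cohorts, so their information signals
#'   are estimable at cohort scale.
#' @param ld_rho Exchangeable correlation within LD blocks of
#'   `block_size` features (default 0.4).
#' @param block_size Features per LD block (default 5).
#' @param beta_causal Log-odds of case status per dosage unit of the causal
#'   allele (default 0.6).
#' @param gamma_conf Shift in age of onset (years) per dosage unit of the
#'   confounded allele (default -12).
#' @param ascertain_strength Strength of the control-arm ascertainment on
#'   early onset; controls are accept/reject sampled with weight
#'   proportional to exp(-aao * ascertain_strength / 15). 0 disables
#'   ascertainment; the default 1 reproduces strong preferential
#'   recruitment of early-onset psoriasis.
#' @param pc_effect Allele-frequency shift (logit units) per unit of the
#'   latent ancestry axis (default 0.1, mild structure).
#' @param jitter_sd Gaussian jitter added to integer genotypes to emulate
#'   imputed dosages, clipped to \[0,2\] (default 0.05 truncated at +-2 sd).
#' @param seed Seed for the whole generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 1250L, n_control = 1250L, p = 70L,
                             allele_freqs = NULL, ld_rho = 0.4, block_size = 5L,
                             beta_causal = 0.6, gamma_conf = -12,
                             ascertain_strength = 1, pc_effect = 0.1,
                             jitter_sd = 0.05, seed = 1L) {
  if (n_case < 20 || n_control < 20) stopf("n_case and n_control must be >= 20")
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must be in [0,1)")
  if (is.null(allele_freqs)) {
    allele_freqs <- seq(0.05, 0.45, length.out = p)
    allele_freqs[1L] <- 0.25                        # causal (HLA-B*27 analogue)
    allele_freqs[min(block_size + 1L, p)] <- 0.35   # confounded (HLA-C*06 analogue)
  }
  if (length(allele_freqs) != p) stopf("allele_freqs must have length p")
  if (any(allele_freqs <= 0.01 | allele_freqs >= 0.5))
    stopf("allele frequencies must lie in (0.01, 0.5)")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 p = as.integer(p), allele_freqs = allele_freqs, ld_rho = ld_rho,
                 block_size = as.integer(block_size), beta_causal = beta_causal,
                 gamma_conf = gamma_conf, ascertain_strength = ascertain_strength,
                 pc_effect = pc_effect, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw a pool of individuals from the population model (before any
# ascertainment). Returns dosages, confounders, labels.
draw_pool <- function(cfg, n) {
  p <- cfg$p
  # latent ancestry and principal components
  u <- rnorm(n)
  pc1 <- u + rnorm(n, sd = 0.5)
  pc2 <- rnorm(n)
  # allele dosages: per haplotype, block-exchangeable latent Gaussians
  # thresholded at HW quantiles of ancestry-shifted allele frequencies
  n_blocks <- ceiling(p / cfg$block_size)
  blk <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(p)]
  freq_logit <- matrix(qlogis(cfg$allele_freqs), n, p, byrow = TRUE) +
    cfg$pc_effect * u
  freq <- plogis(freq_logit)
  geno <- matrix(0L, n, p)
  for (h in 1:2) {
    shared <- matrix(rnorm(n * n_blocks), n, n_blocks)[, blk, drop = FALSE]
    z <- sqrt(cfg$ld_rho) * shared + sqrt(1 - cfg$ld_rho) * matrix(rnorm(n * p), n, p)
    geno <- geno + (z < qnorm(freq))
  }
  causal <- which_causal(cfg)
  confounded <- which_confounded(cfg)
  # case status: logistic in the causal dosage plus a small ancestry term;
  # the confounded allele has NO direct effect on the label
  eta <- -0.3 + cfg$beta_causal * geno[, causal] + 0.2 * pc1
  label <- rbinom(n, 1, plogis(eta))
  # age of psoriasis onset, shifted earlier by the confounded allele
  aao <- rnorm(n, 45, 15) + cfg$gamma_conf * geno[, confounded]
  aao <- pmin(pmax(aao, 1), 99)
  list(geno = geno, pc1 = pc1, pc2 = pc2, label = label, aao = aao)
}

which_causal <- function(cfg) 1L
which_confounded <- function(cfg) min(cfg$block_size + 1L, cfg$p)

feature_names_for <- function(cfg) {
  nm <- sprintf("HLA_X_%02d", seq_len(cfg$p))
  nm[which_causal(cfg)] <- "HLA_B_27"
  nm[which_confounded(cfg)] <- "HLA_C_06"
  nm
}

#' Generate a synthetic case-control dosage cohort
#'
#' Draws individuals from the population model of [synthetic_config()],
#' then ascertains: cases (PsA) are sampled uniformly, controls (PsC) are
#' accept/reject sampled with weight proportional to
#' exp(-aao * ascertain_strength / 15), emulating preferential recruitment
#' of early-onset psoriasis. Because the confounded allele lowers age of
#' onset, this sampling alone induces its marginal association with the
#' label. Returns exactly `n_case` cases and `n_control` controls.
#'
#' @param config A [synthetic_config()].
#' @return A cohort tibble; the ground truth (names and effect sizes of the
#'   causal and confounded features) is attached as attribute
#'   `"ground_truth"` and retrievable with [ground_truth()].
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  cfg <- config
  withr::local_seed(cfg$seed)
  n_target <- cfg$n_case + cfg$n_control
  max_draw <- 100L * n_target
  cases <- list(); controls <- list()
  n_cases <- 0L; n_controls <- 0L; drawn <- 0L
  while ((n_cases < cfg$n_case || n_controls < cfg$n_control) && drawn < max_draw) {
    batch <- min(4L * n_target, max_draw - drawn)
    pool <- draw_pool(cfg, batch)
    drawn <- drawn + batch
    is_case <- pool$label == 1L
    keep_case <- which(is_case)
    # accept/reject on early onset for controls only
    w <- exp(-pool$aao * cfg$ascertain_strength / 15)
    accept <- runif(batch) < w / max(w)
    keep_ctrl <- which(!is_case & accept)
    take <- function(idx) lapply(pool[c("geno", "pc1", "pc2", "label", "aao")],
                                 function(x) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx])
    if (n_cases < cfg$n_case && length(keep_case) > 0) {
      keep_case <- head(keep_case, cfg$n_case - n_cases)
      cases[[length(cases) + 1L]] <- take(keep_case)
      n_cases <- n_cases + length(keep_case)
    }
    if (n_controls < cfg$n_control && length(keep_ctrl) > 0) {
      keep_ctrl <- head(keep_ctrl, cfg$n_control - n_controls)
      controls[[length(controls) + 1L]] <- take(keep_ctrl)
      n_controls <- n_controls + length(keep_ctrl)
    }
  }
  if (n_cases < cfg$n_case || n_controls < cfg$n_control)
    stopf(paste("rejection sampling exhausted %d draws before reaching the target",
                "cohort size; use a weaker ascertain_strength"), max_draw)
  bind <- function(parts, fld) do.call(if (is.matrix(parts[[1]][[fld]])) rbind else c,
                                       lapply(parts, `[[`, fld))
  parts <- c(cases, controls)
  geno <- bind(parts, "geno")
  dos <- geno + pmin(pmax(matrix(rnorm(length(geno), 0, cfg$jitter_sd), nrow(geno)),
                          -2 * cfg$jitter_sd), 2 * cfg$jitter_sd)
  dos <- pmin(pmax(dos, 0), 2)
  colnames(dos) <- feature_names_for(cfg)
  out <- tibble::tibble(sample_id = sprintf("S%05d", seq_len(nrow(dos))),
                        label = as.integer(bind(parts, "label")),
                        aao = bind(parts, "aao"),
                        pc1 = bind(parts, "pc1"),
                        pc2 = bind(parts, "pc2"))
  out <- dplyr::bind_cols(out, tibble::as_tibble(dos))
  attr(out, "ground_truth") <- list(
    causal_feature = "HLA_B_27", confounded_feature = "HLA_C_06",
    beta_causal = cfg$beta_causal, gamma_conf = cfg$gamma_conf,
    ascertain_strength = cfg$ascertain_strength)
  out
}

#' Ground truth of a simulated cohort
#'
#' @param cohort A tibble returned by [simulate_cohort()].
#' @return A list with `causal_feature`, `confounded_feature` and the true
#'   effect sizes.
#' @export
ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) stopf("no ground-truth attribute; not a simulated cohort?")
  gt
}
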