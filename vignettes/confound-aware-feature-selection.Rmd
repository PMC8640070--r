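---
title: "Confound-aware information-theoretic feature selection and risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confound-aware information-theoretic feature selection and risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratifs)
library(dplyr)
```

## The problem

Genetic risk-prediction studies that contrast two related phenotypes — here
psoriatic arthritis (PsA) against cutaneous-only psoriasis (PsC) — typically
start from a table of imputed allele dosages in $[0,2]$ across the HLA
region. Two properties of such data defeat naive feature selection:

* **Redundancy.** Linkage disequilibrium (LD) makes neighbouring alleles
  highly correlated, so univariate rankings select blocks of
  near-duplicates.
* **Confounding by ascertainment.** When one arm of a case-control cohort
  is recruited preferentially at early disease onset, any allele associated
  with onset age acquires a spurious marginal association with the outcome.
  HLA-C\*06 is the canonical example: it drives early-onset psoriasis, so
  onset-biased recruitment of the psoriasis-only arm makes it look like the
  most informative "PsA predictor" even though its association is an
  artefact of sampling. The real discriminating allele, HLA-B\*27, is then
  out-ranked.

`stratifs` implements a pipeline that addresses both: mutual-information
filter criteria handle redundancy explicitly, and a stratification step
removes confounder-label associations before selection.

## Information estimators

All information quantities are plug-in (histogram) estimates on
independently discretised columns, in bits (base-2 logarithms; rankings are
invariant to the base). The binning scheme follows the data's natural
cutpoints: dosages split at 1 into $[0,1)$ vs $[1,2]$ (carrier of at least
one allele copy), principal components at 0, and age at onset into five
20-year bins on integer-rounded years ($[0,20], [21,40], \dots, [81,100]$,
out-of-range values clipped to the nearest bin). Zero-probability cells
contribute zero and no smoothing is applied. Interval endpoints are closed
on the side that keeps the full $[0,2]$ dosage range covered; the
conventions are fixed in `bin_scheme()` and asserted by tests.

For discrete $X$, $Y$:

$$I(X;Y)=\sum_{x,y} p(x,y)\log_2\frac{p(x,y)}{p(x)p(y)}$$

with conditional and joint variants $I(X;Z\mid Y)$ and $I(X_1X_2;Y)$ (the
pair treated as one variable over the product alphabet). The test suite
checks non-negativity, symmetry, the bound $I(X;Y)\le\min(H(X),H(Y))$ and
the chain rule $I(X_1X_2;Y)=I(X_1;Y)+I(X_2;Y\mid X_1)$ to $10^{-10}$ on
randomised tables.

## The seven selection criteria

Forward selection maintains a selected set $S$ and at each step adds the
candidate $X_k$ maximising the criterion score:

| Criterion | Score for candidate $X_k$ |
|---|---|
| MIM  | $I(X_k;Y)$ |
| MIFS | $I(X_k;Y)-\beta\sum_{j\in S} I(X_k;X_j)$ |
| mRMR | $I(X_k;Y)-\frac{1}{|S|}\sum_{j\in S} I(X_k;X_j)$ |
| CMIM | $I(X_k;Y)-\max_{j\in S}\,[I(X_k;X_j)-I(X_k;X_j\mid Y)]$ |
| ICAP | $I(X_k;Y)-\sum_{j\in S}\max(0,\,I(X_k;X_j)-I(X_k;X_j\mid Y))$ |
| JMI  | $\sum_{j\in S} I(X_kX_j;Y)$ |
| DISR | $\sum_{j\in S} I(X_kX_j;Y)\,/\,H(X_k,X_j,Y)$ |

Empty-set conventions: sums over $S$ are zero and the CMIM max is zero, so
every criterion starts from univariate relevance; DISR, whose sum would be
identically zero, starts from the normalised univariate score
$I(X_k;Y)/H(X_k,Y)$, preserving its normalisation idea. The MIFS
redundancy weight defaults to $\beta=1$, the canonical setting in that
criterion's literature, and is exposed as `mifs_beta`. Ties are broken by
ascending feature name everywhere, which makes selections bit-reproducible.

Internally the greedy loop reads all pairwise quantities from a cache built
by one-hot crossproducts (overall and per label stratum), so a full
7-criterion sweep over 100 bootstraps costs seconds rather than hours;
`score_candidate()` recomputes every score from the raw estimators and the
suite asserts the two paths agree, so caching cannot change results.

## Stratification-based mitigation

`mitigate_cohort()` divides samples into strata over the cross-product of
the three binned confounders (age-at-onset bin × PC1 sign × PC2 sign) and,
within every stratum containing both classes, upsamples the minority class
with replacement until the class counts are exactly equal. Single-class
strata are dropped with a warning; original rows of retained strata are
always kept. After balancing, the class label is exactly independent of
each binned confounder, so a confounder can no longer transmit a marginal
association to any allele: the confounded allele's MI with the label
collapses while a directly associated allele's MI is preserved up to
estimator noise.

Design choices that were genuinely open:

* **Joint vs sequential strata.** Balancing once over the joint confounder
  grid controls all three confounders simultaneously and is
  order-invariant; a `sequential = TRUE` mode (age, then PC1, then PC2,
  rebalancing after each) is provided for comparison experiments.
* **Upsampling, never downsampling**, so no observed data are discarded.
* **Order relative to the hold-out split.** Mitigation is applied to the
  training portion only, after the split: hold-out and external samples
  must never influence, or be duplicated into, anything the models see.

A caveat worth knowing: because balancing duplicates rows, cross-validation
*on the mitigated table* lets copies of one sample fall on both sides of a
fold boundary. Memorising models (k-NN especially) then show optimistic CV
AUC; the clean hold-out and external sets expose this, and the effect is
visible in this package's own end-to-end outputs. This is inherent to
balance-then-CV designs, which is why the unresampled hold-out is split off
first and kept pristine.

## Bootstrap stability aggregation

Single greedy selections are unstable under resampling, so each criterion
is run on $B=100$ bootstrap resamples (drawn with replacement *within each
class*, preserving class counts — this cannot produce a single-class
resample) with $K=10$ features kept per bootstrap. Per feature and
criterion this yields the vote $V$ (number of bootstraps where the feature
entered the top-$K$; $\sum_f V_f = BK$ exactly) and the mean rank $R$ over
exactly those bootstraps. Across the seven criteria the overall ranking
reports the Technique Vote (how many criteria's aggregate top-$K$ contain
the feature), the average bootstrap vote $\mathrm{ABV} = \sum_c V_c / 7$
(absent criteria contribute 0), and the average bootstrap rank
$\mathrm{ABR}$, averaged over the criteria where $R$ is defined (an
all-criterion denominator would need an arbitrary penalty rank for
never-selected features, which nothing in the procedure defines). Ordering
is Technique Vote desc, ABV desc, ABR asc, name asc.

## Risk-prediction benchmarking

`run_grid()` evaluates every combination of selection criterion,
feature-subset size ($n \in \{1, 10, 20, \dots, 70\}$ by default, capped at
$p$) and model. Seven classifiers are supported: penalised logistic
regression (glmnet ridge, grid over inverse regularisation $C$), AdaBoost
(discrete SAMME over depth-1 CART stumps, implemented in-package; grids
over rounds and learning rate), gradient-boosted trees (xgboost; rounds,
learning rate, depth, min child weight, with $\gamma=2$, $\lambda=0.5$,
$\alpha=0.5$ fixed), random forest (ranger; trees, depth, `mtry`, leaf
size), k-NN ($k \in \{1,3,5\}$), a single decision tree (rpart; depth, min
split, min leaf — CART has no per-split feature subsampling, so no `mtry`
analogue), and Gaussian naive Bayes (no tunables; tuning is a no-op refit).

Each cell runs stratified 5×2 nested cross-validation: outer folds estimate
generalisation, inner folds pick hyperparameters by mean inner AUC. Per
model type the best cell maximises mean outer AUC, with ties broken by
fewer features then criterion name; it is then re-tuned on the whole
training set and scored on the hold-out and external data. With the default
7 criteria × 8 subset sizes × 7 models the grid has 392 cells; an optional
no-selection arm (`include_all_features = TRUE`) adds an eighth
"all-features" criterion column for 448. Metrics are AUC (rank statistic
with midranks), and accuracy/precision/recall/F1 at threshold 0.5 with the
zero convention for empty denominators. Decision-curve analysis reports the
net benefit $\mathrm{NB}(p_t) = TP/N - (FP/N)\,p_t/(1-p_t)$ on the
threshold range $p_t \in [0.25, 0.75]$ with treat-all and treat-none
references.

## What the synthetic generator emulates

Restricted-access cohorts cannot ship with a package, so every stage is
exercised on `simulate_cohort()`, which reproduces the *structure* the
analysis assumes:

1. a latent ancestry axis $u$, observed noisily as PC1 (PC2 is pure noise);
2. 70 allele dosages in LD blocks of 5 with exchangeable correlation
   $\rho = 0.4$, thresholded from Gaussians at Hardy-Weinberg quantiles of
   ancestry-shifted frequencies, plus clipped jitter (sd 0.05) to mimic
   imputation;
3. case status logistic in the causal allele (log-odds 0.6 per dosage
   unit, the HLA-B\*27 analogue) plus a small PC1 term — the confounded
   allele has **no** direct effect;
4. age at onset normal(45, 15) shifted by $-12$ years per dosage unit of
   the confounded allele (the HLA-C\*06 analogue), clipped to $[1,99]$;
5. ascertainment: cases sampled uniformly, controls accept/reject sampled
   with weight $\propto e^{-\mathrm{aao}/15}$ — this sampling alone
   creates the confounded allele's marginal association with the label.

Default cohort size is 1250 cases + 1250 controls. Allele frequencies
default to an even spread over $[0.05, 0.45]$ with the causal allele at
0.25 and the confounded allele at 0.35; both analogues are common alleles
in real psoriasis cohorts, and at these frequencies the confounded signal
(≈0.02 bits) dominates the causal one (≈0.012 bits) before mitigation
while the causal signal stays well above estimator noise at $n = 2500$,
which is the regime the real study describes. These values were fixed once,
by simulation at large $n$, and are exposed in `synthetic_config()`.

What the generator does *not* emulate: realistic MHC haplotype structure
(block-exchangeable LD is enough to stress the redundancy terms but not to
mimic real LD decay), 4-digit alleles or amino-acid features, genotyping or
imputation error beyond dosage jitter, and case-control misclassification.
Passing tests therefore demonstrate that the pipeline recovers the designed
causal structure under ascertainment confounding — not that any particular
real-data AUC is reproducible.

## Numerical choices and degenerate inputs

* Entropies use $0\log 0 = 0$; MI is clamped only by test tolerance
  ($\ge -10^{-12}$), never rounded in computation.
* Non-finite dosages or confounders are rejected with the offending cell
  named; missing values are rejected rather than imputed (quality control
  belongs upstream of the dosage table).
* A cohort with a single class, a stratum layout with no two-class
  stratum, or an empty hyperparameter grid are hard errors.
* All randomness descends from one master seed through deterministic
  per-stage child seeds; identical configuration and inputs give
  byte-identical result tables.

## Problem sizes used in the shipped checks

The test suite runs the confounding-recovery property at the full study
configuration (n = 2500 cohorts, $B = 100$, $K = 10$, all seven criteria,
20 master seeds) and the permutation-null guard at n = 500, p = 20 over 20
seeds. `scripts/acceptance.R` recomputes the same quantities over 8
replicate cohorts, runs a 10-seed permutation null, and finishes with an
end-to-end `run_pipeline()` on one default cohort against an independently
simulated external cohort, using reduced model grids (LR, RF, k-NN, NB;
subset sizes 1/10/20) so the whole script completes in minutes.

## Known limitations

* Plug-in MI is biased upward on small strata; no bias correction or
  adaptive binning is attempted (by design — the estimators are the plain
  histogram ones).
* Upsampling duplicates rows, so CV on mitigated data is optimistic for
  memorising models (see above); compare against the hold-out.
* ABR is undefined for features never selected by any criterion and is
  reported as `NA`, not imputed.
* The stratification controls only the three declared confounders at the
  chosen bin resolution; residual within-bin confounding survives.
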