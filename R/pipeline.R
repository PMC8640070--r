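#' Run the full confound-aware selection and prediction pipeline
#'
#' Convenience wrapper chaining the four stages on one cohort: (1)
#' class-stratified hold-out split; (2) stratification-based confounder
#' mitigation of the training portion only (the hold-out is never
#' resampled, avoiding leakage); (3) per-criterion bootstrap stability
#' selection on the mitigated training data plus the cross-criterion
#' overall ranking; (4) the criterion x feature-count x model evaluation
#' grid with hold-out (and optional external) validation.
#'
#' @param cohort A cohort tibble.
#' @param config A [run_config()]; its master seed drives every stage.
#' @param external Optional external-validation cohort.
#' @param mitigate Apply confounder mitigation to the training portion
#'   (default `TRUE`).
#' @param grids Optional hyperparameter-grid overrides (see [run_grid()]).
#' @return A list: `split`, `train` (mitigated), `votes` (per-criterion
#'   [bootstrap_votes()] tables), `overall` ([aggregate_techniques()]
#'   ranking), `eval` (the [run_grid()] result).
#' @export
run_pipeline <- function(cohort, config = run_config(), external = NULL,
                         mitigate = TRUE, grids = NULL) {
  sp <- split_holdout(cohort, frac = config$holdout_frac,
                      seed = derive_seed(config$seed, "holdout"))
  train <- if (mitigate) {
    mitigate_cohort(sp$train, config$scheme,
                    seed = derive_seed(config$seed, "mitigate"))
  } else sp$train
  votes <- bootstrap_votes_all(train, config$criteria, k = config$k,
                               b = config$b,
                               seed = derive_seed(config$seed, "bootstrap"),
                               scheme = config$scheme, beta = config$mifs_beta)
  overall <- aggregate_techniques(votes)
  ev <- run_grid(train, sp$holdout, rankings = votes, config = config,
                 external = external, grids = grids)
  list(split = sp, train = train, votes = votes, overall = overall, eval = ev)
}
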