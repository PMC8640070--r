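#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a tuned model
#'
#' @param x A `stratifs_model` from [tune_final()].
#' @param ... Unused.
#' @return One row per selected feature with the model's chosen
#'   hyperparameters attached as a list column.
#' @method tidy stratifs_model
#' @export
tidy.stratifs_model <- function(x, ...) {
  tibble::tibble(model = x$model, feature = x$features,
                 rank = seq_along(x$features), params = list(x$params))
}

#' @rdname tidy.stratifs_model
#' @method glance stratifs_model
#' @export
glance.stratifs_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = x$model,
                                  n_features = length(x$features)),
                   tibble::as_tibble(x$params))
}

#' Tidy nested-CV results
#'
#' @param x A `stratifs_cv` tibble from [nested_cv()].
#' @param ... Unused.
#' @return `tidy()`: the per-fold table; `glance()`: one row of metric
#'   means over the outer folds.
#' @method tidy stratifs_cv
#' @export
tidy.stratifs_cv <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.stratifs_cv
#' @method glance stratifs_cv
#' @export
glance.stratifs_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = attr(x, "model"), n_features = length(attr(x, "features"))),
    dplyr::summarise(tibble::as_tibble(x),
                     dplyr::across(c("auc", "accuracy", "precision", "recall", "f1"),
                                   mean)))
}

#' Plot a decision curve
#'
#' Net benefit against threshold probability, with the treat-all and
#' treat-none references.
#'
#' @param object A `decision_curve` tibble from [net_benefit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decision_curve
#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold probability", y = "net benefit") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap votes or the overall ranking
#'
#' @param data A [bootstrap_votes()] or [aggregate_techniques()] tibble.
#' @param top Number of top features to show (default 10).
#' @return A ggplot bar chart of votes (per-criterion) or ABV (overall).
#' @export
plot_votes <- function(data, top = 10L) {
  ycol <- if ("abv" %in% names(data)) "abv" else "vote"
  d <- head(data, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[ycol]], y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = if (ycol == "abv") "average bootstrap vote (ABV)"
                  else sprintf("vote over %s bootstraps", attr(data, "b") %||% "B"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
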