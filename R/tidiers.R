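#' Tidy a tuned classifier
#'
#' One row per hyperparameter configuration evaluated during the CV grid
#' search, with its mean CV F1.
#'
#' @param x A `cm_model` from [tune_classifier()].
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy cm_model
#' @export
tidy.cm_model <- function(x, ...) {
  x$cv_results
}

#' One-row summary of a tuned classifier
#' @param x A `cm_model`.
#' @param ... Ignored.
#' @return A one-row tibble: family, task, best mean CV F1, training size.
#' @method glance cm_model
#' @export
glance.cm_model <- function(x, ...) {
  tibble::tibble(family = x$family, task = x$task, best_cv_f1 = x$best_cv_f1,
                 n_train = length(x$train_ids),
                 n_configs = nrow(x$cv_results))
}

#' Tidy classification metrics
#' @param x A `cm_metrics`.
#' @param ... Ignored.
#' @return A tibble with one row per metric.
#' @method tidy cm_metrics
#' @export
tidy.cm_metrics <- function(x, ...) {
  tibble::tibble(metric = c("precision", "recall", "accuracy", "f1"),
                 value = c(x$precision, x$recall, x$accuracy, x$f1))
}

#' One-row summary of classification metrics
#' @param x A `cm_metrics`.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @method glance cm_metrics
#' @export
glance.cm_metrics <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 accuracy = x$accuracy, f1 = x$f1, n = sum(x$confusion))
}

#' Tidy Shapley scores
#' @param x A `cm_shapley`.
#' @param ... Ignored.
#' @return A tibble: feature, score (and standard error in sampled mode),
#'   ordered by absolute score.
#' @method tidy cm_shapley
#' @export
tidy.cm_shapley <- function(x, ...) {
  out <- tibble::tibble(feature = names(x$scores), score = unname(x$scores))
  if (!is.null(x$se)) out$se <- unname(x$se)
  dplyr::arrange(out, dplyr::desc(abs(.data$score)))
}

#' Tidy an optimizer result
#' @param x A `cm_filteropt`.
#' @param ... Ignored.
#' @return The evaluation trace tibble `M, N, f1`.
#' @method tidy cm_filteropt
#' @export
tidy.cm_filteropt <- function(x, ...) {
  x$trace
}

#' One-row summary of an optimizer result
#' @param x A `cm_filteropt`.
#' @param ... Ignored.
#' @return A one-row tibble: `M_star`, `N_star`, `best_f1`, `n_evaluations`.
#' @method glance cm_filteropt
#' @export
glance.cm_filteropt <- function(x, ...) {
  tibble::tibble(M_star = x$M_star, N_star = x$N_star, best_f1 = x$best_f1,
                 n_evaluations = nrow(x$trace))
}
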