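# broom-style tidiers for fitted objects and evaluation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained FoG classifier
#'
#' One row per boosting round: the estimator weight (alpha) and the number
#' of leaves of the tree.
#'
#' @param x a `fog_adaboost`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fog_adaboost <- function(x, ...) {
  n_leaves <- function(node) {
    if (!is.null(node$leaf)) {
      return(1L)
    }
    n_leaves(node$left) + n_leaves(node$right)
  }
  tibble::tibble(
    estimator = seq_along(x$trees),
    alpha = x$alphas,
    n_leaves = vapply(x$trees, n_leaves, 1L)
  )
}

#' @rdname tidy.fog_adaboost
#' @export
glance.fog_adaboost <- function(x, ...) {
  tibble::tibble(
    n_estimators = length(x$trees),
    max_tree_depth = x$config$max_tree_depth,
    n_features = length(x$feature_names),
    total_alpha = sum(x$alphas)
  )
}

#' Tidy leave-one-subject-out results
#'
#' `tidy()` returns the per-fold metrics; `glance()` the mean/sd summary in
#' wide form plus the summed-confusion totals.
#'
#' @param x a `fog_cv` from [loso_cv()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fog_cv <- function(x, ...) {
  x$folds
}

#' @rdname tidy.fog_cv
#' @export
glance.fog_cv <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_folds = nrow(x$folds),
    auc_mean = s$mean[s$metric == "auc"],
    auc_sd = s$sd[s$metric == "auc"],
    sensitivity_mean = s$mean[s$metric == "sensitivity"],
    specificity_mean = s$mean[s$metric == "specificity"],
    accuracy_mean = s$mean[s$metric == "accuracy"],
    total_sensitivity = x$total[["sensitivity"]],
    total_specificity = x$total[["specificity"]],
    total_accuracy = x$total[["accuracy"]]
  )
}

#' Tidy phase-matching results
#'
#' `tidy()` returns the matched pairs; `glance()` the counts and printed
#' rates.
#'
#' @param x a `fog_match` from [match_phases()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fog_match <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.fog_match
#' @export
glance.fog_match <- function(x, ...) {
  tibble::tibble(
    n_annotated = x$counts$n_annotated,
    n_correct = x$counts$n_correct,
    n_missed = x$counts$n_missed,
    n_false = x$counts$n_false,
    rate_correct = x$rates$rate_correct,
    rate_missed = x$rates$rate_missed
  )
}
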