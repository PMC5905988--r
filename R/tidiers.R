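# broom-style accessors for the package's fitted objects.

#' Tidy a fitted profile model
#'
#' @param x A `vc_fit` from [fit_profile_stack()].
#' @param ... Unused.
#' @return Tibble with one row per model parameter (`term`, `estimate`).
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params))
}

#' One-row summary of a fitted profile model
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return Tibble with the goodness-of-fit metrics, `model_id`, `converged`
#'   and the pooled point count.
#' @export
glance.vc_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model_id = x$model_id),
    x$gof,
    tibble::tibble(converged = x$converged)
  )
}

#' One-row summary of a trained width regressor
#'
#' @param x A `vc_width_regressor`.
#' @param ... Unused.
#' @return Tibble with the ensemble hyperparameters and out-of-bag fit
#'   statistics.
#' @export
glance.vc_width_regressor <- function(x, ...) {
  tibble::tibble(
    n_trees = x$forest$num.trees,
    mtry = x$forest$mtry,
    min_leaf = x$forest$min.node.size,
    n_records = x$forest$num.samples,
    oob_mse = x$forest$prediction.error,
    oob_r2 = x$forest$r.squared
  )
}

#' Per-profile predictions of a validation run
#'
#' @param x A `vc_validation` from [run_kfold()] or [run_loso()].
#' @param ... Unused.
#' @return The predictions tibble (records plus `width_pred` and `fold`).
#' @export
tidy.vc_validation <- function(x, ...) {
  tibble::as_tibble(x$predictions)
}

#' One-row summary of a validation run
#'
#' @param x A `vc_validation`.
#' @param ... Unused.
#' @return The pooled `vc_evaluation` report.
#' @export
glance.vc_validation <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Matched center-point pairs as a tibble
#'
#' @param x A `vc_matching` from [match_centers()].
#' @param ... Unused.
#' @return The pairs tibble (`gt_index`, `det_index`, `distance`).
#' @export
tidy.vc_matching <- function(x, ...) {
  x$pairs
}
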