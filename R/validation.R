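#' Width-measurement evaluation metrics
#'
#' Computes the precision metrics of the method from paired estimated and
#' ground-truth widths. The per-profile error is `chi_i = omega_i - psi_i`
#' (estimate minus ground truth); `mu_error` is its mean and `sigma_error`
#' its standard deviation with an `n_p - 1` denominator - the primary
#' precision criterion. The success rate is the percentage of ground-truth
#' profiles for which a measurement was returned.
#'
#' @param widths_est,widths_gt Equal-length numeric vectors of measured and
#'   ground-truth widths (pixels), one element per evaluated profile.
#' @param n_gt_total Total number of ground-truth profiles (the success-rate
#'   denominator); defaults to the number of evaluated pairs.
#' @return One-row tibble of class `vc_evaluation` with `n_p`, `sr`,
#'   `mu_meas`, `sigma_meas`, `mu_error`, `sigma_error`.
#' @export
evaluate_widths <- function(widths_est, widths_gt,
                            n_gt_total = length(widths_gt)) {
  w <- as.numeric(widths_est); g <- as.numeric(widths_gt)
  if (length(w) != length(g)) abort("Width vectors must have equal length.",
                                    class = "vc_error_input")
  n_p <- length(w)
  if (n_p < 2) abort("At least 2 pairs are needed for sigma_error.",
                     class = "vc_error_input")
  chi <- w - g
  out <- tibble::tibble(
    n_p = n_p,
    sr = 100 * n_p / n_gt_total,
    mu_meas = mean(w),
    sigma_meas = sd(w),
    mu_error = mean(chi),
    sigma_error = sd(chi)
  )
  class(out) <- c("vc_evaluation", class(out))
  out
}

# Shared engine for the two validation schemes: trains on all records outside
# each fold and predicts the held-out fold, then pools the errors.
run_validation_folds <- function(records, fold, config, n_gt_total) {
  preds <- rep(NA_real_, nrow(records))
  for (f in unique(fold)) {
    test <- fold == f
    reg <- train_width_regressor(records[!test, , drop = FALSE], config)
    preds[test] <- predict_width(reg, records[test, , drop = FALSE])
  }
  predictions <- dplyr::mutate(records, width_pred = preds, fold = fold)
  structure(
    list(
      report = evaluate_widths(preds, records$width_gt, n_gt_total),
      predictions = predictions
    ),
    class = "vc_validation"
  )
}

#' k-fold cross-validation of the width regressor
#'
#' Randomly partitions the training records into `k` folds at the profile
#' level; each fold is predicted exactly once by a regressor trained on the
#' other `k - 1` folds, and the pooled out-of-fold errors are summarized.
#'
#' @param records Training-record tibble (see [train_width_regressor()]).
#' @param k Number of folds (default 10). `k = nrow(records)` degenerates to
#'   leave-one-out.
#' @param seed Seed for the random fold assignment.
#' @param config A [regressor_config()].
#' @param n_gt_total Success-rate denominator (defaults to `nrow(records)`).
#' @return List of class `vc_validation` with `report` (a `vc_evaluation`
#'   tibble) and `predictions` (records plus `width_pred` and `fold`).
#' @export
run_kfold <- function(records, k = 10, seed = 1,
                      config = regressor_config(),
                      n_gt_total = nrow(records)) {
  n <- nrow(records)
  if (n < k) abort("Fewer records than folds.", class = "vc_error_input")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  run_validation_folds(records, fold, config, n_gt_total)
}

#' Leave-one-segment-out validation of the width regressor
#'
#' One validation iteration per vessel segment: all profiles of the held-out
#' segment are predicted by a regressor trained on the remaining segments,
#' so no test profile shares a segment with its training set.
#'
#' @param records Training-record tibble with a `segment_id` column and at
#'   least two distinct segments.
#' @param config A [regressor_config()].
#' @param n_gt_total Success-rate denominator (defaults to `nrow(records)`).
#' @return List of class `vc_validation`, as [run_kfold()].
#' @export
run_loso <- function(records, config = regressor_config(),
                     n_gt_total = nrow(records)) {
  if (!"segment_id" %in% names(records)) {
    abort("`records` needs a segment_id column.", class = "vc_error_input")
  }
  if (length(unique(records$segment_id)) < 2) {
    abort("Leave-one-segment-out needs at least 2 segments.",
          class = "vc_error_input")
  }
  run_validation_folds(records, records$segment_id, config, n_gt_total)
}

#' Pairwise correlation between segment mean profiles
#'
#' Measures the similarity between vessel segments of a dataset: each
#' segment is represented by the mean of its cross-section profiles; for
#' every unordered pair the two mean profiles are aligned at their maxima,
#' the cross-correlation is computed at that alignment over the overlapping
#' samples, and the value is normalized by the larger of the two
#' autocorrelation peaks, so identical profiles score 1.
#'
#' @param segment_mean_profiles List of numeric vectors (one mean profile per
#'   segment), or a data frame with `segment_id` and `value` columns in
#'   profile order.
#' @return One-row tibble with `mu_corr`, `sigma_corr`, `max_corr` and the
#'   pair count `n_comb = n (n - 1) / 2`.
#' @export
segment_correlations <- function(segment_mean_profiles) {
  profs <- segment_mean_profiles
  if (is.data.frame(profs)) {
    profs <- split(profs$value, profs$segment_id)
  }
  ns <- length(profs)
  if (ns < 2) abort("Need at least 2 segments.", class = "vc_error_input")
  cors <- numeric(0)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      a <- as.numeric(profs[[i]]); b <- as.numeric(profs[[j]])
      shift <- which.max(a) - which.max(b)   # align b's maximum onto a's
      ia <- seq_along(a)
      ib <- ia - shift                        # index into b aligned under a
      ok <- ib >= 1 & ib <= length(b)
      aa <- a[ia[ok]]; bb <- b[ib[ok]]
      denom <- max(sum(aa^2), sum(bb^2))
      cors <- c(cors, if (denom > 0) sum(aa * bb) / denom else 0)
    }
  }
  tibble::tibble(
    mu_corr = mean(cors),
    sigma_corr = sd(cors),
    max_corr = max(cors),
    n_comb = ns * (ns - 1) / 2
  )
}

#' Bland-Altman points for width agreement
#'
#' One point per measured profile with the ground-truth diameter on the
#' abscissa and the measurement error (estimate minus ground truth) on the
#' ordinate.
#'
#' @param widths_est,widths_gt Equal-length numeric width vectors (pixels).
#' @return Tibble with columns `width_gt` and `error`.
#' @export
bland_altman_points <- function(widths_est, widths_gt) {
  w <- as.numeric(widths_est); g <- as.numeric(widths_gt)
  if (length(w) != length(g)) abort("Width vectors must have equal length.",
                                    class = "vc_error_input")
  tibble::tibble(width_gt = g, error = w - g)
}
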