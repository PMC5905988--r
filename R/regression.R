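#' Configuration for the width regressor ensemble
#'
#' Hyperparameters of the ensemble of bagged regression trees with random
#' feature selection used to map best-fit model parameters to vessel width.
#'
#' @param n_trees Number of trees (default 100).
#' @param predictors_per_split Predictors sampled at each split; `NULL`
#'   (default) resolves to `max(1, round(N / 3))` for `N` model parameters at
#'   training time.
#' @param min_leaf Minimum records per leaf (default 5).
#' @param seed RNG seed making training deterministic (default 1).
#' @return List of class `vc_regressor_config`.
#' @export
regressor_config <- function(n_trees = 100, predictors_per_split = NULL,
                             min_leaf = 5, seed = 1) {
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(
    list(n_trees = as.integer(n_trees),
         predictors_per_split = predictors_per_split,
         min_leaf = as.integer(min_leaf),
         seed = as.integer(seed)),
    class = "vc_regressor_config"
  )
}

# Columns of a training-record tibble that are metadata, not predictors.
RECORD_META_COLS <- c("width_gt", "segment_id", "dataset_id", "profile_id",
                      "point_index", "gt_index", "fold")

record_param_cols <- function(records) {
  cols <- setdiff(names(records), RECORD_META_COLS)
  cols[vapply(records[cols], is.numeric, logical(1))]
}

#' Train the width regressor
#'
#' Fits an ensemble of bagged regression trees (bootstrap-resampled, with
#' random predictor selection at each split) mapping the `N` best-fit model
#' parameters of a profile to its ground-truth width. Training is
#' deterministic given the config seed.
#'
#' @param records Tibble of training records: one row per profile with the
#'   numeric model-parameter columns and a `width_gt` column (pixels, > 0).
#'   Columns named `segment_id`, `dataset_id`, `profile_id`, `point_index`
#'   are treated as metadata, not predictors.
#' @param config A [regressor_config()].
#' @return Object of class `vc_width_regressor`.
#' @export
train_width_regressor <- function(records, config = regressor_config()) {
  stopifnot(is.data.frame(records))
  if (!"width_gt" %in% names(records) || nrow(records) < 2) {
    abort("`records` needs a width_gt column and at least 2 rows.",
          class = "vc_error_input")
  }
  if (any(records$width_gt <= 0)) {
    abort("All ground-truth widths must be positive.", class = "vc_error_input")
  }
  pcols <- record_param_cols(records)
  if (!length(pcols)) abort("No numeric predictor columns found.",
                            class = "vc_error_input")
  n_par <- length(pcols)
  mtry <- config$predictors_per_split %||% max(1L, round(n_par / 3))
  mtry <- min(as.integer(mtry), n_par)
  dat <- as.data.frame(records[, c(pcols, "width_gt")])
  forest <- ranger::ranger(
    dependent.variable.name = "width_gt",
    data = dat,
    num.trees = config$n_trees,
    mtry = mtry,
    min.node.size = config$min_leaf,
    replace = TRUE,
    seed = config$seed,
    num.threads = 1
  )
  structure(
    list(forest = forest, param_cols = pcols, config = config,
         width_range = range(records$width_gt)),
    class = "vc_width_regressor"
  )
}

#' Predict vessel width from model parameters
#'
#' @param regressor A `vc_width_regressor` from [train_width_regressor()].
#' @param params Named numeric vector with the model parameters, or a data
#'   frame with one row per profile.
#' @return Numeric vector of estimated widths (pixels).
#' @export
predict_width <- function(regressor, params) {
  stopifnot(inherits(regressor, "vc_width_regressor"))
  if (!is.data.frame(params)) {
    if (is.null(names(params)) || !all(regressor$param_cols %in% names(params))) {
      abort(sprintf("`params` must provide columns: %s",
                    paste(regressor$param_cols, collapse = ", ")),
            class = "vc_error_input")
    }
    params <- tibble::as_tibble(as.list(params[regressor$param_cols]))
  }
  if (!all(regressor$param_cols %in% names(params))) {
    abort("`params` is missing predictor columns.", class = "vc_error_input")
  }
  pr <- predict(regressor$forest,
                data = as.data.frame(params[, regressor$param_cols]),
                num.threads = 1)
  as.numeric(pr$predictions)
}

#' @export
print.vc_width_regressor <- function(x, ...) {
  cat(sprintf("<vc_width_regressor> %d trees, %d predictors (mtry %d), widths %.2f-%.2f px\n",
              x$forest$num.trees, length(x$param_cols), x$forest$mtry,
              x$width_range[1], x$width_range[2]))
  invisible(x)
}

#' Match ground-truth center points to detected center points
#'
#' Establishes a unique correspondence between annotated and detected vessel
#' center points: candidate pairs closer than `max_dist` pixels are accepted
#' greedily in order of increasing distance, so each ground-truth point and
#' each detected point is used at most once and ties go to the closer pair.
#'
#' @param gt_centers,detected_centers Data frames with numeric `x` and `y`
#'   columns (0-based pixel coordinates) in a common frame.
#' @param max_dist Exclusive distance cutoff in pixels (default 5).
#' @return List of class `vc_matching` with `pairs` (tibble `gt_index`,
#'   `det_index`, `distance`; 1-based row indices into the inputs) and
#'   `unmatched_gt` (integer vector).
#' @export
match_centers <- function(gt_centers, detected_centers, max_dist = 5) {
  gx <- as.numeric(gt_centers$x); gy <- as.numeric(gt_centers$y)
  dx <- as.numeric(detected_centers$x); dy <- as.numeric(detected_centers$y)
  ng <- length(gx); nd <- length(dx)
  pairs <- tibble::tibble(gt_index = integer(), det_index = integer(),
                          distance = numeric())
  if (ng && nd) {
    dmat <- sqrt(outer(gx, dx, "-")^2 + outer(gy, dy, "-")^2)
    cand <- which(dmat < max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dmat[cand])
      cand <- cand[ord, , drop = FALSE]
      used_g <- logical(ng); used_d <- logical(nd)
      keep_g <- integer(0); keep_d <- integer(0); keep_dist <- numeric(0)
      for (i in seq_len(nrow(cand))) {
        g <- unname(cand[i, 1]); d <- unname(cand[i, 2])
        if (used_g[g] || used_d[d]) next
        used_g[g] <- TRUE; used_d[d] <- TRUE
        keep_g <- c(keep_g, g); keep_d <- c(keep_d, d)
        keep_dist <- c(keep_dist, dmat[g, d])
      }
      pairs <- tibble::tibble(gt_index = keep_g, det_index = keep_d,
                              distance = keep_dist)
    }
  }
  structure(
    list(pairs = pairs,
         unmatched_gt = setdiff(seq_len(ng), pairs$gt_index),
         n_gt = ng, n_detected = nd),
    class = "vc_matching"
  )
}

#' @export
print.vc_matching <- function(x, ...) {
  cat(sprintf("<vc_matching> %d/%d ground-truth points matched (%d detected)\n",
              nrow(x$pairs), x$n_gt, x$n_detected))
  invisible(x)
}
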