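#' Measure vessel profiles in an image
#'
#' Runs the measurement stages on one image: centerline extraction
#' (thinning, junction removal, spur pruning), spline smoothing, profile
#' extraction on the green channel, profile-length determination with the
#' CLR rules, anisotropic smoothing, and per-point model fitting on stacks
#' of neighboring profiles.
#'
#' @param image RGB array or green-channel matrix in `[0, 1]`.
#' @param mask Logical vessel mask of the same shape.
#' @param config A [vc_config()].
#' @return Measurement tibble: one row per centerline point with location,
#'   best-fit parameters, goodness-of-fit metrics, the segment profile
#'   length and CLR flag, and `estimated_width`/`matched_gt_width` columns
#'   (filled by [run_pipeline()]).
#' @export
measure_segments <- function(image, mask, config = vc_config()) {
  green <- green_channel(image)
  mask <- as_logical_mask(mask)
  if (!all(dim(green) == dim(mask))) {
    abort("Image and mask shapes differ.", class = "vc_error_input")
  }
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  empty <- tibble::tibble(
    segment_id = integer(), point_index = integer(),
    center_x = numeric(), center_y = numeric(), model_id = character(),
    prof_length = numeric(), is_clr = logical(),
    sse = numeric(), r2 = numeric(), r2_adj = numeric(), rmse = numeric(),
    converged = logical(),
    estimated_width = numeric(), matched_gt_width = numeric()
  )
  if (!any(mask)) {
    warn("Empty vessel mask; no measurements.")
    return(empty)
  }

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", what, conditionMessage(e)), parent = e)
    })
  }

  skel <- stage("centerline", split_at_junctions(skeletonize(mask)))
  segments <- stage("centerline",
                    prune_short_segments(extract_segments(skel),
                                         config$min_segment_length))
  n_seg <- length(unique(segments$segment_id))
  log_msg("centerline: %d segment(s) after junction removal and pruning", n_seg)
  if (n_seg == 0) {
    warn("No centerline segments survive pruning; no measurements.")
    return(empty)
  }
  half0 <- stage("profiles", initial_half_length(mask))
  log_msg("profiles: initial half-length %d px", half0)

  half_nb <- (config$neighbors - 1) %/% 2
  param_names <- model_param_names(config$model)
  rows_out <- list()
  for (sid in unique(segments$segment_id)) {
    seg <- segments[segments$segment_id == sid, ]
    sm <- stage("geometry", fit_spline(seg, config$spline_spacing))
    st <- stage("profiles", straighten_segment(green, sm, half0))
    out_frac <- rowMeans(attr(st, "outside"))
    eligible <- which(out_frac <= 0.25)
    lims <- purrr::map_dfr(eligible, function(i) {
      determine_limits(smoothed_mean_profile(st, i), config$clr_rules, half0)
    })
    seg_len <- if (nrow(lims)) segment_profile_length(lims) else 2 * half0
    seg_len <- min(seg_len, 2 * half0)
    is_clr_seg <- if (nrow(lims)) mean(lims$is_clr) > 0.5 else FALSE
    cut <- stage("profiles", cut_profiles(st, seg_len))
    smd <- stage("profiles", smooth_straightened(cut, seg_len))

    n_pts <- nrow(smd)
    fits <- vector("list", n_pts)
    for (i in seq_len(n_pts)) {
      rows <- max(1, i - half_nb):min(n_pts, i + half_nb)
      fit <- stage("models", fit_profile_stack(
        smd[rows, , drop = FALSE], config$model,
        standard_gaussian = config$standard_gaussian
      ))
      fits[[i]] <- dplyr::bind_cols(
        tibble::tibble(
          segment_id = sid, point_index = sm$point_index[i],
          center_x = sm$x[i], center_y = sm$y[i],
          model_id = config$model,
          prof_length = seg_len, is_clr = is_clr_seg
        ),
        tibble::as_tibble(as.list(fit$params)),
        fit$gof[, c("sse", "r2", "r2_adj", "rmse")],
        tibble::tibble(converged = fit$converged)
      )
    }
    rows_out[[length(rows_out) + 1L]] <- dplyr::bind_rows(fits)
    log_msg("segment %d: %d profiles measured (prof_length %.1f px, %d fits converged)",
            sid, n_pts, seg_len, sum(vapply(fits, function(f) f$converged, logical(1))))
  }
  meas <- dplyr::bind_rows(rows_out)
  meas$estimated_width <- NA_real_
  meas$matched_gt_width <- NA_real_
  meas
}

#' Run the full width-measurement pipeline
#'
#' Executes every stage on one image/mask pair and, when ground-truth
#' annotations are supplied, matches annotated center points to detected
#' ones, builds training records from the best-fit parameters, evaluates
#' width estimation with the configured validation scheme (out-of-fold
#' predictions fill `estimated_width` for matched points) and trains a final
#' regressor on all matched records. Alternatively a previously trained
#' regressor can be supplied to obtain widths without annotations.
#'
#' @param image RGB array or green-channel matrix in `[0, 1]`.
#' @param mask Logical vessel mask of the same shape.
#' @param config A [vc_config()].
#' @param annotations Optional annotation tibble (see [read_annotations()];
#'   a `width` column is derived from the edge points if absent).
#' @param regressor Optional `vc_width_regressor` used to predict widths.
#' @return List of class `vc_pipeline` with `measurements`, `report` (a
#'   `vc_evaluation` tibble or `NULL`), `validation`, `matching`,
#'   `regressor` and `config`.
#' @export
run_pipeline <- function(image, mask, config = vc_config(),
                         annotations = NULL, regressor = NULL) {
  meas <- measure_segments(image, mask, config)
  report <- NULL; validation <- NULL; matching <- NULL
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  if (!is.null(regressor) && nrow(meas)) {
    meas$estimated_width <- predict_width(regressor, meas)
  }
  if (!is.null(annotations) && nrow(meas)) {
    if (!"width" %in% names(annotations)) {
      annotations$width <- sqrt((annotations$edge1_x - annotations$edge2_x)^2 +
                                  (annotations$edge1_y - annotations$edge2_y)^2)
    }
    matching <- match_centers(
      data.frame(x = annotations$center_x, y = annotations$center_y),
      data.frame(x = meas$center_x, y = meas$center_y)
    )
    log_msg("matching: %d of %d ground-truth profiles matched",
            nrow(matching$pairs), nrow(annotations))
    if (nrow(matching$pairs) >= 2) {
      pn <- model_param_names(config$model)
      records <- dplyr::bind_cols(
        meas[matching$pairs$det_index, c("segment_id", pn)],
        tibble::tibble(
          width_gt = annotations$width[matching$pairs$gt_index],
          profile_id = matching$pairs$det_index,
          gt_index = matching$pairs$gt_index
        )
      )
      validation <- if (config$validation == "loso") {
        run_loso(records, config$regressor, n_gt_total = nrow(annotations))
      } else {
        run_kfold(records, k = config$k, seed = config$seed,
                  config = config$regressor, n_gt_total = nrow(annotations))
      }
      report <- validation$report
      meas$estimated_width[records$profile_id] <- validation$predictions$width_pred
      meas$matched_gt_width[records$profile_id] <- records$width_gt
      regressor <- train_width_regressor(records, config$regressor)
      un <- which(is.na(meas$estimated_width))
      if (length(un)) {
        meas$estimated_width[un] <- predict_width(regressor, meas[un, ])
      }
      log_msg("evaluation (%s): SR %.1f%%, mu_error %.3f px, sigma_error %.3f px",
              config$validation, report$sr, report$mu_error, report$sigma_error)
    } else {
      warn("Fewer than 2 matched profiles; skipping width evaluation.")
    }
  }
  structure(
    list(measurements = meas, report = report, validation = validation,
         matching = matching, regressor = regressor, config = config),
    class = "vc_pipeline"
  )
}

#' @export
print.vc_pipeline <- function(x, ...) {
  cat(sprintf("<vc_pipeline> %d measurements on %d segment(s), model %s\n",
              nrow(x$measurements),
              length(unique(x$measurements$segment_id)), x$config$model))
  if (!is.null(x$report)) {
    cat(sprintf("  SR %.1f%%  mu_error %+.3f px  sigma_error %.3f px (n_p = %d)\n",
                x$report$sr, x$report$mu_error, x$report$sigma_error, x$report$n_p))
  }
  invisible(x)
}
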