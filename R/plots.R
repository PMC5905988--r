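# ggplot2 displays for the package's result types.

#' Plot a fitted profile model over its data
#'
#' @param object A `vc_fit` from [fit_profile_stack()].
#' @param ... Unused.
#' @return A ggplot: pooled profile samples and the best-fit model curve.
#' @export
autoplot.vc_fit <- function(object, ...) {
  dat <- object$data
  xs <- seq(min(dat$x), max(dat$x), length.out = 200)
  curve <- tibble::tibble(
    x = xs,
    y = evaluate_model(object$model_id, object$params, xs)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, color = "darkorange", linewidth = 0.9) +
    ggplot2::labs(
      x = "position along cross-section (px)", y = "intensity",
      title = sprintf("%s fit (R² = %.3f)", object$model_id, object$gof$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a straightened vessel segment
#'
#' @param object A `vc_straightened` matrix from [straighten_segment()].
#' @param ... Unused.
#' @return A ggplot raster of the straightened vessel image (profiles lie
#'   horizontally, the vessel runs vertically).
#' @export
autoplot.vc_straightened <- function(object, ...) {
  offs <- attr(object, "offsets")
  dat <- tidyr::expand_grid(row = seq_len(nrow(object)), offset = offs)
  dat$value <- as.numeric(t(unclass(object)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$offset, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "offset from centerline (px)", y = "centerline point") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of a validation run
#'
#' @param object A `vc_validation` from [run_kfold()] or [run_loso()].
#' @param ... Unused.
#' @return A ggplot of measurement errors against ground-truth diameter,
#'   with the mean error and the 1.96-sigma agreement limits.
#' @export
autoplot.vc_validation <- function(object, ...) {
  pts <- bland_altman_points(object$predictions$width_pred,
                             object$predictions$width_gt)
  mu <- object$report$mu_error
  sdv <- object$report$sigma_error
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$width_gt, y = .data$error)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = mu, color = "darkorange") +
    ggplot2::geom_hline(yintercept = mu + c(-1.96, 1.96) * sdv,
                        linetype = "dashed", color = "darkorange") +
    ggplot2::labs(x = "ground-truth diameter (px)",
                  y = "measured - ground truth (px)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic dataset
#'
#' @param object A `vc_synthetic` from [render_vessel_image()].
#' @param show_gt Overlay the ground-truth edge points (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot raster of the green channel.
#' @export
autoplot.vc_synthetic <- function(object, show_gt = TRUE, ...) {
  g <- object$green
  dat <- tidyr::expand_grid(y = seq_len(nrow(g)) - 1, x = seq_len(ncol(g)) - 1)
  dat$value <- as.numeric(t(g))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (show_gt && nrow(object$gt_profiles)) {
    edges <- dplyr::bind_rows(
      dplyr::transmute(object$gt_profiles, x = .data$edge1_x, y = .data$edge1_y),
      dplyr::transmute(object$gt_profiles, x = .data$edge2_x, y = .data$edge2_y)
    )
    p <- p + ggplot2::geom_point(data = edges,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE,
                                 color = "yellow", size = 0.2)
  }
  p
}
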