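#' Smooth a centerline segment with a least-squares cubic spline
#'
#' Fits a piecewise-cubic planar curve to the ordered centerline points of one
#' segment by least squares, using the centripetal scheme (parameter
#' increments proportional to the square root of chordal distance) for
#' parametrization. The number of polynomial pieces is the segment point
#' count divided by 20 pixels, rounded to the nearest integer with a floor of
#' one. One smoothed sample is returned per input point, together with the
#' unit tangent (first derivative direction) and the unit normal (tangent
#' rotated by +90 degrees).
#'
#' @param segment Tibble with the ordered points of a single segment; must
#'   have columns `x` and `y` (0-based pixel coordinates) and at least 4
#'   points. A `segment_id` column, if present, must be constant.
#' @param spacing Target pixel spacing per spline piece (default 20).
#' @return A tibble of class `vc_smoothed` with columns `segment_id`,
#'   `point_index`, `x`, `y`, `tan_x`, `tan_y`, `nrm_x`, `nrm_y` and an
#'   `n_pieces` attribute.
#' @examples
#' seg <- tibble::tibble(x = 0:39, y = rep(5, 40))
#' sm <- fit_spline(seg)
#' attr(sm, "n_pieces")
#' @export
fit_spline <- function(segment, spacing = 20) {
  stopifnot(is.data.frame(segment), all(c("x", "y") %in% names(segment)))
  if ("segment_id" %in% names(segment) &&
      length(unique(segment$segment_id)) > 1) {
    abort("`segment` must contain a single segment_id.", class = "vc_error_input")
  }
  if ("point_index" %in% names(segment)) {
    segment <- dplyr::arrange(segment, .data$point_index)
  }
  px <- as.numeric(segment$x)
  py <- as.numeric(segment$y)
  n <- length(px)
  if (n < 4) {
    abort("Segment has fewer than 4 points; cannot fit a cubic spline.",
          class = "vc_error_short_segment")
  }

  # drop exact consecutive duplicates for parametrization, remembering the
  # representative of each original point
  keep <- c(TRUE, (diff(px) != 0) | (diff(py) != 0))
  rep_of <- cumsum(keep)
  ux <- px[keep]; uy <- py[keep]
  if (length(ux) < 4) {
    abort("Segment has fewer than 4 distinct points.",
          class = "vc_error_short_segment")
  }

  # centripetal parametrization
  chord <- sqrt(diff(ux)^2 + diff(uy)^2)
  t_u <- c(0, cumsum(sqrt(chord)))
  n_pieces <- max(1L, as.integer(round(n / spacing)))

  bknots <- range(t_u)
  iknots <- if (n_pieces > 1) {
    bknots[1] + (seq_len(n_pieces - 1) / n_pieces) * diff(bknots)
  } else {
    numeric(0)
  }
  basis_at <- function(tt) {
    splines::bs(tt, knots = iknots, degree = 3, intercept = TRUE,
                Boundary.knots = bknots)
  }
  B <- basis_at(t_u)
  cx <- lm.fit(B, ux)$coefficients
  cy <- lm.fit(B, uy)$coefficients
  cx[is.na(cx)] <- 0
  cy[is.na(cy)] <- 0

  t_all <- t_u[rep_of]
  Bp <- basis_at(t_all)
  sx <- as.numeric(Bp %*% cx)
  sy <- as.numeric(Bp %*% cy)

  # first derivative by symmetric finite differences in parameter space,
  # one-sided at the boundary (the basis is undefined outside its knots)
  h <- max(diff(bknots) * 1e-6, 1e-9)
  tl <- pmax(t_all - h, bknots[1])
  tr <- pmin(t_all + h, bknots[2])
  Bl <- basis_at(tl)
  Br <- basis_at(tr)
  dx <- as.numeric((Br - Bl) %*% cx) / (tr - tl)
  dy <- as.numeric((Br - Bl) %*% cy) / (tr - tl)
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm == 0] <- 1
  tx <- dx / nrm; ty <- dy / nrm

  out <- tibble::tibble(
    segment_id = if ("segment_id" %in% names(segment)) segment$segment_id else 1L,
    point_index = if ("point_index" %in% names(segment)) segment$point_index else seq_len(n) - 1L,
    x = sx, y = sy,
    tan_x = tx, tan_y = ty,
    nrm_x = -ty, nrm_y = tx
  )
  attr(out, "n_pieces") <- n_pieces
  class(out) <- c("vc_smoothed", class(out))
  out
}

#' Points and unit normals of a smoothed segment
#'
#' @param smoothed A `vc_smoothed` tibble from [fit_spline()].
#' @return Tibble with columns `x`, `y`, `nrm_x`, `nrm_y`, one row per sample.
#' @export
normals_at <- function(smoothed) {
  stopifnot(inherits(smoothed, "vc_smoothed") ||
              all(c("x", "y", "nrm_x", "nrm_y") %in% names(smoothed)))
  tibble::as_tibble(smoothed[, c("x", "y", "nrm_x", "nrm_y")])
}
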