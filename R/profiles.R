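#' Sample a cross-section intensity profile
#'
#' Samples the green-channel image along the normal to the centerline at one
#' point, at 1-pixel spacing with bilinear interpolation, symmetrically about
#' the centerline point. Samples falling outside the image are filled with
#' the nearest-edge value and flagged.
#'
#' @param green Numeric image matrix in `[0, 1]`, indexed `[row, col]`.
#' @param point Numeric length-2 vector `c(x, y)`, 0-based pixel coordinates
#'   of the centerline point; must lie inside the image.
#' @param normal Unit 2-vector `c(x, y)` giving the profile direction.
#' @param half_len Integer half-length; the profile has `2 * half_len + 1`
#'   samples at offsets `-half_len .. half_len`.
#' @return A tibble of class `vc_profile` with columns `offset` (pixels from
#'   the centerline point), `value` and `outside` (logical flag).
#' @export
sample_profile <- function(green, point, normal, half_len) {
  stopifnot(is.matrix(green), length(point) == 2, length(normal) == 2,
            half_len >= 1)
  if (point[1] < 0 || point[1] > ncol(green) - 1 ||
      point[2] < 0 || point[2] > nrow(green) - 1) {
    abort("`point` lies outside the image.", class = "vc_error_input")
  }
  k <- seq(-half_len, half_len)
  s <- bilinear_sample(green, point[1] + k * normal[1], point[2] + k * normal[2])
  out <- tibble::tibble(offset = k, value = s$values, outside = s$outside)
  class(out) <- c("vc_profile", class(out))
  out
}

#' Initial profile half-length from the segmentation mask
#'
#' Derives a profile half-length guaranteed to cover the widest vessel in the
#' image: 1.5 times the largest vessel diameter, where the diameter is twice
#' the maximum of the Euclidean distance transform of the mask.
#'
#' @param mask Logical vessel mask with at least one true pixel.
#' @return Integer half-length in pixels.
#' @export
initial_half_length <- function(mask) {
  m <- as_logical_mask(mask)
  if (!any(m)) abort("`mask` has no true pixels.", class = "vc_error_input")
  dm <- EBImage::distmap(m * 1)
  as.integer(ceiling(1.5 * 2 * max(dm)))
}

#' Stack the profiles of a segment into a straightened vessel image
#'
#' Samples one cross-section profile per smoothed centerline point and stacks
#' them row-wise, aligned by their center samples. The result is the
#' straightened vessel image: profiles lie horizontally, the vessel runs
#' vertically.
#'
#' @param green Numeric image matrix in `[0, 1]`.
#' @param smoothed `vc_smoothed` tibble from [fit_spline()].
#' @param half_len Integer profile half-length (see [initial_half_length()]).
#' @return Numeric matrix of class `vc_straightened` with one row per
#'   centerline point and `2 * half_len + 1` columns, carrying attributes
#'   `outside` (logical matrix of edge-filled samples), `centers` (per-row
#'   x/y), `normals`, `segment_id` and `offsets`.
#' @export
straighten_segment <- function(green, smoothed, half_len) {
  stopifnot(is.matrix(green), half_len >= 1)
  n <- nrow(smoothed)
  k <- seq(-half_len, half_len)
  vals <- matrix(NA_real_, n, length(k))
  outs <- matrix(FALSE, n, length(k))
  for (i in seq_len(n)) {
    s <- bilinear_sample(
      green,
      smoothed$x[i] + k * smoothed$nrm_x[i],
      smoothed$y[i] + k * smoothed$nrm_y[i]
    )
    vals[i, ] <- s$values
    outs[i, ] <- s$outside
  }
  structure(
    vals,
    outside = outs,
    centers = cbind(x = smoothed$x, y = smoothed$y),
    normals = cbind(x = smoothed$nrm_x, y = smoothed$nrm_y),
    segment_id = smoothed$segment_id[1],
    offsets = k,
    class = c("vc_straightened", "matrix", "array")
  )
}

# Savitzky-Golay window for extremum detection: a fixed short window (5
# samples, order 2) suppresses pixel noise without displacing or flattening
# the narrow background maxima that bound the vessel; windows that grow with
# the search span smear them into spurious outer peaks.
sg_window <- function(len, order = 2) {
  w <- 5L
  wmax <- if (len %% 2 == 1) len else len - 1
  w <- min(w, wmax)
  if (w <= order) w <- order + 1 + (order %% 2)  # next odd above order
  as.integer(w)
}

#' Smoothed mean profile around one centerline point
#'
#' Averages up to `window` adjacent cross-section profiles (centered on `row`,
#' truncated at the segment ends) and smooths the mean with a Savitzky-Golay
#' filter (polynomial order 2, fixed 5-sample window).
#'
#' @param straight `vc_straightened` matrix from [straighten_segment()].
#' @param row 1-based row (centerline point) index.
#' @param window Number of adjacent profiles to average (default 11).
#' @return Numeric vector with as many samples as the profiles.
#' @export
smoothed_mean_profile <- function(straight, row, window = 11) {
  n <- nrow(straight)
  if (row < 1 || row > n) abort("`row` out of range.", class = "vc_error_input")
  half <- (window - 1) %/% 2
  rows <- max(1, row - half):min(n, row + half)
  mp <- colMeans(straight[rows, , drop = FALSE])
  w <- sg_window(length(mp))
  if (w >= length(mp)) return(mp)
  as.numeric(signal::sgolayfilt(mp, p = 2, n = w))
}

#' Median profile length of a segment
#'
#' @param limits Tibble of per-profile limits from [determine_limits()] (or
#'   any data frame with a `prof_length` column), or a numeric vector of
#'   lengths.
#' @return Median profile length in pixels; for an even count, the mean of
#'   the two middle values.
#' @export
segment_profile_length <- function(limits) {
  len <- if (is.data.frame(limits)) limits$prof_length else as.numeric(limits)
  if (!length(len)) abort("No profile lengths given.", class = "vc_error_input")
  median(len)
}

#' Cut a straightened segment to a common profile length
#'
#' Keeps samples within `round(length / 2)` pixels of the center column, so
#' each profile ends up with `2 * round(length / 2) + 1` samples, symmetric
#' about the centerline.
#'
#' @param straight `vc_straightened` matrix.
#' @param length Target profile length in pixels; must be positive and no
#'   larger than the current profile span.
#' @return The cut `vc_straightened` matrix.
#' @export
cut_profiles <- function(straight, length) {
  if (length <= 0) abort("`length` must be positive.", class = "vc_error_input")
  offs <- attr(straight, "offsets")
  half <- max(offs)
  h2 <- round(length / 2)
  if (h2 > half) abort("`length` exceeds the current profile span.",
                       class = "vc_error_input")
  keep <- which(abs(offs) <= h2)
  out <- straight[, keep, drop = FALSE]
  structure(
    out,
    outside = attr(straight, "outside")[, keep, drop = FALSE],
    centers = attr(straight, "centers"),
    normals = attr(straight, "normals"),
    segment_id = attr(straight, "segment_id"),
    offsets = offs[keep],
    class = class(straight)
  )
}

#' Anisotropic Gaussian smoothing of a straightened segment
#'
#' Smooths the straightened vessel image with an anisotropic Gaussian whose
#' standard deviations scale with the segment profile length: across the
#' profile (horizontal) `0.1 * prof_length` and along the vessel (vertical)
#' `1.5 * prof_length`, so wider vessels are smoothed more than thinner ones
#' while vessel edges stay sharp. Boundaries are handled by symmetric
#' reflection; the kernel is normalized, so constant images are unchanged.
#'
#' @param straight `vc_straightened` matrix.
#' @param prof_length Segment profile length in pixels.
#' @return The smoothed `vc_straightened` matrix.
#' @export
smooth_straightened <- function(straight, prof_length) {
  stopifnot(prof_length > 0, nrow(straight) >= 1)
  sm <- blur_separable(unclass(straight),
                       sigma_row = 1.5 * prof_length,
                       sigma_col = 0.1 * prof_length)
  attributes(sm) <- attributes(straight)
  sm
}
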