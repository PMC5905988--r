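#' Central-light-reflex rule thresholds
#'
#' Bundles the thresholds of the peak-search rules used by
#' [determine_limits()]. The published description of the rules leaves the
#' numeric thresholds open ("obtained by experimentation"); these defaults
#' were chosen from the typical geometry of vessel cross-sections and can all
#' be overridden, individually or through the run configuration.
#'
#' @param min_minima_separation Minimum distance (px) between the two CLR
#'   minima for a candidate CLR region to be accepted.
#' @param max_bump_depth_ratio Maximum relative difference of the two CLR
#'   bump depths (depth = limiting-maximum value minus adjacent-minimum
#'   value).
#' @param max_limit_distance_difference Maximum relative difference
#'   `|dL - dR| / max(dL, dR)` between the center-to-limit distances.
#' @param max_limit_distance_frac A limiting maximum farther than this
#'   fraction of the initial half-length from the vessel center is "too far".
#' @param center_value_tolerance Fraction of the profile dynamic range within
#'   which the center-proximal maximum counts as "close in value" to the
#'   lowest maximum.
#' @param center_offset_frac Fraction of the profile length within which a
#'   maximum counts as "not too far" from the profile center.
#' @param min_limit_center_distance Minimum distance (px) between a limiting
#'   maximum and the central minimum in the non-CLR branch ("too close"
#'   test).
#' @return A list of class `vc_clr_rules`.
#' @export
clr_rules <- function(min_minima_separation = 3,
                      max_bump_depth_ratio = 0.5,
                      max_limit_distance_difference = 0.5,
                      max_limit_distance_frac = 0.8,
                      center_value_tolerance = 0.1,
                      center_offset_frac = 0.25,
                      min_limit_center_distance = 1.5) {
  rules <- list(
    min_minima_separation = min_minima_separation,
    max_bump_depth_ratio = max_bump_depth_ratio,
    max_limit_distance_difference = max_limit_distance_difference,
    max_limit_distance_frac = max_limit_distance_frac,
    center_value_tolerance = center_value_tolerance,
    center_offset_frac = center_offset_frac,
    min_limit_center_distance = min_limit_center_distance
  )
  if (any(vapply(rules, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    abort("All CLR rule thresholds must be strictly positive numbers.",
          class = "vc_error_input")
  }
  structure(rules, class = "vc_clr_rules")
}

#' Interior local extrema of a 1D profile
#'
#' Detects interior local minima and maxima by sign changes of the first
#' difference. A plateau (run of equal values) flanked by opposite slopes is
#' reported at its midpoint, which may be half-integer.
#'
#' @param profile Numeric vector of at least 3 samples.
#' @return List with tibbles `minima` and `maxima`, each with 0-based
#'   `position` and `value` columns, ordered by position.
#' @export
find_extrema <- function(profile) {
  v <- as.numeric(profile)
  if (length(v) < 3) abort("`profile` needs at least 3 samples.",
                           class = "vc_error_input")
  d <- diff(v)
  r <- rle(sign(d))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mins <- numeric(0); maxs <- numeric(0)
  nz <- which(r$values != 0)
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      s1 <- r$values[i]; s2 <- r$values[j]
      if (s1 == s2) next
      pos <- if (j == i + 1L) {
        ends[i]                                   # 0-based vertex position
      } else {
        (ends[i] + starts[j] - 1L) / 2            # 0-based plateau midpoint
      }
      if (s1 < 0 && s2 > 0) mins <- c(mins, pos) else maxs <- c(maxs, pos)
    }
  }
  val_at <- function(p) v[floor(p) + 1L]
  list(
    minima = tibble::tibble(position = mins, value = vapply(mins, val_at, numeric(1))),
    maxima = tibble::tibble(position = maxs, value = vapply(maxs, val_at, numeric(1)))
  )
}

#' Determine the vessel extent of one cross-section profile
#'
#' Applies the two-stage peak-search of the method to a (smoothed mean)
#' cross-section profile. A central-light-reflex (CLR) region - a central
#' maximum flanked by a minimum and a maximum on each side - is searched
#' first under a set of validity rules; if none is accepted, a plain vessel
#' region (central minimum with two adjacent maxima) is searched. In both
#' branches the profile length is twice the mean of the two center-to-limit
#' distances. If neither search succeeds the full current profile span is
#' returned as a fallback.
#'
#' @param profile Numeric profile vector (odd length; the profile center is
#'   at sample `(length - 1) / 2`).
#' @param rules `vc_clr_rules` thresholds from [clr_rules()].
#' @param initial_half_len Reference half-length for the "too far" rule;
#'   defaults to the profile's own half-span.
#' @return One-row tibble with `is_clr`, `x_maxL`, `x_center`, `x_maxR`,
#'   `prof_length` and `fallback` (positions are 0-based sample indices).
#' @export
determine_limits <- function(profile, rules = clr_rules(),
                             initial_half_len = NULL) {
  v <- as.numeric(profile)
  n <- length(v)
  ctr <- (n - 1) / 2
  half0 <- initial_half_len %||% ctr
  rng <- max(v) - min(v)

  fallback <- tibble::tibble(
    is_clr = FALSE, x_maxL = 0, x_center = ctr, x_maxR = n - 1,
    prof_length = n - 1, fallback = TRUE
  )
  if (n < 3 || rng == 0) return(fallback)

  ex <- find_extrema(v)
  mx <- ex$maxima; mn <- ex$minima

  result <- function(is_clr, xl, xc, xr) {
    tibble::tibble(
      is_clr = is_clr, x_maxL = xl, x_center = xc, x_maxR = xr,
      prof_length = 2 * mean(c(xc - xl, xr - xc)), fallback = FALSE
    )
  }

  # ---- CLR branch -----------------------------------------------------------
  clr <- NULL
  if (nrow(mx) >= 1 && nrow(mn) >= 2) {
    lowest <- mx$position[which.min(mx$value)]
    lowest_val <- min(mx$value)
    closest <- mx$position[which.min(abs(mx$position - ctr))]
    closest_val <- mx$value[which.min(abs(mx$position - ctr))]
    x_c <- lowest
    if (abs(closest - ctr) <= rules$center_offset_frac * (n - 1) &&
        closest_val - lowest_val <= rules$center_value_tolerance * rng) {
      x_c <- closest
    }
    v_c <- mx$value[mx$position == x_c][1]

    minL <- mn[mn$position < x_c, ]
    minR <- mn[mn$position > x_c, ]
    if (nrow(minL) && nrow(minR)) {
      minL <- minL[nrow(minL), ]          # nearest on the left
      minR <- minR[1, ]                   # nearest on the right
      maxL <- mx[mx$position < minL$position, ]
      maxR <- mx[mx$position > minR$position, ]
      if (nrow(maxL) && nrow(maxR)) {
        maxL <- maxL[nrow(maxL), ]
        maxR <- maxR[1, ]
        ok <- TRUE
        # rule: the two minima must not be too close
        if (minR$position - minL$position < rules$min_minima_separation) ok <- FALSE
        # rule: the two bump depths must not differ too much
        if (ok) {
          dpL <- maxL$value - minL$value
          dpR <- maxR$value - minR$value
          if (dpL <= 0 || dpR <= 0 ||
              abs(dpL - dpR) / max(dpL, dpR) > rules$max_bump_depth_ratio) {
            ok <- FALSE
          }
        }
        # rule: center-to-limit distances must be similar
        dL <- x_c - maxL$position
        dR <- maxR$position - x_c
        if (ok && abs(dL - dR) / max(dL, dR) > rules$max_limit_distance_difference) {
          ok <- FALSE
        }
        # rule: limits must not be too far from the center; one far side is
        # replicated symmetrically from the other
        if (ok) {
          too_far <- c(dL, dR) > rules$max_limit_distance_frac * half0
          if (all(too_far)) {
            ok <- FALSE
          } else if (too_far[1]) {
            maxL$position <- x_c - dR; maxL$value <- maxR$value; dL <- dR
          } else if (too_far[2]) {
            maxR$position <- x_c + dL; maxR$value <- maxL$value; dR <- dL
          }
        }
        # rule: the CLR elevation must not surpass the vessel limits
        if (ok && v_c > min(maxL$value, maxR$value)) ok <- FALSE
        # the region must contain the profile center
        if (ok && !(maxL$position < ctr && ctr < maxR$position)) ok <- FALSE
        if (ok) clr <- result(TRUE, maxL$position, x_c, maxR$position)
      }
    }
  }
  if (!is.null(clr)) return(clr)

  # ---- non-CLR branch -------------------------------------------------------
  if (nrow(mn) >= 1) {
    x_min <- mn$position[which.min(abs(mn$position - ctr))]
    left_all <- mx[mx$position < x_min, ]
    right_all <- mx[mx$position > x_min, ]
    pL <- if (nrow(left_all)) left_all$position[nrow(left_all)] else NA_real_
    pR <- if (nrow(right_all)) right_all$position[1] else NA_real_
    # a side without a maximum is replicated from the other side
    if (is.na(pL) && is.na(pR)) return(fallback)
    if (is.na(pL)) pL <- x_min - (pR - x_min)
    if (is.na(pR)) pR <- x_min + (x_min - pL)
    dL <- x_min - pL
    dR <- pR - x_min
    mind <- rules$min_limit_center_distance
    if (dL < mind && dR < mind) {
      # both too close: search outward for the first suitable maxima
      candL <- left_all$position[x_min - left_all$position >= mind]
      candR <- right_all$position[right_all$position - x_min >= mind]
      pL <- if (length(candL)) candL[length(candL)] else NA_real_
      pR <- if (length(candR)) candR[1] else NA_real_
      if (is.na(pL) && is.na(pR)) return(fallback)
      if (is.na(pL)) pL <- x_min - (pR - x_min)
      if (is.na(pR)) pR <- x_min + (x_min - pL)
    } else if (dL < mind) {
      pL <- x_min - dR
    } else if (dR < mind) {
      pR <- x_min + dL
    }
    return(result(FALSE, pL, x_min, pR))
  }
  fallback
}
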