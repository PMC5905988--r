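#' Specification of one synthetic vessel
#'
#' Describes a synthetic retinal vessel to be rendered by
#' [render_vessel_image()]: a parametric centerline (straight line, sine wave
#' or circular arc), a tube diameter and the intensity parameters of its
#' cross-section. The cross-section emulates fundus appearance: a dark
#' Gaussian-family dip on a brighter background, an optional bright
#' central-light-reflex (CLR) ridge, and a faint bright rim just outside each
#' edge (the perivascular halo seen next to real vessels, which gives the
#' peak-search rules the background maxima they look for).
#'
#' @param shape `"line"`, `"sine"` or `"arc"`.
#' @param diameter Tube diameter in pixels (>= 3).
#' @param from,to Numeric `c(x, y)` endpoints of the centerline chord
#'   (0-based pixel coordinates). For `"arc"` they are the arc ends.
#' @param amplitude,period Sine shape parameters (pixels); the sine is bent
#'   perpendicular to the chord.
#' @param bulge Arc sagitta (pixels): perpendicular distance from the chord
#'   midpoint to the arc.
#' @param contrast Depth of the vessel dip on the `[0, 1]` intensity scale.
#' @param clr_depth Height of the CLR ridge (0 = no CLR).
#' @param clr_width_fraction CLR ridge width as a fraction (< 1) of the
#'   vessel width.
#' @param background Background intensity level in `(0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @return One-row tibble describing the vessel.
#' @export
vessel_spec <- function(shape = c("line", "sine", "arc"), diameter,
                        from, to, amplitude = 6, period = 60, bulge = 8,
                        contrast = 0.4, clr_depth = 0,
                        clr_width_fraction = 0.4, background = 0.8,
                        noise_sd = 0) {
  shape <- match.arg(shape)
  stopifnot(diameter >= 3, contrast > 0, contrast <= 1, clr_depth >= 0,
            clr_width_fraction > 0, clr_width_fraction < 1,
            background > 0, background <= 1, noise_sd >= 0)
  tibble::tibble(
    shape = shape, diameter = diameter,
    x0 = from[1], y0 = from[2], x1 = to[1], y1 = to[2],
    amplitude = amplitude, period = period, bulge = bulge,
    contrast = contrast, clr_depth = clr_depth,
    clr_width_fraction = clr_width_fraction,
    background = background, noise_sd = noise_sd
  )
}

# Dense centerline samples with analytic unit tangents for one spec row.
# Returns positions at ~`step` px arclength spacing.
curve_points <- function(spec, step = 0.25) {
  p0 <- c(spec$x0, spec$y0); p1 <- c(spec$x1, spec$y1)
  chord <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / chord                 # along-chord unit vector
  w <- c(-u[2], u[1])                    # perpendicular
  tt <- seq(0, 1, length.out = max(2, ceiling(4 * chord / step)))
  s <- tt * chord
  if (spec$shape == "line") {
    px <- p0[1] + s * u[1]; py <- p0[2] + s * u[2]
    dxs <- rep(u[1], length(s)); dys <- rep(u[2], length(s))
  } else if (spec$shape == "sine") {
    off <- spec$amplitude * sin(2 * pi * s / spec$period)
    doff <- spec$amplitude * (2 * pi / spec$period) * cos(2 * pi * s / spec$period)
    px <- p0[1] + s * u[1] + off * w[1]
    py <- p0[2] + s * u[2] + off * w[2]
    dxs <- u[1] + doff * w[1]; dys <- u[2] + doff * w[2]
  } else {                               # arc through the two ends with sagitta
    h <- spec$bulge
    r <- (chord^2 / 4 + h^2) / (2 * h)
    mid <- (p0 + p1) / 2
    cen <- mid + (h - r) * w
    a0 <- atan2(p0[2] - cen[2], p0[1] - cen[1])
    a1 <- atan2(p1[2] - cen[2], p1[1] - cen[1])
    da <- a1 - a0
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    ang <- a0 + tt * da
    px <- cen[1] + r * cos(ang); py <- cen[2] + r * sin(ang)
    dxs <- -sin(ang) * sign(da); dys <- cos(ang) * sign(da)
  }
  nrm <- sqrt(dxs^2 + dys^2)
  tibble::tibble(x = px, y = py, tan_x = dxs / nrm, tan_y = dys / nrm,
                 nrm_x = -dys / nrm, nrm_y = dxs / nrm)
}

# Cross-section intensity increment at unsigned distance d from the
# centerline, relative to the background. Shapes follow the
# Difference-of-Gaussians family of the profile models (printed exponent
# convention); the rim term is a small bright bump centered on each edge.
RIM_HEIGHT_FRAC <- 0.35
RIM_SIGMA <- 0.8

vessel_cross_section <- function(d, diameter, contrast, clr_depth,
                                 clr_width_fraction) {
  g <- function(u, s) exp(-(u / (2 * s))^2)
  sigma_v <- diameter / 4
  sigma_c <- clr_width_fraction * diameter / 4
  -contrast * g(d, sigma_v) +
    clr_depth * g(d, sigma_c) +
    RIM_HEIGHT_FRAC * contrast * g(abs(d) - diameter / 2, RIM_SIGMA)
}

#' Render a synthetic fundus image with ground truth
#'
#' Draws the vessels of `specs` onto a flat background: for every pixel the
#' distance `d` to each centerline is computed and the intensity follows the
#' vessel cross-section (dark Gaussian-family dip of half-width
#' `diameter / 2`, optional CLR ridge, faint edge rim). Zero-mean Gaussian
#' noise is added to the green channel, the binary mask contains every pixel
#' within `diameter / 2` of a centerline, and exact ground-truth edge points
#' at `center +/- (diameter / 2) * normal` are emitted per centerline point.
#' Identical specs, shape and seed give bit-identical output.
#'
#' @param specs Tibble of [vessel_spec()] rows (all sharing `background` and
#'   `noise_sd`).
#' @param shape Integer `c(n_rows, n_cols)` image size.
#' @param seed RNG seed for the pixel noise.
#' @return List of class `vc_synthetic` with `image` (rows x cols x 3 RGB
#'   array; only green carries signal), `green`, `mask`, `gt_profiles`
#'   (annotation tibble: `segment_id`, `point_index`, center and edge
#'   coordinates, `width`), `specs`, and an `overlapping` flag.
#' @export
render_vessel_image <- function(specs, shape = c(100, 100), seed = 1) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1, length(shape) == 2)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (length(unique(specs$background)) > 1 ||
      length(unique(specs$noise_sd)) > 1) {
    abort("All specs must share background and noise_sd.",
          class = "vc_error_input")
  }
  green <- matrix(specs$background[1], nr, nc)
  mask <- matrix(FALSE, nr, nc)
  overlap <- FALSE
  gt <- list()

  px_x <- rep(seq_len(nc) - 1, each = nr)   # column-major pixel coordinates
  px_y <- rep(seq_len(nr) - 1, times = nc)

  for (si in seq_len(nrow(specs))) {
    sp <- specs[si, ]
    cp <- curve_points(sp)
    margin <- sp$diameter / 2
    if (any(cp$x < margin) || any(cp$x > nc - 1 - margin) ||
        any(cp$y < margin) || any(cp$y > nr - 1 - margin)) {
      abort(sprintf("Vessel %d leaves the image bounds.", si),
            class = "vc_error_input")
    }
    reach <- margin + 4 * RIM_SIGMA + 2
    inbox <- px_x >= min(cp$x) - reach & px_x <= max(cp$x) + reach &
      px_y >= min(cp$y) - reach & px_y <= max(cp$y) + reach
    idx <- which(inbox)
    if (length(idx)) {
      d2 <- rep(Inf, length(idx))
      for (k in seq_len(nrow(cp))) {      # nearest distance to the dense curve
        d2 <- pmin(d2, (px_x[idx] - cp$x[k])^2 + (px_y[idx] - cp$y[k])^2)
      }
      d <- sqrt(d2)
      green[idx] <- green[idx] +
        vessel_cross_section(d, sp$diameter, sp$contrast, sp$clr_depth,
                             sp$clr_width_fraction)
      inmask <- idx[d <= margin]
      if (any(mask[inmask])) overlap <- TRUE
      mask[inmask] <- TRUE
    }
    # ground truth at ~1 px arclength spacing
    arc <- c(0, cumsum(sqrt(diff(cp$x)^2 + diff(cp$y)^2)))
    keep <- vapply(seq(0, max(arc), by = 1),
                   function(s) which.min(abs(arc - s)), integer(1))
    keep <- unique(keep)
    gt[[si]] <- tibble::tibble(
      segment_id = si,
      point_index = seq_along(keep) - 1L,
      center_x = cp$x[keep], center_y = cp$y[keep],
      edge1_x = cp$x[keep] + margin * cp$nrm_x[keep],
      edge1_y = cp$y[keep] + margin * cp$nrm_y[keep],
      edge2_x = cp$x[keep] - margin * cp$nrm_x[keep],
      edge2_y = cp$y[keep] - margin * cp$nrm_y[keep],
      width = sp$diameter
    )
  }
  if (overlap) warn("Rendered vessels overlap.")
  if (specs$noise_sd[1] > 0) {
    green <- green + with_seed(seed, matrix(rnorm(nr * nc, 0, specs$noise_sd[1]), nr, nc))
  }
  green <- pmin(pmax(green, 0), 1)
  rgb <- array(0, dim = c(nr, nc, 3))
  rgb[, , 1] <- 0.5 * green
  rgb[, , 2] <- green
  rgb[, , 3] <- 0.3 * green
  structure(
    list(image = rgb, green = green, mask = mask,
         gt_profiles = dplyr::bind_rows(gt), specs = specs,
         overlapping = overlap),
    class = "vc_synthetic"
  )
}

#' @export
print.vc_synthetic <- function(x, ...) {
  cat(sprintf("<vc_synthetic> %dx%d image, %d vessel(s), %d ground-truth profiles\n",
              nrow(x$green), ncol(x$green), nrow(x$specs), nrow(x$gt_profiles)))
  invisible(x)
}

# Numeric vessel width of a noiseless model curve: distance between the two
# edge positions. An edge is the flanking local maximum on that side of the
# central dip when one exists; otherwise (the model tails are monotone) the
# extreme-gradient point on that side.
width_from_curve <- function(f, lo, hi, step = 0.01) {
  xs <- seq(lo, hi, by = step)
  v <- f(xs)
  ctr_idx <- which.min(v)
  dv <- diff(v)
  locmax <- which(dv[-length(dv)] > 0 & dv[-1] <= 0) + 1L
  edge <- function(side) {
    cand <- if (side < 0) locmax[locmax < ctr_idx] else locmax[locmax > ctr_idx]
    if (length(cand)) {
      # nearest flanking maximum
      if (side < 0) xs[cand[length(cand)]] else xs[cand[1]]
    } else {
      half <- if (side < 0) seq_len(ctr_idx - 1) else ctr_idx:(length(xs) - 1)
      xs[half[which.max(abs(dv[half]))] + ifelse(side < 0, 0, 1)]
    }
  }
  edge(1) - edge(-1)
}

#' Synthetic width-estimation study
#'
#' Renders a population of synthetic vessels (one per image; straight, sine
#' and arc centerlines in rotation, diameters drawn uniformly, a
#' central-light-reflex ridge on every other vessel of 10 px or more - CLR
#' being a large-vessel feature), measures each image with the full pipeline
#' and assembles the matched training records for width regression. This is
#' the package's reference study for end-to-end width-recovery evaluation.
#'
#' @param n_vessels Number of vessels/images (default 30).
#' @param diameters Numeric range the diameters are drawn from (default
#'   `c(4, 20)` px).
#' @param noise_sd Pixel noise sd on the `[0, 1]` intensity scale (default
#'   0.02).
#' @param seed Master seed (vessel draws and per-image noise).
#' @param config A [vc_config()]; the model set here is the one fitted.
#' @return Tibble of training records (model parameters, `width_gt`,
#'   globally unique `segment_id`, `profile_id`) with attributes
#'   `n_gt_total` (ground-truth profile count across images) and
#'   `n_matched`.
#' @export
synthetic_study_records <- function(n_vessels = 30, diameters = c(4, 20),
                                    noise_sd = 0.02, seed = 1,
                                    config = vc_config(verbose = FALSE)) {
  stopifnot(n_vessels >= 1)
  draws <- with_seed(seed, tibble::tibble(
    diameter = runif(n_vessels, diameters[1], diameters[2]),
    shape = rep_len(c("line", "sine", "arc"), n_vessels),
    angle = runif(n_vessels, 0, pi),
    contrast = runif(n_vessels, 0.35, 0.5)
  ))
  draws$clr_depth <- ifelse(draws$diameter >= 10 &
                              (seq_len(n_vessels) %% 2 == 0),
                            0.4 * draws$contrast, 0)
  shape_px <- c(90, 110)
  ctr <- c((shape_px[2] - 1) / 2, (shape_px[1] - 1) / 2)   # (x, y)
  half_span <- 34
  records <- list()
  n_gt_total <- 0L
  pn <- model_param_names(config$model)
  for (i in seq_len(n_vessels)) {
    dirv <- c(cos(draws$angle[i]), sin(draws$angle[i]))
    sp <- vessel_spec(
      draws$shape[i], diameter = draws$diameter[i],
      from = ctr - half_span * dirv, to = ctr + half_span * dirv,
      amplitude = 4, period = 60, bulge = 6,
      contrast = draws$contrast[i], clr_depth = draws$clr_depth[i],
      noise_sd = noise_sd
    )
    ds <- render_vessel_image(sp, shape = shape_px, seed = seed + i)
    meas <- measure_segments(ds$green, ds$mask, config)
    n_gt_total <- n_gt_total + nrow(ds$gt_profiles)
    if (!nrow(meas)) next
    mt <- match_centers(
      data.frame(x = ds$gt_profiles$center_x, y = ds$gt_profiles$center_y),
      data.frame(x = meas$center_x, y = meas$center_y)
    )
    if (!nrow(mt$pairs)) next
    records[[length(records) + 1L]] <- dplyr::bind_cols(
      meas[mt$pairs$det_index, pn],
      tibble::tibble(
        segment_id = i,
        width_gt = ds$gt_profiles$width[mt$pairs$gt_index],
        profile_id = paste0(i, "_", mt$pairs$det_index)
      )
    )
  }
  out <- dplyr::bind_rows(records)
  attr(out, "n_gt_total") <- n_gt_total
  attr(out, "n_matched") <- nrow(out)
  out
}

#' Generate model-based profile sets with known ground truth
#'
#' Draws parameter vectors for one of the profile models, evaluates the
#' noiseless curves on an integer sample grid and adds Gaussian noise,
#' providing exact ground truth for fitting-recovery and regression tests.
#' The default sampler draws realistic vessel-profile parameters (dark dip
#' near the profile center, optional CLR, small slope), all inside the
#' default fitting bounds for the profile length.
#'
#' @param model_id One of [model_ids()].
#' @param n Number of profiles.
#' @param len Number of samples per profile (odd; default 21).
#' @param noise_sd Additive Gaussian noise sd on the intensity scale.
#' @param seed RNG seed.
#' @param sampler Optional function `function(n, len)` returning a tibble of
#'   `n` parameter draws.
#' @param clr Should the default sampler include a CLR ridge (default TRUE)?
#' @param within_default_bounds Keep only draws that lie inside the default
#'   fitting bounds of their own noiseless profile (rejection sampling,
#'   default `TRUE`): the bounds are data-driven, so for strong CLR a drawn
#'   `h2` can fall outside the box the fit is allowed to search.
#' @return List with `profiles` (n x len matrix), `params` (tibble of true
#'   parameters), `widths` (numeric; distance between the curve's edge
#'   positions, computed numerically) and `xs` (0-based sample positions).
#' @export
generate_profile_set <- function(model_id, n, len = 21, noise_sd = 0,
                                 seed = 1, sampler = NULL, clr = TRUE,
                                 within_default_bounds = TRUE) {
  model_id <- match.arg(model_id, model_ids())
  L <- len - 1
  ctr <- L / 2
  sampler <- sampler %||% function(n, len) {
    t <- runif(n, 0.6, 0.9)
    h1 <- runif(n, -0.55, -0.35)
    mu <- runif(n, ctr - 2, ctr + 2)
    sigma1 <- runif(n, L / 8, L / 5.5)
    h2 <- if (clr) runif(n, -0.3, -0.15) else runif(n, -0.02, 0.02)
    sigma2 <- runif(n, 0.8, 1.6)
    lambda <- runif(n, -0.02, 0.02)
    switch(model_id,
      dogl7 = tibble::tibble(t, h1, mu, sigma1, h2, sigma2, lambda),
      dogl8 = tibble::tibble(t, h1, mu1 = mu, sigma1, h2,
                             mu2 = mu + runif(n, -1, 1), sigma2, lambda),
      hermite = tibble::tibble(t, h = h1, beta = runif(n, 0, 0.4), mu,
                               delta = runif(n, -1, 1),
                               sigma = sigma1)
    )
  }
  xs <- seq_len(len) - 1
  drawn <- with_seed(seed, {
    kept <- list()
    guard <- 0
    while (length(kept) < n && guard < 100 * n) {
      guard <- guard + 1
      par_row <- sampler(1, len)
      p <- unlist(par_row)
      prof <- evaluate_model(model_id, p, xs)
      if (within_default_bounds) {
        bi <- default_bounds_and_init(model_id, prof)
        pn <- names(bi$lower)
        if (!all(p[pn] >= bi$lower & p[pn] <= bi$upper)) next
      }
      kept[[length(kept) + 1L]] <- list(params = par_row, profile = prof)
    }
    if (length(kept) < n) {
      abort("Parameter sampler rejected too many draws.", class = "vc_error_input")
    }
    kept
  })
  params <- dplyr::bind_rows(lapply(drawn, `[[`, "params"))
  profiles <- do.call(rbind, lapply(drawn, `[[`, "profile"))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    p <- unlist(params[i, ])
    widths[i] <- width_from_curve(
      function(x) evaluate_model(model_id, p, x), 0, L
    )
  }
  if (noise_sd > 0) {
    profiles <- profiles +
      with_seed(seed + 1L, matrix(rnorm(n * len, 0, noise_sd), n, len))
  }
  list(profiles = profiles, params = params, widths = widths, xs = xs)
}
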