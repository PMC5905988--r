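MODEL_PARAMS <- list(
  hermite = c("t", "h", "beta", "mu", "delta", "sigma"),
  dogl7 = c("t", "h1", "mu", "sigma1", "h2", "sigma2", "lambda"),
  dogl8 = c("t", "h1", "mu1", "sigma1", "h2", "mu2", "sigma2", "lambda")
)

#' Profile model identifiers
#'
#' @return Character vector of the supported cross-section profile models:
#'   `"hermite"` (adapted Hermite, 6 parameters), `"dogl7"`
#'   (Difference-of-Gaussians times line, 7 parameters) and `"dogl8"` (as
#'   `dogl7` but with an independent center for the CLR Gaussian, 8
#'   parameters).
#' @export
model_ids <- function() names(MODEL_PARAMS)

#' Parameter names of a profile model
#'
#' @param model_id One of [model_ids()].
#' @return Character vector of parameter names, in canonical order.
#' @export
model_param_names <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  MODEL_PARAMS[[model_id]]
}

# The Gaussian-shaped factor of the profile models. The default follows the
# models' printed form exp(-((x - mu) / (2 sigma))^2); standard = TRUE
# switches to the conventional density kernel exp(-(x - mu)^2 / (2 sigma^2)).
model_gaussian <- function(x, mu, sigma, standard = FALSE) {
  if (standard) exp(-((x - mu)^2) / (2 * sigma^2))
  else exp(-((x - mu) / (2 * sigma))^2)
}

#' Evaluate a cross-section profile model
#'
#' Computes the model intensity at positions `xs` (pixels along the
#' cross-section). The models are extrusions along the vessel direction, so a
#' single coordinate suffices.
#'
#' The adapted Hermite model is
#' `t + h (1 + beta((x - mu - delta)^2 - 1)) (2 pi sigma^2)^(-1/2) G(x)`,
#' the DoG-L7 model is
#' `(t + h1 G1(x) - h2 G2(x)) (lambda (x - mu) + t)` with both Gaussians
#' centered at `mu`, and DoG-L8 gives the second (central-light-reflex)
#' Gaussian its own center `mu2`. All Gaussian factors use the exponent
#' `exp(-((x - mu) / (2 sigma))^2)` unless `standard_gaussian = TRUE`.
#'
#' @param model_id One of [model_ids()].
#' @param params Named numeric vector (or list) with the model's parameters;
#'   see [model_param_names()]. Spreads must be positive.
#' @param xs Numeric vector of evaluation positions (pixels).
#' @param standard_gaussian Use the conventional Gaussian exponent instead of
#'   the model's printed form (default `FALSE`).
#' @return Numeric vector of model values at `xs`.
#' @examples
#' evaluate_model("dogl7",
#'   c(t = 0.5, h1 = -0.5, mu = 10, sigma1 = 3, h2 = -0.33, sigma2 = 1,
#'     lambda = 0.02), xs = 10)
#' @export
evaluate_model <- function(model_id, params, xs, standard_gaussian = FALSE) {
  model_id <- match.arg(model_id, model_ids())
  p <- as.list(params)
  need <- MODEL_PARAMS[[model_id]]
  if (!all(need %in% names(p))) {
    abort(sprintf("Missing parameters: %s",
                  paste(setdiff(need, names(p)), collapse = ", ")),
          class = "vc_error_params")
  }
  sig <- unlist(p[grep("^sigma", need, value = TRUE)])
  if (any(sig <= 0)) abort("Gaussian spreads must be positive.",
                           class = "vc_error_params")
  g <- function(mu, s) model_gaussian(xs, mu, s, standard_gaussian)
  switch(model_id,
    hermite = {
      pref <- 1 / sqrt(2 * pi * p$sigma^2)
      p$t + p$h * (1 + p$beta * ((xs - p$mu - p$delta)^2 - 1)) * pref *
        g(p$mu, p$sigma)
    },
    dogl7 = {
      (p$t + p$h1 * g(p$mu, p$sigma1) - p$h2 * g(p$mu, p$sigma2)) *
        (p$lambda * (xs - p$mu) + p$t)
    },
    dogl8 = {
      (p$t + p$h1 * g(p$mu1, p$sigma1) - p$h2 * g(p$mu2, p$sigma2)) *
        (p$lambda * (xs - p$mu1) + p$t)
    }
  )
}

# Term-by-term expansion of the adapted Hermite model: main Gaussian, minus
# the CLR Gaussian, plus a parabola-modulated Gaussian. Used as an algebraic
# cross-check of evaluate_model().
hermite_expanded <- function(params, xs, standard_gaussian = FALSE) {
  p <- as.list(params)
  pref <- 1 / sqrt(2 * pi * p$sigma^2)
  gg <- model_gaussian(xs, p$mu, p$sigma, standard_gaussian)
  p$t + p$h * pref * gg - p$h * p$beta * pref * gg +
    p$h * p$beta * (xs - p$mu - p$delta)^2 * pref * gg
}

#' Default parameter bounds and initialization for model fitting
#'
#' Derives box bounds and a starting point for the bounded least-squares fit
#' from the profile itself (its dynamic range, length and dip location),
#' following the common appearance of vessel cross-sections. For the DoG
#' models the multiplying line makes the background level of the curve
#' `t^2`, so `t` starts at the square root of the larger end sample and the
#' dip height at `-range / t`; the center starts at the intensity-weighted
#' centroid of the dip (robust to the central-light-reflex splitting the
#' minimum into two flank dips); the CLR Gaussian starts switched off and
#' the line slope at zero. The Hermite dip height is scaled by its
#' `(2 pi sigma^2)^(-1/2)` prefactor.
#'
#' @param model_id One of [model_ids()].
#' @param profile Numeric profile vector (a `vc_profile` tibble is also
#'   accepted).
#' @return List with named numeric vectors `lower`, `init`, `upper`
#'   (componentwise `lower <= init <= upper`).
#' @export
default_bounds_and_init <- function(model_id, profile) {
  model_id <- match.arg(model_id, model_ids())
  v <- if (is.data.frame(profile)) profile$value else as.numeric(profile)
  n <- length(v)
  if (n < 3) abort("`profile` too short.", class = "vc_error_input")
  rng <- max(v) - min(v)
  if (rng == 0) abort("Profile has zero dynamic range; cannot set bounds.",
                      class = "vc_error_degenerate")
  L <- n - 1                      # profile span, px
  ctr <- L / 2
  xs <- seq_len(n) - 1
  wts <- max(v) - v               # dip-weighted centroid of the cross-section
  mu0 <- sum(xs * wts) / sum(wts)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  t0 <- sqrt(max(v[1], v[n]))     # DoG background level is t^2
  sigma1_init <- max(0.5, L / 6)

  base <- list(
    t = c(0, clamp(t0, 0, 2 * max(v)), 2 * max(v)),
    h1 = c(-2 * rng, clamp(-rng / max(t0, 0.1), -2 * rng, 0), 0),
    mu = c(ctr - L / 4, clamp(mu0, ctr - L / 4, ctr + L / 4), ctr + L / 4),
    sigma1 = c(0.5, sigma1_init, L / 2),
    h2 = c(-rng, 0, rng),
    sigma2 = c(0.5, max(0.5, L / 12), L / 2),
    lambda = c(-0.1, 0, 0.1)
  )
  tab <- switch(model_id,
    dogl7 = base[c("t", "h1", "mu", "sigma1", "h2", "sigma2", "lambda")],
    dogl8 = {
      b <- base
      b$mu1 <- b$mu
      b$mu2 <- c(ctr - L / 8, clamp(b$mu[2], ctr - L / 8, ctr + L / 8), ctr + L / 8)
      b[c("t", "h1", "mu1", "sigma1", "h2", "mu2", "sigma2", "lambda")]
    },
    hermite = {
      b <- base
      # the Hermite Gaussian carries a 1/sqrt(2 pi sigma^2) prefactor, so the
      # dip height lives on a sigma-dependent scale
      pref_max <- sqrt(2 * pi * (L / 2)^2)
      b$t <- c(0, max(v[1], v[n]), 2 * max(v))   # no line factor: background = t
      b$h <- c(-2 * rng * pref_max,
               -rng * sqrt(2 * pi * sigma1_init^2), 0)
      b$beta <- c(-2, 0, 2)
      b$delta <- c(-L / 8, 0, L / 8)
      b$sigma <- b$sigma1
      b[c("t", "h", "beta", "mu", "delta", "sigma")]
    }
  )
  nm <- names(tab)
  list(
    lower = stats::setNames(vapply(tab, `[`, numeric(1), 1), nm),
    init = stats::setNames(vapply(tab, `[`, numeric(1), 2), nm),
    upper = stats::setNames(vapply(tab, `[`, numeric(1), 3), nm)
  )
}

#' Goodness-of-fit metrics
#'
#' Residual-based fit metrics: the sum of squared errors
#' `SSE = sum((y - yhat)^2)`, the coefficient of determination
#' `R^2 = 1 - SSE / SST` (computed from the residuals, since the
#' decomposition `SST = SSR + SSE` does not hold for nonlinear fits), the
#' degrees-of-freedom adjusted `R^2 = 1 - SSE (n - 1) / (SST v)` and the fit
#' standard error `RMSE = sqrt(SSE / v)`, with `v = n - m` residual degrees
#' of freedom.
#'
#' @param y_obs,y_pred Observed and fitted values (equal length `n`).
#' @param m Number of fitted coefficients; `n - m` must be positive.
#' @return One-row tibble with `sse`, `r2`, `r2_adj`, `rmse`, `n`, `m`, `v`.
#' @export
goodness_of_fit <- function(y_obs, y_pred, m) {
  y <- as.numeric(y_obs); yh <- as.numeric(y_pred)
  if (length(y) != length(yh)) abort("`y_obs` and `y_pred` lengths differ.",
                                     class = "vc_error_input")
  n <- length(y)
  v <- n - m
  if (v <= 0) abort("Residual degrees of freedom must be positive.",
                    class = "vc_error_input")
  sse <- sum((y - yh)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("Zero total sum of squares; R-squared undefined.",
                      class = "vc_error_degenerate")
  tibble::tibble(
    sse = sse,
    r2 = 1 - sse / sst,
    r2_adj = 1 - sse * (n - 1) / (sst * v),
    rmse = sqrt(sse / v),
    n = n, m = m, v = v
  )
}

#' Fit a profile model to a stack of neighboring profiles
#'
#' Pools the samples of up to 11 neighboring cross-section profiles into one
#' plane (the models are extrusions along the vessel, so pooling is
#' equivalent to fitting the 2D surface) and solves the bounded nonlinear
#' least-squares problem for the model parameters, minimizing the sum of
#' squared differences with a bounded Levenberg-Marquardt trust-region
#' solver.
#'
#' @param stack Numeric matrix (one profile per row), a single numeric
#'   profile vector, or a list of equal-length profile vectors.
#' @param model_id One of [model_ids()].
#' When no explicit start is given the solver is restarted from a small set
#' of default starting points (the CLR Gaussian switched off, bright, and
#' dark) and the solution with the lowest SSE is kept; the dip-swap local
#' minima of the DoG models make a single start unreliable.
#'
#' @param bounds Optional list with `lower` and `upper` named vectors;
#'   defaults to [default_bounds_and_init()] on the mean profile of the
#'   stack.
#' @param init Optional named start vector (disables the multi-start);
#'   defaults likewise.
#' @param standard_gaussian Passed to [evaluate_model()].
#' @param max_iter,ftol Solver control (defaults 400 iterations, 1e-10
#'   function tolerance).
#' @return Object of class `vc_fit`: a list with `model_id`, `params` (named
#'   vector), `gof` (one-row tibble from [goodness_of_fit()]), `converged`,
#'   `n_points`, `message` and a `data` tibble of the pooled points with
#'   fitted values. Solver failure is reported via `converged = FALSE`, not
#'   an error.
#' @export
fit_profile_stack <- function(stack, model_id, bounds = NULL, init = NULL,
                              standard_gaussian = FALSE,
                              max_iter = 400, ftol = 1e-10) {
  model_id <- match.arg(model_id, model_ids())
  if (is.list(stack) && !is.data.frame(stack)) stack <- do.call(rbind, stack)
  if (is.null(dim(stack))) stack <- matrix(as.numeric(stack), nrow = 1)
  len <- ncol(stack)
  xs <- rep(seq_len(len) - 1, each = nrow(stack))
  ys <- as.numeric(stack)               # column-major matches rep(each=)
  np <- length(MODEL_PARAMS[[model_id]])
  if (length(ys) <= np) {
    abort("Not enough pooled points for the model's parameter count.",
          class = "vc_error_input")
  }
  mean_prof <- colMeans(stack)
  bi <- default_bounds_and_init(model_id, mean_prof)
  pnames <- MODEL_PARAMS[[model_id]]
  lower <- (bounds$lower %||% bi$lower)[pnames]
  upper <- (bounds$upper %||% bi$upper)[pnames]
  if (!is.null(init) && is.null(bounds)) {
    # an explicit start is honored: widen the default box to contain it
    lower <- pmin(lower, init[pnames])
    upper <- pmax(upper, init[pnames])
  }
  clamp <- function(p) pmin(pmax(p, lower), upper)
  starts <- if (!is.null(init)) {
    list(clamp(init[pnames]))
  } else {
    s0 <- clamp(bi$init)
    extra <- list()
    h2name <- if ("h2" %in% pnames) "h2" else NULL
    if (!is.null(h2name)) {
      rng <- max(mean_prof) - min(mean_prof)
      sC <- s0; sC[h2name] <- -rng / 2; extra <- c(extra, list(clamp(sC)))
      sD <- s0; sD[h2name] <- rng / 2; extra <- c(extra, list(clamp(sD)))
    } else if ("beta" %in% pnames) {
      sC <- s0; sC["beta"] <- 0.5; extra <- c(extra, list(clamp(sC)))
    }
    c(list(s0), extra)
  }

  resid_fn <- function(p) {
    ys - evaluate_model(model_id, p, xs, standard_gaussian)
  }
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      res <- list(params = start, converged = FALSE,
                  msg = conditionMessage(fit),
                  sse = sum(resid_fn(start)^2))
    } else {
      pp <- stats::setNames(as.numeric(fit$par), pnames)
      res <- list(params = pp, converged = fit$info %in% 1:4,
                  msg = fit$message, sse = fit$deviance)
    }
    if (is.null(best) || res$sse < best$sse) best <- res
    if (best$sse < 1e-9) break
  }
  params <- best$params
  converged <- best$converged
  msg <- best$msg
  yhat <- evaluate_model(model_id, params, xs, standard_gaussian)
  gof <- goodness_of_fit(ys, yhat, np)
  structure(
    list(
      model_id = model_id,
      params = params,
      gof = gof,
      converged = converged,
      n_points = length(ys),
      message = msg,
      data = tibble::tibble(x = xs, y = ys, fitted = yhat)
    ),
    class = "vc_fit"
  )
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> %s model, %d pooled points, %s\n", x$model_id,
              x$n_points, if (x$converged) "converged" else "NOT converged"))
  print(round(x$params, 4))
  cat(sprintf("SSE %.4g  R2 %.4f  adjR2 %.4f  RMSE %.4g\n",
              x$gof$sse, x$gof$r2, x$gof$r2_adj, x$gof$rmse))
  invisible(x)
}
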