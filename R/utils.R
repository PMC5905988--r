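# Internal helpers shared across modules.

# Coerce a mask-like input to a logical matrix. Accepts logical matrices or
# numeric matrices whose values are all 0/1 (or in [0,1], thresholded at 0.5).
as_logical_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || length(dim(mask)) != 2) {
    abort(sprintf("`%s` must be a 2D matrix.", arg), class = "vc_error_input")
  }
  if (is.logical(mask)) {
    m <- mask
    m[is.na(m)] <- FALSE
    return(m)
  }
  if (is.numeric(mask)) {
    if (any(mask < 0 | mask > 1, na.rm = TRUE)) {
      abort(sprintf("`%s` must be logical or numeric in [0, 1].", arg),
            class = "vc_error_input")
    }
    m <- mask >= 0.5
    m[is.na(m)] <- FALSE
    return(m)
  }
  abort(sprintf("`%s` must be a logical or numeric matrix.", arg),
        class = "vc_error_input")
}

# Shift a logical matrix by (dr, dc), filling exposed border with FALSE.
shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

NEIGHBOR_OFFSETS <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# Count of true 8-neighbors for every pixel of a logical matrix.
count_neighbors8 <- function(m) {
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
    acc <- acc + shift_logical(m, NEIGHBOR_OFFSETS[k, 1], NEIGHBOR_OFFSETS[k, 2])
  }
  acc
}

# Bilinear interpolation on an image matrix at 0-based (x = col, y = row)
# coordinates. Out-of-image positions are clamped to the nearest edge value
# and flagged.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  outside <- x < 0 | x > nc - 1 | y < 0 | y > nr - 1
  xc <- pmin(pmax(x, 0), nc - 1)
  yc <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(xc), nc - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(yc), nr - 2); y0 <- pmax(y0, 0)
  fx <- xc - x0
  fy <- yc - y0
  # 1-based matrix indices
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
  list(values = as.numeric(v), outside = outside)
}

# Symmetric (edge-repeating) reflection indices for padding a length-n signal
# by r samples on each side; handles r >= n by repeated mirroring.
reflect_indices <- function(n, r) {
  if (n == 1) return(rep(1L, n + 2L * r))
  p <- (1 - r):(n + r) - 1L          # 0-based positions
  period <- 2L * n
  p <- ((p %% period) + period) %% period
  idx <- ifelse(p < n, p, period - 1L - p)
  as.integer(idx + 1L)
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Centered 1D convolution with symmetric boundary reflection.
conv1d_reflect <- function(v, kernel) {
  if (length(kernel) == 1) return(v)
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(v)
  ext <- v[reflect_indices(n, r)]
  out <- stats::filter(ext, kernel, method = "convolution", sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# Separable Gaussian blur of a matrix: sigma_col smooths along each row
# (across columns), sigma_row along each column (across rows).
blur_separable <- function(m, sigma_row, sigma_col) {
  kc <- gaussian_kernel(sigma_col)
  kr <- gaussian_kernel(sigma_row)
  if (length(kc) > 1) m <- t(apply(m, 1, conv1d_reflect, kernel = kc))
  if (length(kr) > 1 && nrow(m) > 1) m <- apply(m, 2, conv1d_reflect, kernel = kr)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

# Evaluate code with a temporary RNG state derived from `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
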