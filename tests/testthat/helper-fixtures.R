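# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk.

# Independent brute-force goodness-of-fit oracle (plain formula evaluation,
# no package code).
gof_oracle <- function(y, yh, m) {
  n <- length(y)
  sse <- sum((y - yh)^2)
  sst <- sum((y - mean(y))^2)
  v <- n - m
  list(sse = sse, r2 = 1 - sse / sst,
       r2_adj = 1 - sse * (n - 1) / (sst * v), rmse = sqrt(sse / v))
}

# Count 8-connected components of a logical matrix by flood fill
# (independent of the package's traversal code).
count_components8 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      r <- (i - 1L) %% nrow(m) + 1L; c <- (i - 1L) %/% nrow(m) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
        if (m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1L) * nrow(m) + rr)
        }
      }
    }
  }
  nxt
}

# Plus-shaped skeleton: two 11-pixel lines crossing at one pixel.
make_cross_skeleton <- function() {
  m <- matrix(FALSE, 15, 15)
  m[8, 3:13] <- TRUE
  m[3:13, 8] <- TRUE
  m
}

# T-shaped skeleton: an 11-pixel bar with a 5-pixel stem from its middle.
make_t_skeleton <- function() {
  m <- matrix(FALSE, 15, 15)
  m[4, 3:13] <- TRUE
  m[5:9, 8] <- TRUE
  m
}

# One straight synthetic vessel, horizontal, centered off-grid in y.
straight_vessel <- function(diameter, clr_depth = 0, noise_sd = 0,
                            seed = 1, shape = c(80, 100)) {
  sp <- vessel_spec("line", diameter = diameter,
                    from = c(16, 40), to = c(shape[2] - 17, 40),
                    clr_depth = clr_depth, noise_sd = noise_sd)
  render_vessel_image(sp, shape = shape, seed = seed)
}

# Noiseless cross-section profile of a rendered-style vessel, sampled
# directly from the synthetic cross-section model at 1 px spacing with the
# vessel center off-grid by `off`.
synthetic_cross_profile <- function(diameter, clr_depth = 0, off = 0,
                                    contrast = 0.4, clr_width_fraction = 0.4,
                                    background = 0.8, half = NULL) {
  half <- half %||% ceiling(1.5 * diameter)
  d <- abs(seq(-half, half) + off)
  background + vesselcaliber:::vessel_cross_section(
    d, diameter, contrast, clr_depth, clr_width_fraction)
}

# The reference synthetic width-estimation study is expensive; build it once
# per test session and reuse.
.study_cache <- new.env(parent = emptyenv())
get_study_records <- function() {
  if (is.null(.study_cache$records)) {
    .study_cache$records <- synthetic_study_records(
      n_vessels = 30, diameters = c(4, 20), noise_sd = 0.02, seed = 11,
      config = vc_config(verbose = FALSE)
    )
  }
  .study_cache$records
}
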