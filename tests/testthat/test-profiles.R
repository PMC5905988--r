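test_that("profile sampling interpolates bilinearly and flags edge fills", {
  img <- matrix(0.7, 20, 20)
  p <- sample_profile(img, point = c(10, 10), normal = c(0, 1), half_len = 5)
  expect_equal(nrow(p), 11)
  expect_true(all(p$value == 0.7))
  expect_false(any(p$outside))

  # bilinear at a node equals the pixel value; at the midpoint of a 2x2
  # block with rows (0,0) and (1,1) it is 0.5
  img2 <- rbind(c(0, 0), c(1, 1))
  s <- vesselcaliber:::bilinear_sample(img2, c(1, 0.5), c(0, 0.5))
  expect_equal(s$values[1], 0)
  expect_equal(s$values[2], 0.5)

  near_edge <- sample_profile(img, point = c(1, 1), normal = c(0, 1), half_len = 4)
  expect_true(any(near_edge$outside))
  expect_error(sample_profile(img, point = c(50, 2), normal = c(0, 1), half_len = 2),
               class = "vc_error_input")
})

test_that("initial half-length covers the widest vessel with margin", {
  disc <- function(r, nr = 40, nc = 40, cx = 20, cy = 20) {
    d <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
    d <= r
  }
  expect_gte(initial_half_length(disc(5)), 8)
  two <- disc(3) | disc(7, cx = 32, cy = 20)
  expect_gte(initial_half_length(two), 11)
  expect_error(initial_half_length(matrix(FALSE, 5, 5)), class = "vc_error_input")
})

test_that("the 11-row smoothed mean preserves low-order rows and averages out noise", {
  offs <- -10:10
  quad <- 0.5 + 0.002 * offs^2
  st <- matrix(rep(quad, each = 15), 15, length(offs))
  out <- smoothed_mean_profile(st, 8)
  expect_lt(max(abs(out - quad)), 1e-10)          # SG reproduces a quadratic

  ramp <- seq(0, 1, length.out = 21)
  st_r <- matrix(rep(ramp, each = 15), 15, 21)
  expect_lt(max(abs(smoothed_mean_profile(st_r, 8) - ramp)), 1e-10)

  set.seed(13)
  clean <- 0.8 - 0.4 * exp(-(offs / 4)^2)
  noisy <- t(sapply(1:15, function(i) clean + rnorm(21, 0, 0.05)))
  sm <- smoothed_mean_profile(noisy, 8)
  rms_sm <- sqrt(mean((sm - clean)^2))
  rms_single <- min(sapply(1:15, function(i) sqrt(mean((noisy[i, ] - clean)^2))))
  expect_lt(rms_sm, rms_single)
  expect_error(smoothed_mean_profile(noisy, 0), class = "vc_error_input")
})

test_that("interior extrema are located by sign change with plateau midpoints", {
  expect_equal(nrow(find_extrema(seq(0, 1, length.out = 10))$minima), 0)
  expect_equal(nrow(find_extrema(seq(0, 1, length.out = 10))$maxima), 0)

  v_shape <- c(7:0, 1:7)                    # vertex at index 7
  ex <- find_extrema(v_shape)
  expect_equal(ex$minima$position, 7)
  expect_equal(nrow(ex$maxima), 0)

  w <- c(3, 2, 1, 0, 1, 2, 2, 1, 0, 1, 2, 2, 1, 0, 1, 2, 3)
  exw <- find_extrema(w)
  expect_equal(exw$minima$position, c(3, 8, 13))
  expect_equal(exw$maxima$position, c(5.5, 10.5))
  expect_error(find_extrema(c(1, 2)), class = "vc_error_input")
})

test_that("segment profile length is the median with the even-count convention", {
  expect_equal(segment_profile_length(c(10, 12, 14)), 12)
  expect_equal(segment_profile_length(9), 9)
  expect_equal(segment_profile_length(c(10, 12, 14, 100)), 13)
  expect_equal(segment_profile_length(tibble::tibble(prof_length = c(4, 8))), 6)
  expect_error(segment_profile_length(numeric(0)), class = "vc_error_input")
})

test_that("profiles are cut symmetrically about the centerline", {
  st <- straighten_segment(matrix(runif(400), 20, 20),
                           fit_spline(tibble::tibble(x = 2:17, y = rep(10, 16))),
                           half_len = 20)
  expect_equal(ncol(st), 41)
  cut <- cut_profiles(st, 20)
  expect_equal(ncol(cut), 21)
  center_before <- st[, which(attr(st, "offsets") == 0)]
  center_after <- cut[, which(attr(cut, "offsets") == 0)]
  expect_identical(center_before, center_after)
  expect_identical(dim(cut_profiles(st, 2 * 20)), dim(st))
  expect_error(cut_profiles(st, 0), class = "vc_error_input")
  expect_error(cut_profiles(st, 100), class = "vc_error_input")
})

test_that("anisotropic smoothing is normalized and has the requested spread", {
  st <- straighten_segment(matrix(0.42, 30, 60),
                           fit_spline(tibble::tibble(x = 5:54, y = rep(15, 50))),
                           half_len = 10)
  sm <- smooth_straightened(st, 20)
  expect_lt(max(abs(sm - 0.42)), 1e-12)     # constant image unchanged

  # impulse response across the profile: second moment matches sigma^2 = 4
  imp <- matrix(0, 1, 41)
  imp[1, 21] <- 1
  out <- vesselcaliber:::blur_separable(imp, sigma_row = 30, sigma_col = 2)
  k <- seq(-20, 20)
  m2 <- sum(out[1, ] * k^2) / sum(out[1, ])
  expect_lt(abs(m2 - 4) / 4, 0.05)
})
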