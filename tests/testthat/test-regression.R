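make_records <- function(n, seed = 1, width_fun = function(s1) 3 * s1 + 1) {
  set.seed(seed)
  tibble::tibble(
    sigma1 = runif(n, 1, 5),
    h1 = runif(n, -0.6, -0.3),
    t = runif(n, 0.6, 0.9),
    segment_id = rep(seq_len(max(2, n %/% 10)), length.out = n),
    width_gt = width_fun(sigma1)
  )
}

test_that("a constant-width training set predicts that constant", {
  rec <- make_records(50, width_fun = function(s1) rep(7, length(s1)))
  reg <- train_width_regressor(rec)
  pred <- predict_width(reg, rec)
  expect_true(all(abs(pred - 7) < 1e-10))
})

test_that("a monotone parameter-width relationship is learned accurately", {
  rec <- make_records(200, seed = 2)
  reg <- train_width_regressor(rec, regressor_config(n_trees = 200, seed = 5))
  pred <- predict_width(reg, rec)
  mae <- mean(abs(pred - rec$width_gt))
  expect_lt(mae, 0.05 * diff(range(rec$width_gt)))
  # trees cannot extrapolate beyond the training width range
  expect_true(all(pred >= min(rec$width_gt) & pred <= max(rec$width_gt)))
})

test_that("training is deterministic given the seed", {
  rec <- make_records(100, seed = 3)
  p1 <- predict_width(train_width_regressor(rec, regressor_config(seed = 9)), rec)
  p2 <- predict_width(train_width_regressor(rec, regressor_config(seed = 9)), rec)
  expect_identical(p1, p2)
})

test_that("degenerate training input and wrong predictors are rejected", {
  rec <- make_records(50)
  expect_error(train_width_regressor(rec[0, ]), class = "vc_error_input")
  bad <- rec; bad$width_gt[1] <- -1
  expect_error(train_width_regressor(bad), class = "vc_error_input")
  reg <- train_width_regressor(rec)
  expect_error(predict_width(reg, c(sigma1 = 2)), class = "vc_error_input")
  gl <- glance(reg)
  expect_equal(gl$n_trees, 100)
})

test_that("center matching is unique, distance-ordered and cut at 5 px", {
  gt <- data.frame(x = c(10, 30, 50), y = c(10, 10, 10))
  det <- data.frame(x = c(10, 36, 50.4), y = c(10, 10, 10))
  m <- match_centers(gt, det)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$distance[m$pairs$gt_index == 1], 0)
  expect_true(2 %in% m$unmatched_gt)         # nearest detected point 6 px away

  # two ground-truth points near one detected point: only the closer matches
  gt2 <- data.frame(x = c(10, 11), y = c(0, 0))
  det2 <- data.frame(x = 10.2, y = 0)
  m2 <- match_centers(gt2, det2)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$gt_index, 1L)
  expect_equal(tidy(m2), m2$pairs)

  # the cutoff is exclusive
  m3 <- match_centers(data.frame(x = 0, y = 0), data.frame(x = 5, y = 0))
  expect_equal(nrow(m3$pairs), 0)
})

test_that("evaluation metrics follow the error-statistics definitions", {
  ev <- evaluate_widths(c(10, 14), c(10, 12))     # chi = {0, 2}
  expect_equal(ev$mu_error, 1)
  expect_equal(ev$sigma_error, sqrt(2))

  ev2 <- evaluate_widths(c(5, 6, 7) + 2, c(5, 6, 7))
  expect_equal(ev2$mu_error, 2)
  expect_equal(ev2$sigma_error, 0)

  ev3 <- evaluate_widths(rep(8, 8), rep(8, 8), n_gt_total = 10)
  expect_equal(ev3$sr, 80)
  expect_error(evaluate_widths(1, 1), class = "vc_error_input")
})

test_that("k-fold validation predicts every record exactly once, reproducibly", {
  rec <- make_records(60, seed = 4)
  cv <- run_kfold(rec, k = 10, seed = 7)
  expect_false(any(is.na(cv$predictions$width_pred)))
  expect_equal(nrow(cv$predictions), 60)
  expect_equal(sort(unique(cv$predictions$fold)), 1:10)
  cv2 <- run_kfold(rec, k = 10, seed = 7)
  expect_identical(cv$predictions$fold, cv2$predictions$fold)
  expect_identical(cv$report, cv2$report)
  # leave-one-out degenerate case runs
  small <- make_records(12, seed = 5)
  loo <- run_kfold(small, k = 12, seed = 1)
  expect_equal(length(unique(loo$predictions$fold)), 12)
  expect_error(run_kfold(small, k = 20), class = "vc_error_input")
})

test_that("leave-one-segment-out holds out whole segments", {
  rec <- make_records(70, seed = 6)
  rec$segment_id <- rep(1:7, each = 10)
  lo <- run_loso(rec)
  expect_equal(sort(unique(lo$predictions$fold)), 1:7)
  expect_equal(lo$predictions$fold, rec$segment_id)   # fold = held-out segment
  expect_false(any(is.na(lo$predictions$width_pred)))
  one_seg <- rec[rec$segment_id == 1, ]
  expect_error(run_loso(one_seg), class = "vc_error_input")
  expect_equal(nrow(glance(lo)), 1)
})

test_that("segment correlations are maximum-aligned and autocorrelation-normalized", {
  base <- 0.8 - 0.5 * exp(-((0:30 - 15) / 5)^2)
  same <- replicate(5, base, simplify = FALSE)
  sc <- segment_correlations(same)
  expect_equal(sc$mu_corr, 1, tolerance = 1e-12)
  expect_equal(sc$n_comb, 10)

  bump <- 0.2 + exp(-((0:30 - 15) / 4)^2)          # unique interior maximum
  shifted <- c(bump[4:31], rep(0.2, 3))            # integer shift by 3
  sc2 <- segment_correlations(list(bump, shifted))
  expect_gt(sc2$max_corr, 0.999)

  twenty <- lapply(1:20, function(i) base + i * 1e-3)
  expect_equal(segment_correlations(twenty)$n_comb, 190)
  expect_error(segment_correlations(list(base)), class = "vc_error_input")
})

test_that("Bland-Altman points carry ground truth and signed error", {
  pts <- bland_altman_points(c(12, 8), c(10, 8))
  expect_equal(pts$width_gt, c(10, 8))
  expect_equal(pts$error, c(2, 0))
  expect_equal(nrow(bland_altman_points(1:7, 1:7)), 7)
  expect_true(all(bland_altman_points(1:7, 1:7)$error == 0))
})
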