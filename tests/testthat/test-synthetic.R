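test_that("a noiseless render equals the analytic intensity field", {
  ds <- straight_vessel(10)
  # far from the vessel: pure background
  expect_equal(ds$green[5, 50], 0.8, tolerance = 1e-12)
  # on the centerline (y = 40): background minus full contrast; the dense
  # curve is sampled at 1/4 px, so distances are exact to ~0.13 px
  expect_equal(ds$green[41, 51],
               0.8 + vesselcaliber:::vessel_cross_section(0, 10, 0.4, 0, 0.4),
               tolerance = 1e-4)
  # mask width along a normal: pixels within D/2 of the center row
  col <- ds$mask[, 51]
  expect_true(abs(sum(col) - 10) <= 1)
  # ground-truth edges are exactly one diameter apart
  w <- sqrt((ds$gt_profiles$edge1_x - ds$gt_profiles$edge2_x)^2 +
              (ds$gt_profiles$edge1_y - ds$gt_profiles$edge2_y)^2)
  expect_lt(max(abs(w - 10)), 1e-9)
})

test_that("rendering is bit-identical for identical spec and seed", {
  a <- straight_vessel(8, noise_sd = 0.02, seed = 9)
  b <- straight_vessel(8, noise_sd = 0.02, seed = 9)
  expect_identical(a$green, b$green)
  expect_identical(a$mask, b$mask)
  expect_identical(a$gt_profiles, b$gt_profiles)
  c <- straight_vessel(8, noise_sd = 0.02, seed = 10)
  expect_false(identical(a$green, c$green))
})

test_that("vessels leaving the image are rejected and overlaps flagged", {
  sp <- vessel_spec("line", diameter = 10, from = c(2, 40), to = c(90, 40))
  expect_error(render_vessel_image(sp, shape = c(80, 100)),
               class = "vc_error_input")
  two <- dplyr::bind_rows(
    vessel_spec("line", diameter = 8, from = c(16, 40), to = c(84, 40)),
    vessel_spec("line", diameter = 8, from = c(16, 42), to = c(84, 42))
  )
  expect_warning(ds <- render_vessel_image(two, shape = c(80, 100)), "overlap")
  expect_true(ds$overlapping)
})

test_that("model-generated profile sets reproduce their stored parameters", {
  ps <- generate_profile_set("dogl7", 5, len = 21, noise_sd = 0, seed = 19)
  for (i in 1:5) {
    expect_equal(ps$profiles[i, ],
                 evaluate_model("dogl7", unlist(ps$params[i, ]), ps$xs),
                 tolerance = 1e-12)
  }
  expect_true(all(ps$widths > 0))
  # additive noise has the requested scale (law of large numbers)
  psn <- generate_profile_set("dogl7", 50, len = 21, noise_sd = 0.05, seed = 19)
  clean <- generate_profile_set("dogl7", 50, len = 21, noise_sd = 0, seed = 19)
  resid <- psn$profiles - clean$profiles
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.05)
})

test_that("CLR renders are classified as CLR by the peak rules", {
  hits <- 0; n <- 0
  for (D in c(10, 12, 14, 16, 18, 20)) {
    for (off in c(0, 0.3)) {
      v <- synthetic_cross_profile(D, clr_depth = 0.16, off = off)
      sm <- smoothed_mean_profile(matrix(v, 1), 1)
      lim <- determine_limits(sm, initial_half_len = (length(v) - 1) / 2)
      n <- n + 1
      hits <- hits + lim$is_clr
    }
  }
  expect_gte(hits / n, 0.95)
})

test_that("the full pipeline recovers the diameter of noiseless straight vessels", {
  cfg <- vc_config(verbose = FALSE)
  recs <- list()
  for (D in c(6, 10, 16)) {
    ds <- straight_vessel(D)
    meas <- measure_segments(ds$green, ds$mask, cfg)
    mt <- match_centers(
      data.frame(x = ds$gt_profiles$center_x, y = ds$gt_profiles$center_y),
      data.frame(x = meas$center_x, y = meas$center_y)
    )
    recs[[length(recs) + 1]] <- dplyr::bind_cols(
      meas[mt$pairs$det_index, model_param_names(cfg$model)],
      tibble::tibble(width_gt = ds$gt_profiles$width[mt$pairs$gt_index],
                     segment_id = D)
    )
  }
  rec <- dplyr::bind_rows(recs)
  cv <- run_kfold(rec, k = 5, seed = 3)
  per_vessel <- dplyr::summarise(
    dplyr::group_by(cv$predictions, .data$segment_id),
    mean_w = mean(.data$width_pred)
  )
  expect_true(all(abs(per_vessel$mean_w - per_vessel$segment_id) <= 0.5))
})
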