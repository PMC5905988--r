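test_that("skeletonize handles the empty mask and validates input", {
  m <- matrix(FALSE, 8, 8)
  expect_identical(skeletonize(m), m)
  expect_error(skeletonize(array(TRUE, c(2, 2, 2))), class = "vc_error_input")
  expect_error(skeletonize(matrix("a", 2, 2)), class = "vc_error_input")
})

test_that("a solid bar thins to a single-pixel path of the bar's length", {
  mask <- matrix(FALSE, 9, 24)
  mask[3:7, 3:22] <- TRUE
  sk <- skeletonize(mask)
  expect_true(all(mask[sk]))                       # skeleton inside mask
  expect_equal(count_components8(sk), 1)
  expect_true(all(colSums(sk)[colSums(sk) > 0] == 1))  # one pixel per column
  # reference thinning routines shorten a blunt bar by about half its width
  # at each end (16-17 px here for a 5x20 bar); allow one more pixel of slack
  expect_true(sum(sk) >= 14 && sum(sk) <= 18)
})

test_that("skeleton is a subset of the mask and the pipeline is deterministic", {
  set.seed(41)
  for (i in 1:5) {
    mask <- matrix(runif(30 * 40) < 0.4, 30, 40)
    sk <- skeletonize(mask)
    expect_true(all(mask[sk]))
    sk2 <- split_at_junctions(sk)
    nb <- vesselcaliber:::count_neighbors8(sk2)
    expect_lte(max(nb[sk2], 0), 2)
    # identical input gives identical segments
    s1 <- extract_segments(sk2)
    s2 <- extract_segments(split_at_junctions(skeletonize(mask)))
    expect_identical(s1, s2)
  }
})

test_that("junction removal splits crossings and T-junctions as the neighbor counts dictate", {
  straight <- matrix(FALSE, 5, 12)
  straight[3, 2:11] <- TRUE
  expect_identical(split_at_junctions(straight), straight)

  cross <- make_cross_skeleton()
  out <- split_at_junctions(cross)
  expect_false(out[8, 8])                  # crossing pixel removed
  expect_equal(count_components8(out), 4)  # four arms remain

  tee <- make_t_skeleton()
  out_t <- split_at_junctions(tee)
  expect_false(out_t[4, 8])                # the >=3-neighbor pixel removed
  expect_equal(count_components8(out_t), 3)
})

test_that("extract_segments returns ordered simple paths with distinct ids", {
  m <- matrix(FALSE, 10, 20)
  m[3, 3:17] <- TRUE                       # one 15-pixel path
  segs <- extract_segments(m)
  expect_equal(length(unique(segs$segment_id)), 1)
  expect_equal(nrow(segs), 15)

  m[8, 5:12] <- TRUE                       # second disjoint path
  segs2 <- extract_segments(m)
  expect_equal(sort(unique(segs2$segment_id)), c(1L, 2L))

  # ordering: consecutive points 8-adjacent, no repeated coordinates
  for (sid in unique(segs2$segment_id)) {
    s <- segs2[segs2$segment_id == sid, ]
    expect_false(anyDuplicated(s[, c("x", "y")]) > 0)
    expect_true(all(pmax(abs(diff(s$x)), abs(diff(s$y))) == 1))
    # terminal points have one in-segment neighbor, interior two
    adj <- outer(seq_len(nrow(s)), seq_len(nrow(s)), function(i, j) {
      pmax(abs(s$x[i] - s$x[j]), abs(s$y[i] - s$y[j])) == 1
    })
    deg <- rowSums(adj)
    expect_equal(sum(deg == 1), 2)
    expect_true(all(deg[deg != 1] == 2))
  }
})

test_that("closed loops are dropped with a warning and isolated pixels silently", {
  m <- matrix(FALSE, 10, 10)
  ring <- rbind(c(3, 5), c(4, 4), c(5, 3), c(6, 4),   # diamond ring: every
                c(7, 5), c(6, 6), c(5, 7), c(4, 6))   # pixel has 2 neighbors
  m[ring] <- TRUE
  m[9, 9] <- TRUE                          # isolated pixel
  expect_warning(segs <- extract_segments(m), "loop")
  expect_equal(nrow(segs), 0)
})

test_that("spur pruning is strict below 10 points and keeps exactly-10 segments", {
  seg9 <- tibble::tibble(segment_id = 1L, point_index = 0:8, x = 0:8, y = 0L)
  seg10 <- tibble::tibble(segment_id = 2L, point_index = 0:9, x = 0:9, y = 2L)
  both <- dplyr::bind_rows(seg9, seg10)
  kept <- prune_short_segments(both)
  expect_equal(unique(kept$segment_id), 2L)
  expect_equal(nrow(kept), 10)
  empty <- both[0, ]
  expect_equal(nrow(prune_short_segments(empty)), 0)
})
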