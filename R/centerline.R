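#' Skeletonize a binary vessel mask
#'
#' Reduces a binary vessel segmentation mask to a one-pixel-wide, 8-connected
#' centerline using Zhang-Suen morphological thinning. Every skeleton pixel
#' lies inside the mask and the connectivity of each mask component is
#' preserved.
#'
#' @param mask Logical matrix (`TRUE` = vessel), or a numeric matrix in
#'   `[0, 1]` which is thresholded at 0.5.
#' @return Logical matrix of the same shape as `mask`.
#' @examples
#' mask <- matrix(FALSE, 9, 20)
#' mask[3:7, ] <- TRUE
#' skel <- skeletonize(mask)
#' sum(skel)
#' @export
skeletonize <- function(mask) {
  m <- as_logical_mask(mask)
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # 8-neighborhood in circular order P2..P9 (N, NE, E, SE, S, SW, W, NW),
      # rows increase downward so "north" is row - 1
      p2 <- shift_logical(m, -1, 0); p3 <- shift_logical(m, -1, 1)
      p4 <- shift_logical(m, 0, 1); p5 <- shift_logical(m, 1, 1)
      p6 <- shift_logical(m, 1, 0); p7 <- shift_logical(m, 1, -1)
      p8 <- shift_logical(m, 0, -1); p9 <- shift_logical(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  remove_redundant_pixels(m)
}

# Final cleanup after thinning: drop pixels that are not needed for
# connectivity (their true 8-neighbors stay mutually 8-connected without
# them). Thinning can leave staircase corners with 3 neighbors that would
# otherwise be mistaken for junctions; genuine junctions connect separate
# branches and are therefore kept.
remove_redundant_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    nb <- count_neighbors8(m)
    cand <- which(m & nb >= 3)
    removed <- FALSE
    for (i in cand) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      pts <- NEIGHBOR_OFFSETS +
        matrix(c(r, c), nrow(NEIGHBOR_OFFSETS), 2, byrow = TRUE)
      ok <- pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc
      pts <- pts[ok, , drop = FALSE]
      pts <- pts[m[pts], , drop = FALSE]
      k <- nrow(pts)
      if (k < 3) next
      # connectivity of the neighbors among themselves (8-adjacency)
      adj <- abs(outer(pts[, 1], pts[, 1], "-")) <= 1 &
        abs(outer(pts[, 2], pts[, 2], "-")) <= 1
      seen <- logical(k); seen[1] <- TRUE
      repeat {
        nxt <- seen | (colSums(adj & seen) > 0)
        if (all(nxt == seen)) break
        seen <- nxt
      }
      if (all(seen)) {
        m[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

#' Remove junction pixels from a skeleton
#'
#' Deletes every skeleton pixel with three or more true 8-neighbors
#' (bifurcations and crossovers), so the centerline network falls apart into
#' individual junction-free runs. Idempotent on junction-free input.
#'
#' @param skel Logical skeleton matrix, as produced by [skeletonize()].
#' @return Logical matrix in which every true pixel has at most two true
#'   8-neighbors.
#' @export
split_at_junctions <- function(skel) {
  m <- as_logical_mask(skel, "skel")
  nb <- count_neighbors8(m)
  m[m & nb >= 3] <- FALSE
  m
}

#' Extract centerline segments from a junction-free skeleton
#'
#' Collects each connected component of a junction-free skeleton that forms a
#' simple path (two endpoints, interior pixels with exactly two neighbors)
#' into an ordered run of pixels. Isolated single pixels are dropped silently;
#' closed loops (components without endpoints) are dropped with a warning.
#'
#' @param skel Logical junction-free skeleton matrix.
#' @return A tibble with one row per centerline pixel and columns
#'   `segment_id`, `point_index` (0-based position along the segment), and
#'   0-based pixel coordinates `x` (column) and `y` (row). Consecutive points
#'   of a segment are 8-adjacent.
#' @export
extract_segments <- function(skel) {
  m <- as_logical_mask(skel, "skel")
  nb <- count_neighbors8(m)
  if (any(m & nb >= 3)) {
    abort("`skel` still contains junction pixels; run split_at_junctions() first.",
          class = "vc_error_input")
  }
  nr <- nrow(m)
  idx <- which(m)                       # column-major linear indices
  empty <- tibble::tibble(
    segment_id = integer(), point_index = integer(),
    x = integer(), y = integer()
  )
  if (!length(idx)) return(empty)

  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  key <- function(r, c) (c - 1L) * nr + r
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = present)

  neighbors_of <- function(i) {
    r <- rows[i]; c <- cols[i]
    out <- integer(0)
    for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
      rr <- r + NEIGHBOR_OFFSETS[k, 1]; cc <- c + NEIGHBOR_OFFSETS[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
      j <- mget(as.character(key(rr, cc)), envir = present,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }

  visited <- logical(length(idx))
  segments <- list()
  seg_id <- 0L
  n_loops <- 0L
  for (start in seq_along(idx)) {
    if (visited[start]) next
    # gather the connected component by breadth-first traversal
    comp <- integer(0)
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, i)
      for (j in neighbors_of(i)) {
        if (!visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    if (length(comp) == 1L) next        # isolated pixel
    deg <- vapply(comp, function(i) length(neighbors_of(i)), integer(1))
    ends <- comp[deg == 1L]
    if (length(ends) == 0L) {
      n_loops <- n_loops + 1L
      next
    }
    if (length(ends) != 2L || any(deg > 2L)) next   # not a simple path
    # trace from one endpoint to the other
    path <- integer(length(comp))
    prev <- 0L
    cur <- ends[[1]]
    for (p in seq_along(comp)) {
      path[p] <- cur
      nxt <- setdiff(neighbors_of(cur), prev)
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[[1]]
    }
    seg_id <- seg_id + 1L
    segments[[seg_id]] <- tibble::tibble(
      segment_id = seg_id,
      point_index = seq_along(path) - 1L,
      x = cols[path] - 1L,
      y = rows[path] - 1L
    )
  }
  if (n_loops > 0L) {
    warn(sprintf("Discarded %d closed centerline loop(s) without endpoints.", n_loops))
  }
  if (!length(segments)) return(empty)
  dplyr::bind_rows(segments)
}

#' Remove short centerline segments
#'
#' Drops segments whose pixel count is below `min_len`; these short spurs are
#' usually artifacts of the thinning step rather than true vessel segments.
#' The bound is strict: a segment of exactly `min_len` points is kept.
#'
#' @param segments Segment tibble from [extract_segments()].
#' @param min_len Minimum number of points a segment must have to be kept
#'   (default 10).
#' @return The filtered segment tibble.
#' @export
prune_short_segments <- function(segments, min_len = 10) {
  stopifnot(is.data.frame(segments))
  dplyr::filter(
    dplyr::group_by(segments, .data$segment_id),
    dplyr::n() >= min_len
  ) |> dplyr::ungroup()
}
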