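# Image and table I/O. All tables use 0-based pixel coordinates with
# x = column and y = row, origin at the top-left pixel center.

#' Read a fundus image
#'
#' Reads a PNG/TIFF/JPEG image into an RGB array scaled to `[0, 1]` (the
#' reader divides by the bit-depth maximum), indexed `[row, col, channel]`.
#' Grayscale files are replicated across the three channels.
#'
#' @param path Image file path.
#' @return Numeric `rows x cols x 3` array.
#' @export
read_fundus_image <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(sprintf("Cannot read image '%s': %s",
                                                    path, conditionMessage(e)),
                                            class = "vc_error_io"))
  a <- as.array(img)
  if (length(dim(a)) == 2) {
    g <- t(a)
    out <- array(0, dim = c(dim(g), 3))
    out[, , 1] <- g; out[, , 2] <- g; out[, , 3] <- g
    return(out)
  }
  if (length(dim(a)) != 3) abort("Unsupported image dimensionality.",
                                 class = "vc_error_io")
  nch <- dim(a)[3]
  out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
  for (ch in 1:3) out[, , ch] <- t(a[, , min(ch, nch)])
  out
}

#' Extract the green channel
#'
#' @param image RGB array from [read_fundus_image()] (or a plain matrix,
#'   returned unchanged).
#' @return Numeric matrix in `[0, 1]`.
#' @export
green_channel <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3)
  image[, , 2]
}

#' Read a binary vessel mask
#'
#' Reads an image file and binarizes it at 0.5 (so masks stored as
#' `{0, 255}` grayscale work directly).
#'
#' @param path Image file path.
#' @return Logical matrix.
#' @export
read_vessel_mask <- function(path) {
  a <- read_fundus_image(path)
  a[, , 1] >= 0.5
}

#' Write an image or mask to file
#'
#' @param image RGB array, numeric matrix in `[0, 1]`, or logical mask.
#' @param path Output path; the extension (png/tiff/jpeg) selects the format.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  dat <- if (is.matrix(image)) {
    t(image)
  } else {
    aperm(image, c(2, 1, 3))
  }
  img <- EBImage::Image(dat, colormode = if (is.matrix(dat)) "Grayscale" else "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

ANNOTATION_COLS <- c("segment_id", "point_index", "center_x", "center_y",
                     "edge1_x", "edge1_y", "edge2_x", "edge2_y")

#' Read a ground-truth annotation table
#'
#' Reads a CSV of per-profile edge annotations with columns `segment_id`,
#' `point_index`, `center_x`, `center_y`, `edge1_x`, `edge1_y`, `edge2_x`,
#' `edge2_y` (0-based pixel coordinates, sub-pixel values allowed). Unknown
#' extra columns are preserved. Rows with coincident edge points (zero
#' width) or duplicated `(segment_id, point_index)` keys are rejected.
#'
#' @param path CSV file path.
#' @return Annotation tibble with a derived `width` column.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(tbl))
  if (length(missing)) {
    abort(sprintf("Annotation file lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vc_error_schema")
  }
  w <- sqrt((tbl$edge1_x - tbl$edge2_x)^2 + (tbl$edge1_y - tbl$edge2_y)^2)
  if (any(w == 0)) abort("Annotation rows with coincident edge points (zero width).",
                         class = "vc_error_schema")
  if (anyDuplicated(tbl[, c("segment_id", "point_index")])) {
    abort("Duplicate (segment_id, point_index) keys in annotations.",
          class = "vc_error_schema")
  }
  tbl$width <- w
  tbl
}

#' Write an annotation table
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param path Output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path)
  invisible(path)
}

#' Write / read a measurement table
#'
#' The measurement table holds one row per measured centerline point:
#' location, model identifier, best-fit parameters, goodness-of-fit metrics
#' and (when available) the estimated and matched ground-truth widths.
#' Round-trips through CSV at full precision.
#'
#' @param measurements Measurement tibble from [run_pipeline()].
#' @param path CSV path.
#' @return `read_measurements()` returns the tibble.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("segment_id", "point_index", "center_x", "center_y", "model_id")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(sprintf("Measurement file lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vc_error_schema")
  }
  if ("estimated_width" %in% names(tbl) &&
      any(tbl$estimated_width <= 0, na.rm = TRUE)) {
    abort("Estimated widths must be positive where present.",
          class = "vc_error_schema")
  }
  tbl
}

#' Write an evaluation report as JSON
#'
#' @param report A `vc_evaluation` row, a `vc_validation` object, or any
#'   list/tibble of summary numbers.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "vc_validation")) report <- report$report
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
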