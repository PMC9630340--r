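# Per-embryo intensity quantification: summed ROI intensity with
# blank-minimum background subtraction, mirroring the manual Fiji
# measurement on maximum-intensity projections.

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# A point exactly on an edge may fall on either side; pixel centers at
# integer coordinates against the package's non-integer polygon vertices
# avoid that case. Hand-written so the inclusion rule is explicit and
# bit-reproducible.
point_in_polygon <- function(px, py, poly) {
  vx <- poly$x; vy <- poly$y
  n <- length(vx)
  if (n < 3L) stop_("polygon needs at least 3 vertices")
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Measure total embryo fluorescence with blank-minimum background subtraction
#'
#' Sums all pixel intensities whose centers fall inside the outer ROI
#' (even-odd fill rule), finds the minimum pixel intensity inside the blank
#' ROI -- a dot-free patch of the margin whose darkest pixel estimates the
#' per-pixel background -- and subtracts `blank_min * pixel_count` from the
#' raw total, flooring at zero. Subtracting the blank minimum once per ROI
#' pixel treats it as a per-pixel background level, the only reading that
#' is dimensionally consistent with a summed total.
#'
#' @param image A [render_embryo_image()] result, a numeric matrix, or a
#'   path to an 8/16-bit grayscale TIFF file.
#' @param outer_roi,blank_roi Polygon vertex data frames (`x`, `y`, 1-based
#'   pixel-center coordinates), or a path to a ROI JSON file (see
#'   [read_roi_json()]) passed as `outer_roi`. Default to the ROIs embedded
#'   in a `synthetic_image`.
#' @return An object of class `intensity_measure`: `raw_total`,
#'   `blank_min`, `pixel_count`, `corrected_total` (all OD).
#' @export
measure_embryo_intensity <- function(image, outer_roi = NULL, blank_roi = NULL) {
  if (inherits(image, "synthetic_image")) {
    outer_roi <- outer_roi %||% image$outer_roi
    blank_roi <- blank_roi %||% image$blank_roi
    image <- image$pixels
  } else if (is.character(image)) {
    image <- read_image_tiff(image)
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop_("image must be a numeric matrix, synthetic_image, or TIFF path")
  if (is.character(outer_roi) && is.null(blank_roi)) {
    rois <- read_roi_json(outer_roi)
    outer_roi <- rois$outer_roi; blank_roi <- rois$blank_roi
  }
  if (is.null(outer_roi) || is.null(blank_roi))
    stop_("both outer_roi and blank_roi are required")
  nr <- nrow(image); nc <- ncol(image)
  check_roi <- function(poly, label) {
    if (!all(c("x", "y") %in% names(poly)) || nrow(poly) < 3L)
      stop_("%s must be a polygon data frame with >= 3 rows of x, y", label)
    if (any(poly$x < 0.5 - 1e-9 | poly$x > nc + 0.5 + 1e-9 |
            poly$y < 0.5 - 1e-9 | poly$y > nr + 0.5 + 1e-9))
      stop_("%s extends outside the image bounds", label)
  }
  check_roi(outer_roi, "outer_roi"); check_roi(blank_roi, "blank_roi")

  px <- rep(seq_len(nc), each = nr); py <- rep(seq_len(nr), times = nc)
  in_outer <- point_in_polygon(px, py, outer_roi)
  if (!any(in_outer)) stop_("outer_roi contains no pixel centers")
  in_blank <- point_in_polygon(px, py, blank_roi)
  if (!any(in_blank)) stop_("blank_roi contains no pixel centers")
  if (any(in_blank & !in_outer))
    stop_("blank_roi must lie inside outer_roi")
  vals <- as.vector(image)
  raw_total <- sum(vals[in_outer])
  pixel_count <- sum(in_outer)
  blank_min <- min(vals[in_blank])
  corrected <- max(0, raw_total - blank_min * pixel_count)
  structure(list(raw_total = raw_total, blank_min = blank_min,
                 pixel_count = pixel_count, corrected_total = corrected),
            class = "intensity_measure")
}

#' @export
print.intensity_measure <- function(x, ...) {
  cat(sprintf(paste0("ROI intensity: raw %g OD over %d px, blank min %g OD/px,",
                     " corrected total %g OD\n"),
              x$raw_total, x$pixel_count, x$blank_min, x$corrected_total))
  invisible(x)
}

#' Write / read 16-bit grayscale TIFF images
#'
#' Intensities are stored as 16-bit integer counts (0--65535);
#' `read_image_tiff()` returns them on that integer scale.
#'
#' @param image A `synthetic_image` or numeric matrix of counts.
#' @param path File path.
#' @return `write_image_tiff()`: invisibly, `path`; `read_image_tiff()`:
#'   an integer-valued numeric matrix.
#' @export
write_image_tiff <- function(image, path) {
  if (inherits(image, "synthetic_image")) image <- image$pixels
  if (any(image < 0 | image > 65535)) stop_("pixel values must be in [0, 65535]")
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop_("expected a single-channel grayscale TIFF")
    m <- m[, , 1]
  }
  storage.mode(m) <- "double"
  m
}

#' Write / read ROI polygons as JSON
#'
#' Vertex lists are stored 0-based with origin at the top-left pixel
#' center, `[x, y]` pairs; in-memory polygons are 1-based (R matrix
#' convention). The conversion happens here.
#'
#' @param outer_roi,blank_roi Polygon data frames (`x`, `y`).
#' @param path File path.
#' @return `write_roi_json()`: invisibly, `path`; `read_roi_json()`: list
#'   with elements `outer_roi` and `blank_roi`.
#' @export
write_roi_json <- function(outer_roi, blank_roi, path) {
  to0 <- function(p) unname(as.matrix(p[, c("x", "y")] - 1))
  jsonlite::write_json(list(outer_roi = to0(outer_roi),
                            blank_roi = to0(blank_roi)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from0 <- function(m) data.frame(x = m[, 1] + 1, y = m[, 2] + 1)
  list(outer_roi = from0(obj$outer_roi), blank_roi = from0(obj$blank_roi))
}
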