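#' Render a synthetic embryo image
#'
#' Emulates an animal-pole maximum-intensity projection of a FISH-stained
#' embryo: bright single-pixel staining dots dispersed over a uniform
#' background within a ring-shaped margin, inside a circular outer ROI.
#' A smaller blank ROI inside the margin is kept free of dots so that its
#' minimum pixel equals the true background, as required by the
#' blank-minimum background-subtraction procedure. The summed intensity of
#' all placed dots is recorded as `truth_signal_sum`.
#'
#' Coordinates: the pixel in matrix row `r`, column `c` has its center at
#' `(x = c, y = r)`; polygons are stored in these 1-based pixel-center
#' coordinates (file export is 0-based, see [write_roi_json()]).
#'
#' @param shape Image size `c(rows, cols)`.
#' @param n_dots Number of staining dots (`>= 0`).
#' @param dot_intensity Intensity added per dot (OD counts).
#' @param background_level Uniform background level (`>= 0`).
#' @param seed Integer seed for dot placement.
#' @param margin_radii Ring of dot placement, as fractions of `min(shape)`.
#' @param outer_radius Outer-ROI radius as a fraction of `min(shape)`.
#' @param blank_radius_px Radius of the blank ROI in pixels.
#' @return An object of class `synthetic_image`: list with `pixels`
#'   (matrix), `outer_roi`, `blank_roi` (data frames of polygon vertices
#'   `x`, `y`), and `truth_signal_sum`.
#' @export
render_embryo_image <- function(shape = c(128L, 128L), n_dots = 150L,
                                dot_intensity = 200, background_level = 100,
                                seed = 1L, margin_radii = c(0.28, 0.42),
                                outer_radius = 0.46, blank_radius_px = 5) {
  if (length(shape) != 2L || any(shape < 8)) stop_("shape must be c(rows, cols), each >= 8")
  if (n_dots < 0) stop_("n_dots must be >= 0")
  if (background_level < 0) stop_("background_level must be >= 0")
  if (dot_intensity <= 0) stop_("dot_intensity must be > 0")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  r_out <- outer_radius * min(nr, nc)
  r1 <- margin_radii[1] * min(nr, nc); r2 <- margin_radii[2] * min(nr, nc)
  if (!(r1 < r2 && r2 < r_out)) stop_("margin_radii must satisfy r1 < r2 < outer_radius")

  circle_poly <- function(cx0, cy0, r, k = 72) {
    th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    data.frame(x = cx0 + r * cos(th), y = cy0 + r * sin(th))
  }
  outer_roi <- circle_poly(cx, cy, r_out)
  rb <- (r1 + r2) / 2
  bx <- cx + rb * cos(pi / 4); by <- cy + rb * sin(pi / 4)
  if (sqrt((bx - cx)^2 + (by - cy)^2) + blank_radius_px >= r_out)
    stop_("blank ROI would not be strictly inside the outer ROI")
  blank_roi <- circle_poly(bx, by, blank_radius_px, k = 36)

  px <- rep(seq_len(nc), each = nr); py <- rep(seq_len(nr), times = nc)
  d_center <- sqrt((px - cx)^2 + (py - cy)^2)
  d_blank <- sqrt((px - bx)^2 + (py - by)^2)
  candidate <- d_center >= r1 & d_center <= r2 & d_blank > blank_radius_px + 1
  idx <- which(candidate)
  if (n_dots > length(idx))
    stop_("n_dots = %d infeasible: only %d candidate pixels in the margin ring",
          n_dots, length(idx))
  pixels <- matrix(background_level, nrow = nr, ncol = nc)
  if (n_dots > 0) {
    chosen <- with_seed(seed, sample(idx, n_dots))
    pixels[cbind(py[chosen], px[chosen])] <-
      pixels[cbind(py[chosen], px[chosen])] + dot_intensity
  }
  structure(list(pixels = pixels, outer_roi = outer_roi, blank_roi = blank_roi,
                 truth_signal_sum = n_dots * dot_intensity,
                 background_level = background_level),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic embryo image %d x %d px, background %g, true signal sum %g\n",
              nrow(x$pixels), ncol(x$pixels), x$background_level,
              x$truth_signal_sum))
  invisible(x)
}
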