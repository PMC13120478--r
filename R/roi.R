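#' Annular region of interest between two rectangles
#'
#' The analysis region is the closed set of lattice points inside an outer
#' rectangle minus the *open interior* of an inner rectangle: both rectangle
#' boundaries are retained, so the ROI is a closed annular frame around the
#' fovea. Bounds are inclusive 0-based lattice coordinates. The defaults are
#' the coordinates used throughout the package for full-resolution macular
#' maps (outer 330 x 285 px spanning x 65..395, y 75..360; inner 70 x 50 px
#' spanning x 205..275, y 200..250); `one_based = TRUE` reinterprets the same
#' numbers as 1-based indices by shifting every bound down one lattice step.
#'
#' @param outer,inner Length-4 integer vectors `c(x0, x1, y0, y1)`, inclusive.
#' @param one_based Interpret the supplied coordinates as 1-based indices.
#' @return An object of class `roi_frame`.
#' @export
roi_frame <- function(outer = c(65, 395, 75, 360),
                      inner = c(205, 275, 200, 250),
                      one_based = FALSE) {
  outer <- as.integer(outer); inner <- as.integer(inner)
  if (one_based) { outer <- outer - 1L; inner <- inner - 1L }
  stopifnot(length(outer) == 4L, length(inner) == 4L)
  if (outer[1] >= outer[2] || outer[3] >= outer[4]) {
    stop("outer rectangle must have positive extent", call. = FALSE)
  }
  strictly_inside <- inner[1] > outer[1] && inner[2] < outer[2] &&
    inner[3] > outer[3] && inner[4] < outer[4] &&
    inner[1] < inner[2] && inner[3] < inner[4]
  if (!strictly_inside) {
    stop("inner rectangle must be strictly contained in the outer rectangle",
         call. = FALSE)
  }
  structure(list(outer = outer, inner = inner), class = "roi_frame")
}

#' @export
print.roi_frame <- function(x, ...) {
  cat(sprintf(
    "<roi_frame> outer x %d..%d, y %d..%d; inner x %d..%d, y %d..%d (%d points)\n",
    x$outer[1], x$outer[2], x$outer[3], x$outer[4],
    x$inner[1], x$inner[2], x$inner[3], x$inner[4],
    roi_point_count(x)
  ))
  invisible(x)
}

#' Rescale an ROI frame to a coarser or finer lattice
#'
#' Multiplies every bound by `factor` and rounds to the nearest lattice
#' point, preserving strict containment. Used to run the same annular-frame
#' geometry on reduced lattices.
#'
#' @param roi A [roi_frame()].
#' @param factor Positive scale factor (new lattice width / old width).
#' @return A [roi_frame()].
#' @export
scale_roi <- function(roi, factor) {
  stopifnot(inherits(roi, "roi_frame"), factor > 0)
  roi_frame(round(roi$outer * factor), round(roi$inner * factor))
}

#' Number of lattice points in an ROI frame
#'
#' Closed-form count: outer area minus the open interior of the inner
#' rectangle.
#' @param roi A [roi_frame()].
#' @return Integer point count.
#' @export
roi_point_count <- function(roi) {
  o <- roi$outer; i <- roi$inner
  outer_n <- (o[2] - o[1] + 1L) * (o[4] - o[3] + 1L)
  ix <- max(0L, i[2] - i[1] - 1L)
  iy <- max(0L, i[4] - i[3] - 1L)
  outer_n - ix * iy
}

roi_contains_point <- function(roi, x, y) {
  o <- roi$outer; i <- roi$inner
  in_outer <- x >= o[1] & x <= o[2] & y >= o[3] & y <= o[4]
  in_inner_open <- x > i[1] & x < i[2] & y > i[3] & y < i[4]
  in_outer & !in_inner_open
}

#' Extract the ROI lattice points of a grid
#'
#' Retains every lattice point inside the outer rectangle (boundary
#' inclusive) except points strictly interior to the inner rectangle (the
#' inner boundary is kept), together with the grid value at each point.
#'
#' @param grid A [thickness_grid()].
#' @param roi A [roi_frame()].
#' @return A tibble with columns `x`, `y` (0-based lattice coordinates) and
#'   `value`.
#' @export
extract_roi <- function(grid, roi) {
  stopifnot(inherits(grid, "thickness_grid"), inherits(roi, "roi_frame"))
  o <- roi$outer
  if (o[1] < 0L || o[3] < 0L || o[2] >= grid$width || o[4] >= grid$height) {
    stop("ROI exceeds grid bounds", call. = FALSE)
  }
  xs <- o[1]:o[2]; ys <- o[3]:o[4]
  pts <- expand.grid(x = xs, y = ys)
  keep <- roi_contains_point(roi, pts$x, pts$y)
  pts <- pts[keep, , drop = FALSE]
  tibble::tibble(
    x = pts$x, y = pts$y,
    value = grid_value_at(grid, pts$x, pts$y)
  )
}
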