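#' Rectangular observation window
#'
#' Axis-aligned rectangular window in planar metric coordinates (metres).
#' This is the only window shape supported: the motivating study plots are
#' rectangular, and all edge corrections in the package (translation,
#' Kaplan-Meier, border) assume a rectangle.
#'
#' @param xrange,yrange Numeric vectors of length 2 giving the extent of the
#'   window on each axis, in metres.  Must be strictly increasing.
#'
#' @return An object of class `"rect_window"` with elements `xrange` and
#'   `yrange`.
#' @examples
#' w <- rect_window(c(0, 397), c(0, 220))
#' window_area(w)
#' @export
rect_window <- function(xrange, yrange) {
  xrange <- as.numeric(xrange)
  yrange <- as.numeric(yrange)
  if (length(xrange) != 2L || length(yrange) != 2L)
    stop("'xrange' and 'yrange' must each have length 2")
  if (!all(is.finite(c(xrange, yrange))))
    stop("window limits must be finite")
  if (diff(xrange) <= 0 || diff(yrange) <= 0)
    stop("window must have positive extent on both axes")
  structure(list(xrange = xrange, yrange = yrange), class = "rect_window")
}

#' @export
print.rect_window <- function(x, ...) {
  cat(sprintf("rectangular window [%g, %g] x [%g, %g] m (area %g m^2)\n",
              x$xrange[1], x$xrange[2], x$yrange[1], x$yrange[2],
              window_area(x)))
  invisible(x)
}

#' Window area in square metres
#' @param window A [rect_window()].
#' @return Numeric scalar, the window area.
#' @export
window_area <- function(window) {
  diff(window$xrange) * diff(window$yrange)
}

window_sides <- function(window) {
  c(diff(window$xrange), diff(window$yrange))
}

#' Test whether locations fall inside a window
#' @param window A [rect_window()].
#' @param x,y Coordinate vectors (metres).
#' @return Logical vector.
#' @export
inside_window <- function(window, x, y) {
  x >= window$xrange[1] & x <= window$xrange[2] &
    y >= window$yrange[1] & y <= window$yrange[2]
}

#' Distance from locations to the window boundary
#'
#' Shortest distance from each point to any of the four edges of the
#' rectangle.  Used as the censoring distance in the Kaplan-Meier edge
#' correction of the nearest-neighbour distance distribution.
#'
#' @param window A [rect_window()].
#' @param x,y Coordinate vectors (metres); all points must lie inside the
#'   window.
#' @return Numeric vector of distances (metres).
#' @examples
#' boundary_distance(rect_window(c(0, 100), c(0, 100)), 5, 3)  # 3
#' @export
boundary_distance <- function(window, x, y) {
  if (!all(inside_window(window, x, y)))
    stop("all points must lie inside the window")
  pmin(x - window$xrange[1], window$xrange[2] - x,
       y - window$yrange[1], window$yrange[2] - y)
}
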