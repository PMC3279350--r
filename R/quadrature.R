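#' Berman-Turner quadrature scheme
#'
#' Discretises the pseudolikelihood integral onto nodes: the data points plus
#' a regular grid of dummy points per type.  Weights follow the counting rule:
#' the window is tiled with rectangles of (approximately) `dummy_spacing`
#' metres a side, and each node's weight is the area of its tile divided by
#' the number of nodes of the same type in that tile.  Weights therefore sum
#' exactly to the window area for every type.
#'
#' @param pattern A [tpp()] pattern.
#' @param dummy_spacing Requested tile side (metres); the actual tile sides
#'   divide the window exactly.
#' @param types Types to build nodes for (default: the pattern's levels).
#' @return A `data.frame` with columns `x`, `y`, `type`, `is_data`, `weight`,
#'   of class `"quadrature"`.
#' @export
make_quadrature <- function(pattern, dummy_spacing = 10,
                            types = levels(pattern$type)) {
  w <- pattern$window
  sides <- window_sides(w)
  if (dummy_spacing <= 0) stop("'dummy_spacing' must be positive")
  if (dummy_spacing > max(sides))
    stop("'dummy_spacing' exceeds the window size")
  nx <- max(1L, round(sides[1] / dummy_spacing))
  ny <- max(1L, round(sides[2] / dummy_spacing))
  sx <- sides[1] / nx
  sy <- sides[2] / ny
  tile_area <- sx * sy
  gx <- w$xrange[1] + (seq_len(nx) - 0.5) * sx
  gy <- w$yrange[1] + (seq_len(ny) - 0.5) * sy
  dummy <- expand.grid(x = gx, y = gy)

  tile_id <- function(x, y) {
    ix <- pmin(pmax(ceiling((x - w$xrange[1]) / sx), 1L), nx)
    iy <- pmin(pmax(ceiling((y - w$yrange[1]) / sy), 1L), ny)
    (iy - 1L) * nx + ix
  }

  out <- vector("list", length(types))
  for (k in seq_along(types)) {
    ty <- types[k]
    dat <- type_coords(pattern, ty)
    x <- c(dat[, 1], dummy$x)
    y <- c(dat[, 2], dummy$y)
    is_data <- c(rep(TRUE, nrow(dat)), rep(FALSE, nrow(dummy)))
    tid <- tile_id(x, y)
    counts <- tabulate(tid, nbins = nx * ny)
    out[[k]] <- data.frame(x = x, y = y, type = ty, is_data = is_data,
                           weight = tile_area / counts[tid])
  }
  q <- do.call(rbind, out)
  q$type <- factor(q$type, levels = types)
  rownames(q) <- NULL
  class(q) <- c("quadrature", "data.frame")
  attr(q, "window") <- w
  q
}
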