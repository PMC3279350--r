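#' Distance-to-nearest-reference spatial covariate
#'
#' A spatial covariate whose value at a location is the exact Euclidean
#' distance to the nearest of a fixed set of reference points (for example
#' unoccupied mounds, or established colonies).  The field is evaluated
#' exactly at query locations, never gridded, and is 1-Lipschitz by
#' construction.
#'
#' @param x,y Reference point coordinates (metres); `x` may alternatively be a
#'   two-column matrix.  At least one reference point is required.
#' @return An object of class `"distance_covariate"`.
#' @examples
#' dc <- distance_covariate(0, 0)
#' eval_covariate(dc, 3, 4)  # 5
#' @export
distance_covariate <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2L)
    refs <- x
  } else {
    refs <- cbind(x, y)
  }
  storage.mode(refs) <- "double"
  if (nrow(refs) < 1L)
    stop("at least one reference point is required")
  colnames(refs) <- c("x", "y")
  structure(list(refs = refs), class = "distance_covariate")
}

#' @export
print.distance_covariate <- function(x, ...) {
  cat(sprintf("distance covariate: nearest of %d reference point(s)\n",
              nrow(x$refs)))
  invisible(x)
}

#' Evaluate a distance covariate at query locations
#' @param covariate A [distance_covariate()].
#' @param x,y Query coordinates (metres).
#' @return Numeric vector of distances to the nearest reference point.
#' @export
eval_covariate <- function(covariate, x, y) {
  d <- cross_dist(cbind(x, y), covariate$refs)
  unname(apply(d, 1, min))
}
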