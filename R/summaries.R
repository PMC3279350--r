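#' Distance grid for summary statistics
#'
#' Evenly spaced distance grid starting at 0.  The defaults (0 to 20 m in
#' 0.1 m steps) match the scales at which mound--colony interactions are
#' expected to act.
#'
#' @param rmax Maximum distance (metres).
#' @param step Grid step (metres).
#' @return Numeric vector of distances.
#' @export
r_grid <- function(rmax = 20, step = 0.1) {
  seq(0, rmax, by = step)
}

#' Construct a summary-function object
#'
#' Container for a spatial summary statistic evaluated on a distance grid.
#' Mostly produced by [k_translation()], [center_l()] and [g_nearest_km()],
#' but exported so theoretical curves (e.g. the Poisson K) can be wrapped
#' for comparison.
#'
#' @param statistic Statistic label, e.g. `"K"`, `"L_KA"`, `"G_AK"`.
#' @param r Distance grid (metres).
#' @param values Statistic values, one per grid point.
#' @param ... Metadata fields (types involved, edge correction, counts).
#' @return An object of class `"summary_function"`.
#' @export
summary_function <- function(statistic, r, values, ...) {
  structure(list(statistic = statistic, r = r, values = values,
                 meta = list(...)),
            class = "summary_function")
}

#' @export
print.summary_function <- function(x, ...) {
  cat(sprintf("summary function %s on r in [%g, %g] m (%d values)\n",
              x$statistic, min(x$r), max(x$r), length(x$r)))
  if (length(x$meta))
    cat("  ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                    sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.summary_function <- function(x, ...) {
  data.frame(r = x$r, value = x$values)
}

#' Write a summary function to CSV
#' @param x A summary function (from [k_translation()], [center_l()],
#'   [g_nearest_km()]).
#' @param path Output file path; columns `r,value`.
#' @return Invisibly, the path.
#' @export
write_summary <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ripley K function with translation edge correction
#'
#' Estimates the (cross-type or univariate) K function
#' \deqn{\hat K_{ij}(r) = \sum_{u \ne v} \frac{1\{d_{uv} \le r\}}
#'   {\hat\lambda_i \hat\lambda_j \, w(\Delta_{uv})}}
#' summing over ordered pairs with a point of `type_i` first and `type_j`
#' second, with intensity estimates \eqn{\hat\lambda = n/|W|} and translation
#' weight \eqn{w(\Delta) = (a - |\Delta x|)(b - |\Delta y|)} for window sides
#' \eqn{a, b}.  For `type_i == type_j` each unordered pair contributes twice
#' and the denominator uses \eqn{\hat\lambda^2} (not the \eqn{n(n-1)}
#' variant), the simplest convention consistent with the centred-L
#' interpretation.
#'
#' @param pattern A [tpp()] pattern in a rectangular window.
#' @param type_i,type_j Type labels ("K" totals, around each `type_i` point,
#'   the `type_j` points within distance r).
#' @param r Distance grid from [r_grid()].
#' @return A summary function with statistic `"K"` (univariate) or `"K_KA"`
#'   style cross label.
#' @seealso [center_l()] for the centred L transform.
#' @export
k_translation <- function(pattern, type_i, type_j, r = r_grid()) {
  same <- identical(as.character(type_i), as.character(type_j))
  ci <- type_coords(pattern, type_i)
  cj <- type_coords(pattern, type_j)
  ni <- nrow(ci); nj <- nrow(cj)
  if (ni < 1L || nj < 1L || (same && ni < 2L))
    stop("not enough points of the requested types")
  A <- window_area(pattern$window)
  sides <- window_sides(pattern$window)
  lami <- ni / A
  lamj <- nj / A

  dx <- abs(outer(ci[, 1], cj[, 1], "-"))
  dy <- abs(outer(ci[, 2], cj[, 2], "-"))
  d <- sqrt(dx^2 + dy^2)
  if (same) {
    keep <- row(d) != col(d)
  } else {
    keep <- rep(TRUE, length(d))
  }
  dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
  stopifnot(all(dx < sides[1]), all(dy < sides[2]))
  w <- (sides[1] - dx) * (sides[2] - dy)
  contrib <- 1 / (lami * lamj * w)

  ord <- order(d)
  cc <- cumsum(contrib[ord])
  idx <- findInterval(r, d[ord])
  K <- c(0, cc)[idx + 1L]

  stat <- if (same) "K" else paste0("K_", type_i, type_j)
  summary_function(stat, r, K,
                   type_i = type_i, type_j = type_j,
                   correction = "translation", n_i = ni, n_j = nj)
}

#' Centred L function
#'
#' Transforms a K function into \eqn{L(r) = \sqrt{K(r)/\pi} - r}: zero under
#' complete spatial randomness, positive for aggregation, negative for
#' regularity.  Where K is 0 the formula gives \eqn{-r}, with no special
#' casing.
#'
#' @param K A summary function with nonnegative values (from
#'   [k_translation()]).
#' @return A summary function with statistic `"L"` (or `"L_KA"` style label).
#' @export
center_l <- function(K) {
  if (any(K$values < 0)) stop("K values must be nonnegative")
  stat <- sub("^K", "L", K$statistic)
  out <- summary_function(stat, K$r, sqrt(K$values / pi) - K$r)
  out$meta <- K$meta
  out
}

#' Centred L with translation correction, in one call
#' @inheritParams k_translation
#' @return A summary function with statistic `"L"` or `"L_KA"` style label.
#' @export
l_translation <- function(pattern, type_i, type_j, r = r_grid()) {
  center_l(k_translation(pattern, type_i, type_j, r))
}

#' Nearest-neighbour distance distribution G with Kaplan-Meier correction
#'
#' Cumulative distribution of the distance from each `from_type` point to the
#' nearest `to_type` point, treating distances exceeding the point's distance
#' to the window boundary as right-censored and applying the product-limit
#' (Kaplan-Meier) estimator.  Deaths at equal distances are aggregated at one
#' event time, and censored observations tied with deaths remain at risk
#' through that time (the standard convention).
#'
#' @param pattern A [tpp()] pattern.
#' @param from_type,to_type Type labels.
#' @param r Distance grid from [r_grid()].
#' @return A summary function with values in `[0, 1]`, nondecreasing in r.
#'   If every observation is censored the estimate is identically 0, with a
#'   warning.
#' @export
g_nearest_km <- function(pattern, from_type, to_type, r = r_grid()) {
  d <- nndist_type(pattern, from_type, to_type)
  keep <- pattern$type == from_type
  cens <- boundary_distance(pattern$window, pattern$x[keep], pattern$y[keep])
  tt <- pmin(d, cens)
  event <- d <= cens
  stat <- paste0("G_", from_type, to_type)
  if (!any(event)) {
    warning("all nearest-neighbour distances censored by the boundary; ",
            "G is identically 0")
    return(summary_function(stat, r, rep(0, length(r)),
                            from = from_type, to = to_type,
                            correction = "km", n_from = length(d)))
  }
  s <- sort(unique(tt[event]))
  at_risk <- vapply(s, function(si) sum(tt >= si), numeric(1))
  deaths <- vapply(s, function(si) sum(tt == si & event), numeric(1))
  surv <- cumprod(1 - deaths / at_risk)
  G_at_event <- 1 - surv
  idx <- findInterval(r, s)
  G <- c(0, G_at_event)[idx + 1L]
  G <- pmin(pmax(G, 0), 1)
  summary_function(stat, r, G,
                   from = from_type, to = to_type,
                   correction = "km", n_from = length(d),
                   n_events = sum(event))
}
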