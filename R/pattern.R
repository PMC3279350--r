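#' Typed (multitype) point pattern in a rectangular window
#'
#' Container for mapped structure locations with a categorical type per point
#' (e.g. `"K"` for kangaroo-rat mounds and `"A"` for harvester-ant colonies)
#' and optional mark columns (disc diameter, occupancy, cohort, survival).
#' Coordinates are continuous planar metres; no projection handling is done.
#'
#' Two points of the same type closer than `dup_tol` are rejected: the
#' hard-core models in this package forbid coincident structures, and
#' duplicate coordinates almost always indicate a data error.
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @param type Character or factor vector of point types, one per point.
#' @param window A [rect_window()] containing all points.
#' @param marks Optional `data.frame` of per-point mark columns.
#' @param dup_tol Duplicate tolerance in metres (default `1e-6`): same-type
#'   pairs closer than this are an error.
#'
#' @return An object of class `"tpp"`: a list with elements `x`, `y`, `type`
#'   (factor), `marks` (data.frame or `NULL`) and `window`.
#' @examples
#' w <- rect_window(c(0, 100), c(0, 100))
#' p <- tpp(c(10, 50, 80), c(20, 50, 90), c("K", "A", "A"), w)
#' npoints(p)
#' @export
tpp <- function(x, y, type, window, marks = NULL, dup_tol = 1e-6) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || length(type) != n)
    stop("'x', 'y' and 'type' must have the same length")
  if (!inherits(window, "rect_window"))
    stop("'window' must be a rect_window object")
  if (n > 0 && !all(inside_window(window, x, y)))
    stop("all points must lie inside the window")
  if (!is.factor(type)) type <- factor(type)
  if (!is.null(marks)) {
    marks <- as.data.frame(marks)
    if (nrow(marks) != n)
      stop("'marks' must have one row per point")
  }
  obj <- structure(list(x = x, y = y, type = type, marks = marks,
                        window = window),
                   class = "tpp")
  for (lev in levels(type)) {
    idx <- which(type == lev)
    if (length(idx) >= 2L) {
      d <- dist(cbind(x[idx], y[idx]))
      if (any(d < dup_tol))
        stop(sprintf(
          "duplicate points of type '%s' within tolerance %g m", lev, dup_tol))
    }
  }
  obj
}

#' @export
print.tpp <- function(x, ...) {
  cat(sprintf("typed point pattern: %d points\n", npoints(x)))
  print(table(x$type))
  if (!is.null(x$marks))
    cat("marks:", paste(names(x$marks), collapse = ", "), "\n")
  print(x$window)
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern A [tpp()] pattern.
#' @param type Optional type label; if given, count only that type.
#' @return Integer count.
#' @export
npoints <- function(pattern, type = NULL) {
  if (is.null(type)) length(pattern$x) else sum(pattern$type == type)
}

#' Extract the sub-pattern of one or more types
#' @param pattern A [tpp()] pattern.
#' @param types Character vector of type labels to keep.
#' @param drop_levels Drop unused factor levels in the result (default TRUE).
#' @return A [tpp()] containing only the requested types (marks subset too).
#' @export
subset_type <- function(pattern, types, drop_levels = TRUE) {
  keep <- pattern$type %in% types
  ty <- pattern$type[keep]
  if (drop_levels) ty <- droplevels(ty)
  tpp(pattern$x[keep], pattern$y[keep], ty, pattern$window,
      marks = if (is.null(pattern$marks)) NULL else
        pattern$marks[keep, , drop = FALSE])
}

type_coords <- function(pattern, type) {
  keep <- pattern$type == type
  cbind(x = pattern$x[keep], y = pattern$y[keep])
}

#' Read a typed point pattern from a delimited text file
#'
#' Reads a comma- or tab-delimited table with header columns `x`, `y`, `type`;
#' any further columns are attached as marks by name.  The delimiter is
#' auto-detected from the header line.
#'
#' @param path Path to the text file.
#' @param window A [rect_window()] the points are expected to lie in.
#' @param strict If `TRUE` (default) a point outside the window is an error;
#'   if `FALSE` such rows are dropped with a message.
#' @param dup_tol Duplicate tolerance passed to [tpp()].
#' @return A [tpp()] pattern.
#' @seealso [write_pattern()]
#' @export
read_pattern <- function(path, window, strict = TRUE, dup_tol = 1e-6) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("x", "y", "type")
  if (!all(required %in% names(df)))
    stop("file must have header columns x, y, type (found: ",
         paste(names(df), collapse = ", "), ")")
  ok <- inside_window(window, df$x, df$y)
  if (!all(ok)) {
    if (strict)
      stop(sprintf("%d point(s) fall outside the window", sum(!ok)))
    message(sprintf("dropping %d point(s) outside the window", sum(!ok)))
    df <- df[ok, , drop = FALSE]
  }
  extra <- setdiff(names(df), required)
  tpp(df$x, df$y, df$type, window,
      marks = if (length(extra)) df[, extra, drop = FALSE] else NULL,
      dup_tol = dup_tol)
}

#' Write a typed point pattern to CSV
#' @param pattern A [tpp()] pattern.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pattern <- function(pattern, path) {
  df <- data.frame(x = pattern$x, y = pattern$y,
                   type = as.character(pattern$type))
  if (!is.null(pattern$marks)) df <- cbind(df, pattern$marks)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise distance matrix between two types
#'
#' Euclidean distances between all points of `type_i` (rows) and all points of
#' `type_j` (columns).  Symmetric with a zero diagonal when the types are
#' equal.  Empty types give a matrix with zero extent, not an error.
#'
#' @param pattern A [tpp()] pattern.
#' @param type_i,type_j Type labels.
#' @return A numeric matrix of distances in metres.
#' @export
pairdist_matrix <- function(pattern, type_i, type_j) {
  ci <- type_coords(pattern, type_i)
  cj <- type_coords(pattern, type_j)
  cross_dist(ci, cj)
}

# distances between rows of two 2-column coordinate matrices
cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Nearest-neighbour distances from one type to another
#'
#' For each point of `from_type`, the distance to the nearest point of
#' `to_type`; when the two types are equal the point itself is excluded.
#'
#' @param pattern A [tpp()] pattern.
#' @param from_type,to_type Type labels.
#' @return Numeric vector, one entry per `from_type` point.
#' @export
nndist_type <- function(pattern, from_type, to_type) {
  ci <- type_coords(pattern, from_type)
  cj <- type_coords(pattern, to_type)
  same <- identical(as.character(from_type), as.character(to_type))
  if (nrow(ci) == 0L)
    stop(sprintf("no points of type '%s' in the pattern", from_type))
  if (nrow(cj) < 1L + same)
    stop(sprintf("too few points of type '%s' to compute nearest neighbours",
                 to_type))
  d <- cross_dist(ci, cj)
  if (same) diag(d) <- Inf
  unname(apply(d, 1, min))
}
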