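#' Multitype Strauss hard-core (MSHC) model
#'
#' Container for the parameters of a multitype Strauss hard-core Gibbs point
#' process.  The conditional intensity of adding a point of type \eqn{m} at
#' location \eqn{u} given the pattern \eqn{x} is
#' \deqn{\lambda((u,m) \mid x) = \beta_m \exp\Big(\sum_c \theta_c Z_c(u)\Big)
#'   \prod_p \gamma_p^{t_p(u)}}
#' where \eqn{t_p(u)} counts points of the pair-opposing type at distances
#' \eqn{d} with \eqn{h_p < d \le r_p}, and the intensity is 0 whenever any
#' relevant point lies within the hard-core distance \eqn{h_p} of \eqn{u}
#' (closed at \eqn{h}: \eqn{d \le h_p} is forbidden).  Interaction triples
#' `(h, r, gamma)` are symmetric per unordered type pair: `gamma > 1` encodes
#' attraction, `gamma = 1` no interaction, `0 <= gamma < 1` repulsion.
#'
#' Unknown values to be estimated by [fit_mshc()] are entered as `NA`
#' (typically `beta`, `gamma` and covariate coefficients); `h` and `r` are
#' irregular parameters, fixed here and profiled with
#' [profile_irregulars()].
#'
#' @param types Character vector of point types (default `c("K", "A")`).
#' @param beta Named numeric vector of first-order intensities per type
#'   (points per square metre); `NA` to estimate.
#' @param interactions A `data.frame` with columns `type1`, `type2`, `h`, `r`,
#'   `gamma`, one row per unordered type pair carrying an interaction.  `h` in
#'   metres (>= 0), `r > h` in metres unless the row is a pure hard core
#'   (`gamma == 1`, where `r == h` is allowed), `gamma >= 0` or `NA` to
#'   estimate.
#' @param covariates Named list; each element is a list with components `cov`
#'   (a [distance_covariate()]), `types` (which types' intensity it enters)
#'   and `coef` (numeric, or `NA` to estimate).
#' @return An object of class `"mshc_model"`.
#' @examples
#' m <- mshc_model(
#'   beta = c(K = 5e-4, A = 3e-3),
#'   interactions = data.frame(
#'     type1 = c("K", "A", "K"), type2 = c("K", "A", "A"),
#'     h = c(10, 4, 1), r = c(30, 20, 5.1), gamma = c(0.2, 0.5, 3.7)))
#' @export
mshc_model <- function(types = c("K", "A"), beta = NULL,
                       interactions = NULL, covariates = list()) {
  types <- as.character(types)
  if (is.null(beta)) beta <- setNames(rep(NA_real_, length(types)), types)
  if (is.null(names(beta)) || !setequal(names(beta), types))
    stop("'beta' must be named with exactly the model types")
  beta <- beta[types]
  if (any(!is.na(beta) & beta <= 0)) stop("'beta' values must be positive")

  if (!is.null(interactions)) {
    interactions <- as.data.frame(interactions)
    need <- c("type1", "type2", "h", "r", "gamma")
    if (!all(need %in% names(interactions)))
      stop("'interactions' needs columns type1, type2, h, r, gamma")
    interactions$type1 <- as.character(interactions$type1)
    interactions$type2 <- as.character(interactions$type2)
    if (!all(c(interactions$type1, interactions$type2) %in% types))
      stop("interaction types must be among the model types")
    # canonical unordered pair order
    swap <- interactions$type1 > interactions$type2
    tmp <- interactions$type1[swap]
    interactions$type1[swap] <- interactions$type2[swap]
    interactions$type2[swap] <- tmp
    key <- paste(interactions$type1, interactions$type2)
    if (anyDuplicated(key)) stop("duplicate interaction pairs")
    if (any(interactions$h < 0)) stop("hard-core distances must be >= 0")
    pure_hc <- !is.na(interactions$gamma) & interactions$gamma == 1
    bad <- ifelse(pure_hc, interactions$r < interactions$h,
                  interactions$r <= interactions$h)
    if (any(bad))
      stop("interaction distance r must exceed hard-core distance h")
    if (any(!is.na(interactions$gamma) & interactions$gamma < 0))
      stop("'gamma' must be >= 0")
    rownames(interactions) <- paste0(interactions$type1, interactions$type2)
  }

  if (length(covariates)) {
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      stop("'covariates' must be a named list")
    for (nm in names(covariates)) {
      cv <- covariates[[nm]]
      if (!inherits(cv$cov, "distance_covariate"))
        stop("each covariate needs a distance_covariate in $cov")
      if (is.null(cv$types)) covariates[[nm]]$types <- types
      else if (!all(cv$types %in% types))
        stop("covariate types must be among the model types")
      if (is.null(cv$coef)) covariates[[nm]]$coef <- NA_real_
    }
  }

  structure(list(types = types, beta = beta, interactions = interactions,
                 covariates = covariates),
            class = "mshc_model")
}

#' @export
print.mshc_model <- function(x, ...) {
  cat("multitype Strauss hard-core model\n")
  cat("  types:", paste(x$types, collapse = ", "), "\n")
  cat("  beta:", paste(names(x$beta), signif(x$beta, 4),
                       sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$interactions)) {
    cat("  interactions:\n")
    print(x$interactions, row.names = FALSE)
  }
  if (length(x$covariates))
    cat("  covariates:",
        paste(sprintf("%s (types %s, coef %s)", names(x$covariates),
                      vapply(x$covariates, function(c)
                        paste(c$types, collapse = ""), ""),
                      vapply(x$covariates, function(c)
                        format(signif(c$coef, 4)), "")),
              collapse = "; "), "\n")
  invisible(x)
}

# M x M matrices of squared h, squared r and log gamma, with sentinel -1 for
# inactive pairs so `d2 <= h2` / `d2 <= r2` can never fire.
pair_matrices <- function(model) {
  M <- length(model$types)
  h2 <- matrix(-1, M, M, dimnames = list(model$types, model$types))
  r2 <- h2
  lg <- matrix(0, M, M, dimnames = list(model$types, model$types))
  ia <- model$interactions
  if (!is.null(ia)) {
    for (i in seq_len(nrow(ia))) {
      a <- ia$type1[i]; b <- ia$type2[i]
      h2[a, b] <- h2[b, a] <- ia$h[i]^2
      r2[a, b] <- r2[b, a] <- ia$r[i]^2
      lg[a, b] <- lg[b, a] <- log(ia$gamma[i])
    }
  }
  list(h2 = h2, r2 = r2, loggamma = lg)
}

#' Count interaction-annulus neighbours of a location
#'
#' The sufficient statistic \eqn{t_p(u)} of the MSHC model: the number of
#' pattern points of the pair-opposing type at distance \eqn{d} from `(x, y)`
#' with \eqn{h < d \le r}.  A pattern point coincident with the query
#' location (distance 0) is excluded by the strict lower bound whenever
#' `h >= 0`.
#'
#' @param x,y Query location (metres).
#' @param type Type of the (hypothetical) point at the query location.
#' @param pattern A [tpp()] pattern.
#' @param pair Character vector of the two types of the interaction pair,
#'   e.g. `c("K", "A")` or `c("K", "K")`.
#' @param h,r Hard-core and interaction distances (metres), `h < r`.
#' @return Nonnegative integer count.
#' @export
pair_count <- function(x, y, type, pattern, pair, h, r) {
  stopifnot(h < r)
  pair <- as.character(pair)
  if (!as.character(type) %in% pair) return(0L)
  other <- if (pair[1] == pair[2]) pair[1]
           else pair[pair != as.character(type)]
  co <- type_coords(pattern, other)
  if (nrow(co) == 0L) return(0L)
  d <- sqrt((co[, 1] - x)^2 + (co[, 2] - y)^2)
  sum(d > h & d <= r)
}

#' Conditional intensity of an MSHC model
#'
#' Papangelou conditional intensity \eqn{\lambda((u,m)\mid x)} of adding a
#' point of type `type` at each query location, given `pattern`.  Returns 0
#' where a hard core is violated (or where an occupied annulus carries
#' `gamma = 0`, its valid limit).
#'
#' @param model An [mshc_model()] with all parameter values filled in.
#' @param pattern A [tpp()] pattern (the conditioning configuration).
#' @param x,y Query coordinates (metres).
#' @param type Type of the added point.
#' @return Numeric vector of nonnegative intensities.
#' @export
conditional_intensity <- function(model, pattern, x, y, type) {
  type <- as.character(type)
  stopifnot(type %in% model$types)
  if (any(is.na(model$beta)))
    stop("model has unestimated beta values")
  if (!is.null(model$interactions) && any(is.na(model$interactions$gamma)))
    stop("model has unestimated gamma values")
  q <- cbind(x, y)
  nq <- nrow(q)
  loglam <- rep(log(model$beta[[type]]), nq)
  pm <- pair_matrices(model)
  for (tj in model$types) {
    h2 <- pm$h2[type, tj]
    r2 <- pm$r2[type, tj]
    if (r2 < 0) next
    co <- type_coords(pattern, tj)
    if (nrow(co) == 0L) next
    d2 <- cross_dist(q, co)^2
    hard <- rowSums(d2 <= h2) > 0
    tcount <- rowSums(d2 > h2 & d2 <= r2)
    lg <- pm$loggamma[type, tj]
    contrib <- tcount * lg
    contrib[tcount == 0] <- 0  # avoid 0 * -Inf when gamma == 0
    loglam <- loglam + ifelse(hard, -Inf, contrib)
  }
  for (cv in model$covariates) {
    if (!(type %in% cv$types)) next
    if (is.na(cv$coef)) stop("model has unestimated covariate coefficients")
    loglam <- loglam + cv$coef * eval_covariate(cv$cov, q[, 1], q[, 2])
  }
  unname(exp(loglam))
}
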