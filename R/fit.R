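# Maximum pseudolikelihood fitting of MSHC models via the Berman-Turner
# device: the discretised log-pseudolikelihood is a weighted Poisson
# log-linear score, maximised with stats::glm.fit.

# Build the design matrix at the quadrature nodes.  Columns:
#   log beta_m   -- one indicator column per type
#   covariates   -- value * indicator(node type in covariate's types)
#   log gamma_p  -- annulus pair count t_p(u) for each estimated interaction
# Fixed (non-NA) gammas and coefficients contribute to an offset instead.
mshc_design <- function(pattern, model, quad) {
  types <- model$types
  n_nodes <- nrow(quad)
  X <- list()
  offset <- rep(0, n_nodes)

  for (ty in types)
    X[[paste0("log_beta_", ty)]] <- as.numeric(quad$type == ty)

  for (nm in names(model$covariates)) {
    cv <- model$covariates[[nm]]
    val <- eval_covariate(cv$cov, quad$x, quad$y) *
      as.numeric(quad$type %in% cv$types)
    if (is.na(cv$coef)) X[[nm]] <- val
    else offset <- offset + cv$coef * val
  }

  infeasible <- rep(FALSE, n_nodes)
  ia <- model$interactions
  if (!is.null(ia)) {
    for (i in seq_len(nrow(ia))) {
      t1 <- ia$type1[i]; t2 <- ia$type2[i]
      h <- ia$h[i]; r <- ia$r[i]
      tcol <- rep(0, n_nodes)
      for (side in unique(c(t1, t2))) {
        other <- if (t1 == t2) t1 else setdiff(c(t1, t2), side)
        rows <- which(quad$type == side)
        if (!length(rows)) next
        co <- type_coords(pattern, other)
        if (nrow(co) == 0L) next
        d <- cross_dist(cbind(quad$x[rows], quad$y[rows]), co)
        viol_count <- rowSums(d <= h)
        if (other == side) {
          # a data node sits at distance 0 from itself in the opposing set;
          # discount that self pair (same-type pairs only)
          viol_count <- viol_count - as.numeric(quad$is_data[rows])
        }
        infeasible[rows] <- infeasible[rows] | (viol_count > 0)
        tcol[rows] <- tcol[rows] + rowSums(d > h & d <= r)
      }
      key <- paste0("log_gamma_", t1, t2)
      if (is.na(ia$gamma[i])) X[[key]] <- tcol
      else if (ia$gamma[i] != 1) offset <- offset + log(ia$gamma[i]) * tcol
    }
  }

  list(X = do.call(cbind, X), offset = offset, infeasible = infeasible)
}

empty_fit <- function(model, pattern, reason, k = NA_integer_) {
  structure(list(model = model, logPL = -Inf, k = k, n = npoints(pattern),
                 aicc = Inf, converged = FALSE, feasible = FALSE,
                 coef = NULL, reason = reason),
            class = "mshc_fit")
}

#' Fit an MSHC model by maximum pseudolikelihood
#'
#' Maximises the Berman-Turner discretised log-pseudolikelihood
#' \deqn{\log PL(\theta) = \sum_i \log\lambda_\theta(x_i)
#'   - \sum_j w_j \lambda_\theta(u_j)}
#' over the regular parameters (log intensities, covariate coefficients, log
#' interaction strengths) by iteratively reweighted least squares on the
#' equivalent weighted Poisson log-linear score.  The irregular parameters
#' `h` and `r` of each interaction are held fixed (profile them with
#' [profile_irregulars()]).  If any pair of data points violates a hard core
#' the model is infeasible and the fit returns `logPL = -Inf`, flagged.
#'
#' Edge handling: `correction = "border"` (default) restricts the score to
#' nodes at least `rbord` (the largest interaction distance in the model)
#' from the window boundary, so every retained node has a fully observed
#' interaction neighbourhood; `"none"` uses all nodes.
#'
#' An interaction whose annulus count is zero at every node carries no
#' information; its column is dropped with a warning, the corresponding
#' gamma is reported as 1 and it is not counted in `k`.
#'
#' @param pattern A [tpp()] pattern.
#' @param model An [mshc_model()]; `NA` parameters are estimated.
#' @param dummy_spacing Dummy grid spacing (metres) for [make_quadrature()].
#' @param correction `"border"` or `"none"`.
#' @param quad Optional precomputed quadrature scheme.
#' @return An object of class `"mshc_fit"`: the fitted model, `logPL`, the
#'   regular-parameter count `k`, `n` (number of data points), `aicc`,
#'   Akaike-weight-ready, convergence flags and the coefficient vector.
#' @seealso [pl_ratio()], [mc_lr_test()], [aicc()]
#' @export
fit_mshc <- function(pattern, model, dummy_spacing = 10,
                     correction = c("border", "none"), quad = NULL) {
  correction <- match.arg(correction)
  if (is.null(quad))
    quad <- make_quadrature(pattern, dummy_spacing, types = model$types)

  if (correction == "border") {
    rbord <- if (is.null(model$interactions)) 0 else max(model$interactions$r)
    if (rbord > 0) {
      keep <- boundary_distance(pattern$window, quad$x, quad$y) >= rbord
      quad <- quad[keep, , drop = FALSE]
      if (!any(quad$is_data))
        stop("border correction removed every data point; ",
             "reduce rbord or use correction = 'none'")
    }
  }

  des <- mshc_design(pattern, model, quad)
  if (any(des$infeasible & quad$is_data))
    return(empty_fit(model, pattern, "data violate a hard core"))
  keep <- !des$infeasible
  X <- des$X[keep, , drop = FALSE]
  offset <- des$offset[keep]
  w <- quad$weight[keep]
  is_data <- quad$is_data[keep]
  y <- as.numeric(is_data) / w

  dropped <- colnames(X)[apply(X == 0, 2, all)]
  if (length(dropped)) {
    warning("design column(s) with no information dropped: ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }

  fitg <- suppressWarnings(
    glm.fit(X, y, weights = w, offset = offset, family = poisson()))
  theta <- coef(fitg)
  bad <- is.na(theta)
  if (any(bad)) theta[bad] <- 0

  eta <- drop(X %*% theta) + offset
  logPL <- sum(eta[is_data]) - sum(w * exp(eta))
  k <- ncol(X)
  n <- npoints(pattern)

  fitted_model <- model
  for (ty in model$types) {
    key <- paste0("log_beta_", ty)
    if (key %in% names(theta)) fitted_model$beta[[ty]] <- exp(theta[[key]])
  }
  for (nm in names(model$covariates))
    if (nm %in% names(theta)) fitted_model$covariates[[nm]]$coef <- theta[[nm]]
  ia <- fitted_model$interactions
  if (!is.null(ia)) {
    for (i in seq_len(nrow(ia))) {
      key <- paste0("log_gamma_", ia$type1[i], ia$type2[i])
      if (key %in% names(theta))
        fitted_model$interactions$gamma[i] <- exp(theta[[key]])
      else if (key %in% dropped)
        fitted_model$interactions$gamma[i] <- 1
    }
  }

  structure(list(model = fitted_model, logPL = logPL, k = k, n = n,
                 aicc = aicc(logPL, k, n),
                 converged = isTRUE(fitg$converged), feasible = TRUE,
                 coef = theta, dropped = dropped,
                 correction = correction, dummy_spacing = dummy_spacing,
                 n_nodes = nrow(quad)),
            class = "mshc_fit")
}

#' @export
print.mshc_fit <- function(x, ...) {
  cat("MSHC maximum pseudolikelihood fit\n")
  if (!x$feasible) {
    cat("  INFEASIBLE:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  logPL = %.2f, k = %d, n = %d, AICc = %.2f%s\n",
              x$logPL, x$k, x$n, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coef, 5))
  invisible(x)
}

#' Akaike information criterion with small-sample correction
#'
#' \eqn{AIC_c = -2 \log PL + 2k + 2k(k+1)/(n-k-1)}.  With `n = Inf` the
#' correction vanishes and the plain AIC is returned.
#'
#' @param logPL Log-(pseudo)likelihood at the optimum.
#' @param k Number of estimated regular parameters.
#' @param n Sample size (number of points); must exceed `k + 1`.
#' @return Numeric criterion value.
#' @examples
#' aicc(-81.7, 4, Inf)  # plain AIC: 171.4
#' @export
aicc <- function(logPL, k, n) {
  if (is.infinite(n)) return(-2 * logPL + 2 * k)
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * logPL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min_j AIC_j}.
#'
#' @param aic Numeric vector of AIC (or AICc) values for the compared models.
#' @return Numeric weights summing to 1.
#' @export
aic_weights <- function(aic) {
  if (length(aic) < 2) stop("need at least two models to compare")
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Log-pseudolikelihood ratio between nested fits
#'
#' \eqn{\Delta = 2(\log PL_{full} - \log PL_{reduced})}.  A negative value
#' triggers a warning: for genuinely nested models it indicates an optimiser
#' failure on the full model.
#'
#' @param full,reduced `"mshc_fit"` objects, or raw log-pseudolikelihood
#'   values.
#' @return The statistic \eqn{\Delta}.
#' @examples
#' pl_ratio(-1755.5, -1780.7)  # 50.4
#' @export
pl_ratio <- function(full, reduced) {
  lf <- if (inherits(full, "mshc_fit")) full$logPL else full
  lr <- if (inherits(reduced, "mshc_fit")) reduced$logPL else reduced
  delta <- 2 * (lf - lr)
  if (is.finite(delta) && delta < 0)
    warning("negative pseudolikelihood ratio: full-model fit may have failed")
  delta
}

#' Profile the irregular parameters (h, r) of one interaction
#'
#' The hard-core distance `h` and interaction distance `r` enter the model
#' non-smoothly, so they are profiled by exhaustive grid search: the model is
#' refitted at every feasible `(h, r)` combination and the pair maximising
#' the log-pseudolikelihood is selected.  Profiled irregulars are not counted
#' in `k`.
#'
#' Default grids: `h` on 0 and just below the smallest observed
#' between-pair distance; `r` on 0.5 m steps over `(h, 15]`.
#'
#' @param pattern A [tpp()] pattern.
#' @param model An [mshc_model()] whose `interactions` include the pair.
#' @param pair Length-2 character vector naming the interaction pair to
#'   profile, e.g. `c("K", "A")`.
#' @param h_values,r_values Candidate grids (metres).  Combinations with
#'   `h >= r` are skipped.
#' @param ... Passed to [fit_mshc()].
#' @return A list of class `"mshc_profile"`: data.frame `grid` (h, r, logPL),
#'   the best `(h, r)`, and the refitted best model.
#' @export
profile_irregulars <- function(pattern, model, pair,
                               h_values = NULL, r_values = NULL, ...) {
  pair <- sort(as.character(pair))
  ia <- model$interactions
  row <- which(ia$type1 == pair[1] & ia$type2 == pair[2])
  if (length(row) != 1L)
    stop("the model has no interaction for pair ", paste(pair, collapse = ""))
  if (is.null(h_values)) {
    dmin <- if (pair[1] == pair[2]) {
      min(nndist_type(pattern, pair[1], pair[1]))
    } else min(cross_dist(type_coords(pattern, pair[1]),
                          type_coords(pattern, pair[2])))
    h_values <- unique(c(0, max(0, dmin - 1e-4)))
  }
  if (is.null(r_values)) r_values <- seq(0.5, 15, by = 0.5)
  grid <- expand.grid(h = h_values, r = r_values)
  grid <- grid[grid$h < grid$r, , drop = FALSE]
  if (!nrow(grid)) stop("no feasible (h, r) combinations in the grid")

  logPL <- rep(-Inf, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- model
    m$interactions$h[row] <- grid$h[i]
    m$interactions$r[row] <- grid$r[i]
    f <- tryCatch(fit_mshc(pattern, m, ...), error = function(e) NULL)
    if (!is.null(f) && f$feasible) logPL[i] <- f$logPL
  }
  if (all(is.infinite(logPL)))
    stop("every (h, r) grid point was infeasible")
  best <- which.max(logPL)
  m <- model
  m$interactions$h[row] <- grid$h[best]
  m$interactions$r[row] <- grid$r[best]
  structure(list(grid = cbind(grid, logPL = logPL),
                 h = grid$h[best], r = grid$r[best],
                 best_fit = fit_mshc(pattern, m, ...), pair = pair),
            class = "mshc_profile")
}

#' @export
print.mshc_profile <- function(x, ...) {
  cat(sprintf("profile over (h, r) for pair %s: best h = %g, r = %g\n",
              paste(x$pair, collapse = ""), x$h, x$r))
  print(x$best_fit)
  invisible(x)
}
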