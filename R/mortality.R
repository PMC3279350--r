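# Colony mortality-risk modelling: competitive influence index, logistic
# regression with all-subsets AIC selection, contingency test, and the
# random- vs logistic-thinning test on the surviving spatial pattern.

#' Competitive influence index
#'
#' For each focal location, the sum over neighbouring colonies within
#' `radius` (strictly: distance < radius) of disc diameter divided by
#' distance, \eqn{\sum_n D_n / dist_{n,f}}, in cm/m.  The caller supplies the
#' neighbour set; a focal point must not be its own neighbour, and a
#' neighbour at distance 0 is an error (coincident structures are invalid).
#'
#' @param focal Two-column matrix (or vector of length 2) of focal
#'   coordinates (metres).
#' @param neighbours Two-column matrix of neighbour coordinates.
#' @param D Neighbour disc diameters (cm), one per neighbour row.
#' @param radius Neighbourhood radius in metres (10 for recently founded
#'   colonies, 20 for established ones, reflecting age-specific foraging
#'   ranges).
#' @return Numeric vector of influence values, one per focal row.
#' @examples
#' influence_index(c(0, 0), rbind(c(2, 0), c(5, 0)), c(100, 50), 10)  # 60
#' @export
influence_index <- function(focal, neighbours, D, radius) {
  if (radius <= 0) stop("'radius' must be positive")
  if (is.null(dim(focal))) focal <- matrix(focal, ncol = 2)
  neighbours <- as.matrix(neighbours)
  if (length(D) != nrow(neighbours))
    stop("'D' must have one entry per neighbour")
  d <- cross_dist(focal, neighbours)
  within <- d < radius
  if (any(within & d == 0))
    stop("neighbour at distance 0: coincident structures are invalid ",
         "(is the focal point included among its own neighbours?)")
  contrib <- matrix(rep(D, each = nrow(focal)), nrow = nrow(focal)) / d
  contrib[!within] <- 0
  rowSums(contrib)
}

#' Build per-colony covariate records for mortality modelling
#'
#' Computes, for every colony, the cohort-specific influence index (10 m
#' radius for recently founded colonies, 20 m for established ones, with all
#' other colonies as neighbours) and the distance to the nearest occupied
#' mound; carries disc diameter, cohort and the survival outcome when
#' present.
#'
#' @param colonies A [tpp()] of colonies, or a data.frame with columns `x`,
#'   `y`, `disc_diameter_cm` and `cohort` (values `"recent"` /
#'   `"established"`), optionally `died`.
#' @param mounds Occupied mound coordinates: two-column matrix or a [tpp()].
#' @param radius_recent,radius_established Influence radii in metres.
#' @return A `data.frame` with columns `x`, `y`, `disc_diameter`, `cohort`,
#'   `influence`, `nearest_mound_distance` and (if available) `died`.
#' @export
colony_records <- function(colonies, mounds,
                           radius_recent = 10, radius_established = 20) {
  if (inherits(colonies, "tpp")) {
    df <- data.frame(x = colonies$x, y = colonies$y)
    df <- cbind(df, colonies$marks)
  } else df <- as.data.frame(colonies)
  need <- c("x", "y", "disc_diameter_cm", "cohort")
  if (!all(need %in% names(df)))
    stop("colony records need columns ", paste(need, collapse = ", "))
  if (inherits(mounds, "tpp")) mounds <- cbind(mounds$x, mounds$y)
  mounds <- as.matrix(mounds)

  n <- nrow(df)
  xy <- cbind(df$x, df$y)
  infl <- numeric(n)
  for (i in seq_len(n)) {
    rad <- if (df$cohort[i] == "recent") radius_recent else radius_established
    infl[i] <- influence_index(xy[i, , drop = FALSE],
                               xy[-i, , drop = FALSE],
                               df$disc_diameter_cm[-i], rad)
  }
  out <- data.frame(x = df$x, y = df$y,
                    disc_diameter = df$disc_diameter_cm,
                    cohort = df$cohort,
                    influence = infl,
                    nearest_mound_distance =
                      apply(cross_dist(xy, mounds), 1, min))
  if ("died" %in% names(df)) out$died <- df$died
  out
}

#' Logistic regression for colony mortality
#'
#' Maximum-likelihood logistic fit of the death indicator on the requested
#' predictors (fitted by iteratively reweighted least squares via
#' [stats::glm()]), with Wald tests, log-likelihood and AIC.  Perfect
#' separation is flagged as non-convergence.
#'
#' @param records A data.frame from [colony_records()] with a logical/0-1
#'   column `died`.
#' @param predictors Character vector of predictor column names (may be
#'   empty, giving the intercept-only model).
#' @return A list of class `"logistic_fit"`: coefficient table (estimate,
#'   SE, Wald z, two-sided p), `logL`, `k`, `aic`, fitted death
#'   probabilities, convergence flag and the underlying `glm` object.
#' @export
fit_mortality <- function(records, predictors = character(0)) {
  if (!"died" %in% names(records)) stop("records need a 'died' column")
  died <- as.numeric(records$died)
  if (length(unique(died)) < 2)
    stop("need at least one death and one survival")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  separated <- FALSE
  g <- withCallingHandlers(
    glm(as.formula(paste("died ~", rhs)), family = binomial(),
        data = cbind(records, died = died)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- coef(g)
  se <- sqrt(diag(vcov(g)))
  z <- est / se
  tab <- data.frame(estimate = est, se = se, z = z,
                    p = 2 * pnorm(-abs(z)))
  ll <- as.numeric(logLik(g))
  k <- length(est)
  structure(list(predictors = predictors, coef = tab,
                 logL = ll, k = k, aic = -2 * ll + 2 * k,
                 fitted = as.numeric(g$fitted.values),
                 converged = g$converged && !separated,
                 separated = separated, glm = g),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic mortality model: died ~ %s\n",
              if (length(x$predictors))
                paste(x$predictors, collapse = " + ") else "1"))
  print(round(x$coef, 4))
  cat(sprintf("  logL = %.2f, k = %d, AIC = %.2f%s\n", x$logL, x$k, x$aic,
              if (x$converged) "" else "  [separation / non-convergence]"))
  invisible(x)
}

#' All-subsets logistic model selection by AIC
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model), ranks by AIC and attaches Akaike weights.
#'
#' @param records As for [fit_mortality()].
#' @param candidates Character vector of candidate predictors (at most 20).
#' @return A list of class `"aic_selection"`: `table` (one row per model,
#'   ranked), `fits` in the same order, and `best` (the top fit).
#' @export
all_subsets_aic <- function(records, candidates) {
  p <- length(candidates)
  if (p > 20) stop("more than 20 candidate predictors")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  fits <- lapply(seq_len(nrow(subsets)), function(i)
    fit_mortality(records, candidates[unlist(subsets[i, ])]))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aics)
  fits <- fits[ord]
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$predictors)) paste(f$predictors, collapse = " + ")
      else "(intercept only)", ""),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    AIC = vapply(fits, function(f) f$aic, numeric(1)))
  tab$weight <- aic_weights(tab$AIC)
  structure(list(table = tab, fits = fits, best = fits[[1]]),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat("all-subsets logistic model selection (AIC)\n")
  print(cbind(x$table[, c("model", "k", "AIC")],
              weight = round(x$table$weight, 4)), row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} without continuity correction, df = 1.
#'
#' @param tab A 2x2 matrix of counts (e.g. deaths/survivors by cohort).
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("'tab' must be a 2x2 matrix")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero marginal in the contingency table")
  ct <- chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = expected)
}

#' Thinning test of a mortality model against the surviving pattern
#'
#' Asks whether deleting colonies from the pre-mortality pattern according to
#' a mortality model reproduces the spatial statistics of the truly observed
#' survivors.  Each replicate deletes exactly `n - n_survivors` colonies by
#' weighted sampling without replacement (successive draws with renormalised
#' weights) with weights proportional to the per-colony deletion
#' probabilities -- equal weights for the random (null) mortality model,
#' fitted logistic death probabilities otherwise -- so every simulated
#' survivor set has exactly the observed survivor count.  The survivor
#' pattern's centred L function is compared to the replicate envelope, and
#' the curvewise CvM statistic summarises the fit.
#'
#' @param colonies A [tpp()] of the pre-mortality colonies (coordinates are
#'   what matters; types are ignored).
#' @param survived Logical vector, one entry per colony: the observed
#'   survival outcome.
#' @param deletion_prob `NULL` for the random model, or a numeric vector of
#'   per-colony deletion probabilities (e.g. `fit$fitted` from
#'   [fit_mortality()]).
#' @param r Distance grid for the L function.
#' @param nsim Number of thinning replicates.
#' @param seed Optional integer seed.
#' @param label Model label carried in the result.
#' @return A list of class `"thinning_test"`: the envelope of the survivor
#'   L(r), its CvM statistic, `n_survivors` and the label.
#' @export
thinning_survival_test <- function(colonies, survived, deletion_prob = NULL,
                                   r = r_grid(), nsim = 999, seed = NULL,
                                   label = if (is.null(deletion_prob))
                                     "random" else "logistic") {
  n <- npoints(colonies)
  survived <- as.logical(survived)
  if (length(survived) != n)
    stop("'survived' must have one entry per colony")
  n_surv <- sum(survived)
  n_dead <- n - n_surv
  if (n_dead < 1) stop("no deaths: nothing to thin")
  wts <- if (is.null(deletion_prob)) rep(1, n) else as.numeric(deletion_prob)
  if (length(wts) != n) stop("'deletion_prob' must have one entry per colony")
  if (all(wts == 0)) stop("all deletion weights are zero")
  if (!is.null(seed)) set.seed(seed)

  surv_l <- function(keep) {
    p <- tpp(colonies$x[keep], colonies$y[keep],
             rep("S", sum(keep)), colonies$window)
    l_translation(p, "S", "S", r)$values
  }
  observed <- surv_l(survived)
  sims <- matrix(NA_real_, nsim, length(r))
  for (i in seq_len(nsim)) {
    dead <- sample.int(n, n_dead, prob = wts)
    keep <- !seq_len(n) %in% dead
    sims[i, ] <- surv_l(keep)
  }
  env <- envelope_from_sims(r, observed, sims, "L")
  structure(list(envelope = env, cvm = env$cvm, n_survivors = n_surv,
                 model = label),
            class = "thinning_test")
}

#' @export
print.thinning_test <- function(x, ...) {
  cat(sprintf(
    "thinning survival test (%s mortality model): n_survivors = %d\n",
    x$model, x$n_survivors))
  cat(sprintf("  CvM of survivor L(r) vs simulation mean = %.4g\n", x$cvm))
  invisible(x)
}
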