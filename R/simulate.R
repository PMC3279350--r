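# Simulation of MSHC models by birth/death/shift Metropolis-Hastings.
# The chain targets the Gibbs measure whose Papangelou conditional intensity
# is conditional_intensity(); the hard cores are respected exactly in every
# state, since a violating proposal has conditional intensity 0.

check_simulable <- function(model) {
  if (any(is.na(model$beta)))
    stop("cannot simulate: model has unestimated beta values")
  if (!is.null(model$interactions) && any(is.na(model$interactions$gamma)))
    stop("cannot simulate: model has unestimated gamma values")
  for (cv in model$covariates)
    if (is.na(cv$coef))
      stop("cannot simulate: model has unestimated covariate coefficients")
}

sampler_args <- function(model) {
  pm <- pair_matrices(model)
  ncov <- length(model$covariates)
  M <- length(model$types)
  covref <- lapply(model$covariates, function(cv) cv$cov$refs)
  covcoef <- matrix(0, M, ncov)
  if (ncov) {
    for (i in seq_len(ncov)) {
      cv <- model$covariates[[i]]
      covcoef[match(cv$types, model$types), i] <- cv$coef
    }
  }
  list(logbeta = log(unname(model$beta)), h2 = pm$h2, r2 = pm$r2,
       loggam = pm$loggamma, covref = unname(covref), covcoef = covcoef)
}

result_to_tpp <- function(res, model, window) {
  tpp(res$x, res$y,
      factor(model$types[res$type + 1L], levels = model$types),
      window)
}

#' Simulate an MSHC model by Metropolis-Hastings
#'
#' Birth/death/shift Metropolis-Hastings sampler with uniform birth locations
#' and uniform type proposals.  Default proposal probabilities are 0.35
#' (birth), 0.35 (death) and 0.30 (shift); `nprop = 1e5` proposals are
#' adequate burn-in for patterns of a few hundred points.  All hard cores are
#' respected exactly in the output, and runs are byte-identical under a fixed
#' seed.
#'
#' @param model An [mshc_model()] with all parameters filled in.
#' @param window A [rect_window()] to simulate in.
#' @param nprop Number of Metropolis-Hastings proposals.
#' @param p_birth,p_death Proposal probabilities for birth and death moves
#'   (the remainder are shifts).
#' @param init Optional [tpp()] initial state (default: empty pattern).
#' @param cap Safety cap on the point count; exceeding it is an error with
#'   diagnostics (it indicates a non-integrable or badly scaled model).
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A [tpp()] pattern.
#' @export
simulate_mshc <- function(model, window, nprop = 1e5,
                          p_birth = 0.35, p_death = 0.35,
                          init = NULL, cap = 10000L, seed = NULL) {
  check_simulable(model)
  if (!is.null(seed)) set.seed(seed)
  a <- sampler_args(model)
  if (is.null(init)) {
    ix <- numeric(0); iy <- numeric(0); it <- integer(0)
  } else {
    ix <- init$x; iy <- init$y
    it <- match(as.character(init$type), model$types) - 1L
  }
  res <- mshc_mh_cpp(window$xrange, window$yrange, a$logbeta,
                     a$h2, a$r2, a$loggam, a$covref, a$covcoef,
                     ix, iy, as.integer(it),
                     as.integer(nprop), p_birth, p_death,
                     FALSE, as.integer(cap))
  result_to_tpp(res, model, window)
}

#' Simulate an MSHC model conditioned on per-type point counts
#'
#' Shift-only Metropolis-Hastings at fixed counts: the chain moves points to
#' uniformly proposed locations, so the per-type counts of the initial packing
#' are preserved and the target is the MSHC model conditioned on those counts
#' (the first-order `beta` terms cancel from the acceptance ratio for
#' uncovariate models).  The initial state is a random sequential (dart
#' throwing) packing; if the requested counts cannot be packed under the hard
#' cores the function errors.
#'
#' @param model An [mshc_model()]; `beta` may be `NA` when there are no
#'   covariates (it cancels).
#' @param window A [rect_window()].
#' @param n Named integer vector of points per type, e.g. `c(K = 48, A = 212)`.
#' @param nprop Number of shift proposals.
#' @param seed Optional integer seed.
#' @param max_tries Dart-throwing attempts per point before declaring the
#'   packing infeasible.
#' @return A [tpp()] pattern with exactly the requested counts.
#' @export
simulate_mshc_fixed_n <- function(model, window, n, nprop = 1e5,
                                  seed = NULL, max_tries = 5000L) {
  if (is.null(names(n)) || !all(names(n) %in% model$types))
    stop("'n' must be named with model types")
  if (!is.null(seed)) set.seed(seed)
  m2 <- model
  if (any(is.na(m2$beta))) {
    if (length(m2$covariates))
      stop("beta must be supplied when the model has covariates")
    m2$beta <- setNames(rep(1, length(m2$types)), m2$types)
  }
  check_simulable(m2)
  a <- sampler_args(m2)

  pm <- pair_matrices(m2)
  h <- sqrt(pmax(pm$h2, 0)) * (pm$h2 >= 0)
  types_idx <- rep(match(names(n), m2$types), unname(n))
  ix <- numeric(0); iy <- numeric(0); it <- integer(0)
  for (m in types_idx) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, window$xrange[1], window$xrange[2])
      y <- runif(1, window$yrange[1], window$yrange[2])
      if (length(ix)) {
        d2 <- (ix - x)^2 + (iy - y)^2
        if (any(d2 <= pm$h2[cbind(m, it)])) next
      }
      ix <- c(ix, x); iy <- c(iy, y); it <- c(it, m)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not pack the requested point counts under the hard cores")
  }

  res <- mshc_mh_cpp(window$xrange, window$yrange, a$logbeta,
                     a$h2, a$r2, a$loggam, a$covref, a$covcoef,
                     ix, iy, as.integer(it - 1L),
                     as.integer(nprop), 0, 0, TRUE, as.integer(1e9))
  result_to_tpp(res, m2, window)
}
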