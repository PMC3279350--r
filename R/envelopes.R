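# Pointwise Monte Carlo critical envelopes and the curvewise Cramer-von Mises
# statistic used to compare model fits.

envelope_from_sims <- function(r, observed, sims, statistic_id = "statistic") {
  nsim <- nrow(sims)
  k <- ceiling(0.025 * (nsim + 1))
  sorted <- apply(sims, 2, sort)
  lower <- sorted[k, ]
  upper <- sorted[nsim + 1L - k, ]
  sim_mean <- colMeans(sims)
  outside <- observed < lower | observed > upper
  structure(list(statistic = statistic_id, r = r, observed = observed,
                 sim_mean = sim_mean, lower = lower, upper = upper,
                 nsim = nsim, rank = k,
                 exceed_r = r[outside],
                 cvm = sum((observed - sim_mean)^2)),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "95%% pointwise critical envelope for %s (%d simulations, rank %d)\n",
    x$statistic, x$nsim, x$rank))
  cat(sprintf("  CvM (observed vs simulation mean) = %.4g\n", x$cvm))
  if (length(x$exceed_r))
    cat(sprintf("  observed leaves the band at %d of %d grid points\n",
                length(x$exceed_r), length(x$r)))
  else cat("  observed curve entirely inside the band\n")
  invisible(x)
}

#' @export
as.data.frame.envelope_result <- function(x, ...) {
  data.frame(r = x$r, observed = x$observed, sim_mean = x$sim_mean,
             lower = x$lower, upper = x$upper)
}

#' Monte Carlo critical envelope of a summary statistic under a model
#'
#' Simulates `nsim` patterns with `simulator`, evaluates the summary
#' statistic(s) on each, and returns the pointwise 95% critical band: at each
#' distance the bounds are the k-th smallest and k-th largest simulated
#' values with `k = ceiling(0.025 (nsim + 1))` (for `nsim = 999`, the 25th
#' from each end; for `nsim = 39`, the minimum and maximum).  The observed
#' curve is evaluated identically.  A simulation on which a statistic is
#' undefined (e.g. a type died out) is resampled, up to `max_retry` times in
#' total.
#'
#' @param pattern The observed [tpp()] pattern.
#' @param simulator A function of no arguments returning a simulated [tpp()]
#'   (see [model_simulator()]).
#' @param statistic A function mapping a pattern to a summary function, or a
#'   named list of such functions (evaluated on shared simulations).
#' @param nsim Number of simulations (>= 39 for a 95% band).
#' @param seed Optional integer seed.
#' @param max_retry Total resampling budget for failed simulations.
#' @return An `"envelope_result"`, or a named list of them when `statistic`
#'   is a list.  Each contains the observed curve, simulation mean, bounds,
#'   the distances where the observed curve leaves the band, and the
#'   curvewise Cramer-von Mises statistic (sum over the grid of squared
#'   deviations of the observed curve from the simulation mean).
#' @export
critical_envelope <- function(pattern, simulator, statistic, nsim = 99,
                              seed = NULL, max_retry = nsim) {
  if (nsim < 39) stop("'nsim' must be at least 39 for a 95% envelope")
  if (!is.null(seed)) set.seed(seed)
  single <- is.function(statistic)
  stats <- if (single) list(statistic = statistic) else statistic
  obs <- lapply(stats, function(f) f(pattern))

  sims <- lapply(obs, function(o)
    matrix(NA_real_, nrow = nsim, ncol = length(o$r)))
  retries <- 0L
  i <- 1L
  while (i <= nsim) {
    ok <- tryCatch({
      sp <- simulator()
      vals <- lapply(stats, function(f) f(sp))
      for (s in seq_along(stats)) sims[[s]][i, ] <- vals[[s]]$values
      TRUE
    }, error = function(e) FALSE)
    if (ok) i <- i + 1L
    else {
      retries <- retries + 1L
      if (retries > max_retry)
        stop("too many failed simulations in critical_envelope")
    }
  }

  out <- lapply(seq_along(stats), function(s)
    envelope_from_sims(obs[[s]]$r, obs[[s]]$values, sims[[s]],
                       obs[[s]]$statistic))
  names(out) <- names(stats)
  if (single) out[[1]] else out
}

#' Simulator closure for envelope and comparison machinery
#'
#' @param model A fully parameterised [mshc_model()].
#' @param window A [rect_window()].
#' @param nprop Metropolis-Hastings proposals per draw.
#' @param fixed_n Optional named count vector; when supplied, draws condition
#'   on these per-type counts (shift-only sampler).
#' @return A function of no arguments returning a simulated [tpp()].
#' @export
model_simulator <- function(model, window, nprop = 1e5, fixed_n = NULL) {
  force(model); force(window); force(nprop); force(fixed_n)
  function() {
    if (is.null(fixed_n)) simulate_mshc(model, window, nprop = nprop)
    else simulate_mshc_fixed_n(model, window, fixed_n, nprop = nprop)
  }
}

#' Curvewise Cramer-von Mises statistic
#'
#' Sum over the distance grid of the squared deviation of the observed curve
#' from the simulation mean: \eqn{\sum_r (obs(r) - \overline{sim}(r))^2}.
#' The raw grid sum is used (no dr weighting); on a constant-step grid the
#' two differ only by a constant factor.
#'
#' @param observed Numeric vector of observed statistic values on the grid.
#' @param sims Matrix of simulated curves (rows = simulations), or a numeric
#'   vector already holding the simulation mean.
#' @return Nonnegative scalar; 0 iff the observed curve equals the mean.
#' @export
cvm_statistic <- function(observed, sims) {
  m <- if (is.matrix(sims)) colMeans(sims) else sims
  if (length(m) != length(observed))
    stop("grid lengths differ between observed and simulations")
  if (any(!is.finite(observed)) || any(!is.finite(m)))
    stop("non-finite values in CvM inputs")
  sum((observed - m)^2)
}

#' Compare two models by curvewise CvM distance to the observed pattern
#'
#' Generates an envelope of `statistic` under each model and declares the
#' model whose simulation mean is closer (smaller CvM) the better fit.
#'
#' @param pattern The observed [tpp()] pattern.
#' @param simulator_a,simulator_b Simulator closures (see
#'   [model_simulator()]).
#' @param statistic A summary-statistic function of a pattern.
#' @param nsim Simulations per model.
#' @param seed Optional integer seed.
#' @param labels Length-2 character labels for the two models.
#' @return A list of class `"cvm_comparison"`: both envelopes, both CvM
#'   values and the winner's label.
#' @export
compare_models_cvm <- function(pattern, simulator_a, simulator_b, statistic,
                               nsim = 99, seed = NULL,
                               labels = c("A", "B")) {
  if (!is.null(seed)) set.seed(seed)
  env_a <- critical_envelope(pattern, simulator_a, statistic, nsim)
  env_b <- critical_envelope(pattern, simulator_b, statistic, nsim)
  cvm <- setNames(c(env_a$cvm, env_b$cvm), labels)
  structure(list(envelopes = setNames(list(env_a, env_b), labels),
                 cvm = cvm, winner = labels[which.min(cvm)]),
            class = "cvm_comparison")
}

#' @export
print.cvm_comparison <- function(x, ...) {
  cat("curvewise CvM model comparison\n")
  for (nm in names(x$cvm))
    cat(sprintf("  %s: CvM = %.4g\n", nm, x$cvm[[nm]]))
  cat("  best fit:", x$winner, "\n")
  invisible(x)
}
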