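# End-to-end pipeline: generate (or accept) a mound/colony dataset, fit
# reduced and full MSHC models, test the interspecific term, compute
# goodness-of-fit envelopes and CvM comparisons, model mortality risk and run
# the thinning survival tests.  Every random stage consumes its own seed
# derived from the master seed.

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [synth_config()] and
#' [run_pipeline()]; `window` may be given as `window: {x: [0, 397],
#' y: [0, 220]}`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (a [synth_config()]) and `run`
#'   (extra arguments for [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc_args <- list()
  if (!is.null(y$window)) {
    win <- y$window
    # YAML 1.1 parses a bare `y` key as boolean TRUE
    names(win)[names(win) == "TRUE"] <- "y"
    sc_args$window <- rect_window(unlist(win$x), unlist(win$y))
  }
  for (nm in setdiff(names(formals(synth_config)), "window"))
    if (!is.null(y[[nm]])) sc_args[[nm]] <- unlist(y[[nm]])
  run <- y[intersect(names(y), c("nsim", "seed", "dummy_spacing",
                                 "correction", "nprop", "reduced_only",
                                 "output_dir"))]
  list(config = do.call(synth_config, sc_args), run = run)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: (1) generate structures and mortality outcomes from `config`;
#' (2) fit reduced (intraspecific only) and full (plus interspecific triple)
#' MSHC models to the mound/colony pattern, both including the
#' distance-to-nearest-unoccupied-mound covariate, and run the Monte Carlo
#' log-pseudolikelihood-ratio test; (3) envelopes and CvM comparison of
#' L_KA, G_KA and G_AK under both fitted models; (4) all-subsets logistic
#' mortality selection for recently founded colonies; (5) random- vs
#' logistic-thinning survival tests.  With `reduced_only = TRUE` the
#' interspecific stages (2b, 3) are skipped.
#'
#' @param config A [synth_config()].
#' @param nsim Simulations per Monte Carlo stage (999 reproduces the
#'   published protocol; the default 99 keeps a demonstration run short).
#' @param seed Master integer seed; each stage uses an independent seed
#'   derived from it.
#' @param dummy_spacing,correction Passed to the fitting routines.
#' @param nprop Metropolis-Hastings proposals per simulation.
#' @param reduced_only Skip the interspecific stages.
#' @param output_dir Optional directory; when given, writes `report.json`,
#'   the pattern CSV and envelope CSVs there.
#' @return A list of class `"pipeline_report"` with the stage results.
#' @export
run_pipeline <- function(config = synth_config(), nsim = 99, seed = 1,
                         dummy_spacing = 10, correction = "border",
                         nprop = 1e5, reduced_only = FALSE,
                         output_dir = NULL) {
  set.seed(seed)
  stage_seed <- sample.int(2^31 - 2, 8)

  ## 1. data
  structures <- generate_structures(config, nprop = nprop,
                                    seed = stage_seed[1])
  records <- generate_mortality(structures, config, seed = stage_seed[2])
  pattern <- structures$pattern
  w <- pattern$window
  covs <- list(dist_unoccupied_mound = list(
    cov = distance_covariate(structures$unoccupied_mounds),
    types = c("K", "A"), coef = NA_real_))

  ia <- synth_model(config)$interactions
  reduced <- mshc_model(interactions = ia[ia$type1 == ia$type2, ],
                        covariates = covs)
  full <- mshc_model(interactions = ia, covariates = covs)

  ## 2. interaction test
  interaction <- NULL
  if (!reduced_only) {
    interaction <- mc_lr_test(pattern, reduced, full, nsim = nsim,
                              dummy_spacing = dummy_spacing,
                              correction = correction, nprop = nprop,
                              fixed_n = TRUE, seed = stage_seed[3])
  } else {
    interaction <- list(fit_reduced = fit_mshc(pattern, reduced,
                                               dummy_spacing, correction))
  }

  ## 3. goodness-of-fit envelopes + CvM
  gof <- NULL
  if (!reduced_only) {
    stats <- list(
      L_KA = function(p) l_translation(p, "K", "A"),
      G_KA = function(p) g_nearest_km(p, "K", "A"),
      G_AK = function(p) g_nearest_km(p, "A", "K"))
    n_by_type <- c(K = npoints(pattern, "K"), A = npoints(pattern, "A"))
    set.seed(stage_seed[4])
    env_full <- critical_envelope(
      pattern, model_simulator(interaction$fit_full$model, w, nprop,
                               fixed_n = n_by_type), stats, nsim)
    set.seed(stage_seed[5])
    env_reduced <- critical_envelope(
      pattern, model_simulator(interaction$fit_reduced$model, w, nprop,
                               fixed_n = n_by_type), stats, nsim)
    cvm <- data.frame(
      statistic = names(stats),
      full = vapply(env_full, function(e) e$cvm, numeric(1)),
      reduced = vapply(env_reduced, function(e) e$cvm, numeric(1)))
    cvm$best <- ifelse(cvm$full <= cvm$reduced, "full", "reduced")
    gof <- list(full = env_full, reduced = env_reduced, cvm = cvm)
  }

  ## 4. mortality selection (recently founded colonies)
  recent <- records[records$cohort == "recent", , drop = FALSE]
  mortality <- NULL
  thinning <- NULL
  if (nrow(recent) && length(unique(recent$died)) == 2) {
    mortality <- all_subsets_aic(
      recent, c("disc_diameter", "influence", "nearest_mound_distance"))
    ## 5. thinning survival tests
    col_pat <- tpp(recent$x, recent$y, rep("A", nrow(recent)), w)
    logistic_fit <- fit_mortality(
      recent, mortality$best$predictors)
    thinning <- list(
      random = thinning_survival_test(col_pat, !recent$died, NULL,
                                      nsim = nsim, seed = stage_seed[6]),
      logistic = thinning_survival_test(col_pat, !recent$died,
                                        logistic_fit$fitted,
                                        nsim = nsim, seed = stage_seed[7]))
  }

  report <- structure(
    list(config = config, seed = seed, nsim = nsim,
         n_points = c(K = npoints(pattern, "K"), A = npoints(pattern, "A")),
         structures = structures, records = records,
         interaction = interaction, gof = gof,
         mortality = mortality, thinning = thinning),
    class = "pipeline_report")

  if (!is.null(output_dir)) write_pipeline_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("burrowmap pipeline report\n")
  cat(sprintf("  pattern: %d mounds (K), %d colonies (A)\n",
              x$n_points[["K"]], x$n_points[["A"]]))
  if (inherits(x$interaction, "mc_lr_test")) print(x$interaction)
  if (!is.null(x$gof)) {
    cat("  CvM model comparison:\n")
    print(x$gof$cvm, row.names = FALSE)
  }
  if (!is.null(x$mortality)) {
    cat(sprintf("  best mortality model: %s\n", x$mortality$table$model[1]))
    cat(sprintf("  thinning CvM: logistic = %.1f, random = %.1f\n",
                x$thinning$logistic$cvm, x$thinning$random$cvm))
  }
  invisible(x)
}

pipeline_summary <- function(report) {
  out <- list(seed = report$seed, nsim = report$nsim,
              n_mounds = unname(report$n_points[["K"]]),
              n_colonies = unname(report$n_points[["A"]]))
  if (inherits(report$interaction, "mc_lr_test")) {
    out$delta <- report$interaction$delta_obs
    out$p_value <- report$interaction$p_value
    ia <- report$interaction$fit_full$model$interactions
    out$gamma_cross <- ia$gamma[ia$type1 != ia$type2]
  }
  if (!is.null(report$gof))
    out$cvm <- report$gof$cvm
  if (!is.null(report$mortality)) {
    out$best_mortality_model <- report$mortality$table$model[1]
    out$mortality_coef <- as.list(report$mortality$best$coef$estimate)
    names(out$mortality_coef) <- rownames(report$mortality$best$coef)
    out$thinning_cvm <- list(logistic = report$thinning$logistic$cvm,
                             random = report$thinning$random$cvm)
  }
  out
}

write_pipeline_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_pattern(report$structures$pattern,
                file.path(output_dir, "pattern.csv"))
  write.csv(report$records, file.path(output_dir, "colony_records.csv"),
            row.names = FALSE)
  if (!is.null(report$gof)) {
    for (model in c("full", "reduced"))
      for (nm in names(report$gof[[model]]))
        write.csv(as.data.frame(report$gof[[model]][[nm]]),
                  file.path(output_dir,
                            sprintf("envelope_%s_%s.csv", model, nm)),
                  row.names = FALSE)
  }
  jsonlite::write_json(pipeline_summary(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
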