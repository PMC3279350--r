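w100 <- rect_window(c(0, 100), c(0, 100))

test_that("the influence index sums D/d over strict-radius neighbours", {
  # (D = 100 at 2 m) + (D = 50 at 5 m) within 10 m: 50 + 10 = 60
  expect_equal(
    influence_index(c(0, 0), rbind(c(2, 0), c(0, 5)), c(100, 50), 10), 60)
  # no neighbours within the radius
  expect_equal(influence_index(c(0, 0), rbind(c(20, 0)), 100, 10), 0)
  # a neighbour exactly at the radius is excluded (strict <)
  expect_equal(influence_index(c(0, 0), rbind(c(10, 0)), 100, 10), 0)
  expect_equal(influence_index(c(0, 0), rbind(c(9.999, 0)), 100, 10),
               100 / 9.999)
  # coincident neighbour is an error
  expect_error(influence_index(c(0, 0), rbind(c(0, 0)), 100, 10),
               "distance 0")
})

test_that("the influence index is additive and linear in disc diameters", {
  set.seed(3)
  nb <- cbind(runif(12, -8, 8), runif(12, -8, 8))
  D <- runif(12, 20, 120)
  all12 <- influence_index(c(0, 0), nb, D, 10)
  split <- influence_index(c(0, 0), nb[1:5, ], D[1:5], 10) +
    influence_index(c(0, 0), nb[6:12, ], D[6:12], 10)
  expect_equal(all12, split)
  expect_equal(influence_index(c(0, 0), nb, 3 * D, 10), 3 * all12)
})

test_that("colony records use cohort-specific radii and nearest mounds", {
  col <- data.frame(x = c(10, 25, 40), y = c(10, 10, 10),
                    disc_diameter_cm = c(100, 60, 80),
                    cohort = c("recent", "established", "established"))
  mounds <- rbind(c(10, 30), c(90, 90))
  rec <- colony_records(col, mounds)
  # recent focal at (10,10): only the 15 m neighbour is outside its 10 m
  # radius, and the 30 m one farther still: influence 0
  expect_equal(rec$influence[1], 0)
  # established focal at (25,10): neighbours at 15 m (D=100) and 15 m (D=80)
  expect_equal(rec$influence[2], 100 / 15 + 80 / 15)
  expect_equal(rec$nearest_mound_distance[1], 20)
})

test_that("the intercept-only logistic fit matches the closed form", {
  rec <- data.frame(died = rep(c(TRUE, FALSE), c(69, 297)))
  f <- fit_mortality(rec)
  p <- 69 / 366
  expect_equal(f$coef$estimate[1], log(69 / 297), tolerance = 1e-7)
  expect_equal(f$logL, 69 * log(p) + 297 * log(1 - p), tolerance = 1e-7)
  expect_equal(f$aic, -2 * f$logL + 2)
})

test_that("the logistic log-likelihood matches an independent optimiser", {
  set.seed(8)
  n <- 200
  x1 <- runif(n, 0, 10); x2 <- rnorm(n)
  p <- plogis(-1 + 0.3 * x1 - 0.5 * x2)
  rec <- data.frame(a = x1, b = x2, died = rbinom(n, 1, p) == 1)
  f <- fit_mortality(rec, c("a", "b"))
  nll <- function(b) {
    eta <- b[1] + b[2] * x1 + b[3] * x2
    -sum(ifelse(rec$died, plogis(eta, log.p = TRUE),
                plogis(-eta, log.p = TRUE)))
  }
  o <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(f$logL, -o$value, tolerance = 1e-6)
  expect_equal(f$aic, -2 * f$logL + 2 * 3)
})

test_that("generated coefficients are recovered within 2 SE", {
  set.seed(12)
  truth <- c(-0.5, 0.08, -0.02)
  hits <- replicate(30, {
    n <- 500
    x1 <- runif(n, 0, 30); x2 <- runif(n, 0, 120)
    rec <- data.frame(a = x1, b = x2,
                      died = rbinom(n, 1, plogis(
                        truth[1] + truth[2] * x1 + truth[3] * x2)) == 1)
    f <- fit_mortality(rec, c("a", "b"))
    all(abs(f$coef$estimate - truth) <= 2 * f$coef$se)
  })
  expect_gte(mean(hits), 0.75)
})

test_that("separation is flagged rather than silently reported", {
  rec <- data.frame(a = c(1:5, 6:10),
                    died = rep(c(FALSE, TRUE), each = 5))
  f <- fit_mortality(rec, "a")
  expect_false(f$converged)
  expect_true(f$separated)
})

test_that("all-subsets selection enumerates and normalises correctly", {
  set.seed(21)
  n <- 300
  rec <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  rec$died <- rbinom(n, 1, plogis(-1 + 2 * rec$a)) == 1
  sel <- all_subsets_aic(rec, c("a", "b", "c"))
  expect_equal(nrow(sel$table), 8)
  expect_equal(sum(sel$table$weight), 1)
  expect_true(grepl("a", sel$table$model[1]))
})

test_that("a null predictor is excluded by AIC in most replicates", {
  set.seed(34)
  wins <- replicate(30, {
    n <- 250
    rec <- data.frame(a = runif(n, 0, 10), noise = runif(n))
    rec$died <- rbinom(n, 1, plogis(-2 + 0.35 * rec$a)) == 1
    sel <- all_subsets_aic(rec, c("a", "noise"))
    !grepl("noise", sel$table$model[1])
  })
  expect_gt(mean(wins), 0.5)
})

test_that("Pearson chi-square matches the hand formula", {
  r <- pearson_chi2(matrix(c(30, 70, 10, 90), 2, 2, byrow = TRUE))
  hand <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  expect_equal(r$statistic, hand(matrix(c(30, 70, 10, 90), 2, 2,
                                        byrow = TRUE)))
  expect_equal(r$df, 1)
  # identical row proportions: exactly zero
  expect_equal(pearson_chi2(matrix(c(20, 80, 10, 40), 2, 2,
                                   byrow = TRUE))$statistic, 0)
  set.seed(2)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    expect_equal(pearson_chi2(tab)$statistic, hand(tab), tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("thinning keeps the survivor count and uniform inclusion when random", {
  set.seed(44)
  n <- 60
  col <- tpp(runif(n, 0, 100), runif(n, 0, 100), rep("A", n), w100)
  survived <- rep(c(TRUE, FALSE), c(40, 20))

  # survivor count enforced in every replicate: L is computed from exactly
  # n_survivors points, so the envelope exists and the count matches
  tt <- thinning_survival_test(col, survived, NULL, r = r_grid(10, 1),
                               nsim = 99, seed = 5)
  expect_equal(tt$n_survivors, 40)

  # equal weights reproduce simple random sampling: inclusion frequency of
  # each colony over replicates is near n_dead/n (hypergeometric marginal)
  nrep <- 600
  inc <- numeric(n)
  set.seed(6)
  for (i in seq_len(nrep)) {
    dead <- sample.int(n, 20, prob = rep(1, n))
    inc[dead] <- inc[dead] + 1
  }
  expect_true(all(abs(inc / nrep - 1 / 3) < 0.09))
})

test_that("mound-dependent mortality is detected by the thinning comparison", {
  # deaths preferentially far from mounds: the logistic model should beat
  # random thinning on the survivor L
  set.seed(71)
  cfg <- synth_config(window = rect_window(c(0, 250), c(0, 180)),
                      n_mound_occupied = 18L, n_mound_unoccupied = 8L,
                      n_colony_established = 0L, n_colony_recent = 150L)
  wins <- replicate(10, {
    st <- generate_structures(cfg, nprop = 8e4)
    rec <- generate_mortality(st, cfg)
    f <- fit_mortality(rec, c("disc_diameter", "influence",
                              "nearest_mound_distance"))
    colp <- tpp(rec$x, rec$y, rep("A", nrow(rec)), st$pattern$window)
    cr <- thinning_survival_test(colp, !rec$died, NULL, nsim = 49)$cvm
    cl <- thinning_survival_test(colp, !rec$died, f$fitted, nsim = 49)$cvm
    cl < cr
  })
  expect_gte(mean(wins), 0.7)
})
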