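w100 <- rect_window(c(0, 100), c(0, 100))

test_that("quadrature weights follow the counting rule and sum to |W|", {
  empty <- tpp(numeric(0), numeric(0),
               factor(character(0), levels = c("K", "A")), w100)
  q <- make_quadrature(empty, 10)
  expect_equal(nrow(q), 200)           # 100 dummies per type
  expect_true(all(q$weight == 100))
  expect_equal(sum(q$weight[q$type == "K"]), 1e4)

  # one data point sharing the single tile with one dummy: each gets half
  w10 <- rect_window(c(0, 10), c(0, 10))
  p1 <- tpp(2, 2, factor("K", levels = "K"), w10)
  q1 <- make_quadrature(p1, 10)
  expect_equal(nrow(q1), 2)
  expect_equal(q1$weight, c(50, 50))

  p <- rpat(10, 20, w100, seed = 6)
  q2 <- make_quadrature(p, 7)
  for (ty in c("K", "A"))
    expect_equal(sum(q2$weight[q2$type == ty]), 1e4, tolerance = 1e-9)
  expect_true(all(q2$weight > 0))
  expect_equal(sum(q2$is_data), 30)
  expect_error(make_quadrature(p, 200), "window")
})

test_that("Poisson pseudolikelihood recovers beta = n/|W| exactly", {
  p <- rpat(24, 36, w100, seed = 42)
  for (corr in c("none", "border")) {
    fit <- fit_mshc(p, mshc_model(), correction = corr)
    expect_equal(unname(fit$model$beta["K"]), 24 / 1e4, tolerance = 1e-8)
    expect_equal(unname(fit$model$beta["A"]), 36 / 1e4, tolerance = 1e-8)
  }
})

test_that("AICc follows its formula, including the plain-AIC limit", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-81.7, 4, Inf), 171.4)
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_error(aicc(-5, 9, 10), "n > k")
})

test_that("Akaike weights renormalise exponential AIC differences", {
  w <- aic_weights(c(3469.0, 3489.4))
  expect_equal(round(w[1], 2), 1)
  expect_equal(round(w[2], 2), 0)
  expect_equal(aic_weights(c(7, 7)), c(0.5, 0.5))
  w3 <- aic_weights(c(10, 12, 14))
  expect_equal(w3 / w3[1], c(1, exp(-1), exp(-2)))
  expect_equal(sum(w3), 1)
  expect_error(aic_weights(5), "two models")
})

test_that("the pseudolikelihood ratio doubles the logPL difference", {
  expect_equal(pl_ratio(-1755.5, -1780.7), 50.4)
  expect_equal(pl_ratio(-1477.3, -1498.1), 41.6)
  expect_equal(pl_ratio(-10, -10), 0)
  expect_warning(pl_ratio(-12, -10), "negative")
})

test_that("data violating a hard core yield a flagged -Inf fit", {
  p <- tpp(c(50, 50.5), c(50, 50), c("K", "A"), w100)
  spec <- mshc_model(interactions = data.frame(type1 = "K", type2 = "A",
                                               h = 1, r = 5, gamma = NA))
  fit <- fit_mshc(p, spec, correction = "none")
  expect_false(fit$feasible)
  expect_equal(fit$logPL, -Inf)
})

test_that("an uninformative interaction column is dropped with a warning", {
  # an interaction range far below every interpoint and node distance: the
  # annulus count is 0 at every node, so its gamma carries no information
  set.seed(13)
  p <- tpp(runif(10, 0, 100), runif(10, 0, 100),
           factor(rep("K", 10), levels = c("K", "A")), w100)
  spec <- mshc_model(interactions = data.frame(type1 = "K", type2 = "K",
                                               h = 0, r = 1e-4, gamma = NA))
  expect_warning(fit <- fit_mshc(p, spec, correction = "none"),
                 "log_gamma_KK")
  reduced <- fit_mshc(p, mshc_model(), correction = "none")
  expect_equal(fit$logPL, reduced$logPL, tolerance = 1e-10)
  ia <- fit$model$interactions
  expect_equal(ia$gamma, 1)
  expect_equal(fit$k, reduced$k)
})

test_that("the full fit never falls below the nested reduced fit", {
  set.seed(17)
  for (i in 1:5) {
    p <- simulate_mshc_fixed_n(test_reduced_model(), w100,
                               c(K = 10, A = 30), nprop = 1.2e4)
    fr <- fit_mshc(p, test_reduced_spec(), correction = "none")
    ff <- fit_mshc(p, test_full_spec(), correction = "none")
    expect_gte(ff$logPL, fr$logPL - 1e-8)
  }
})

test_that("refining the dummy grid changes logPL by little at the default", {
  p <- simulate_mshc_fixed_n(test_reduced_model(), w100,
                             c(K = 10, A = 30), nprop = 1.2e4, seed = 23)
  f10 <- fit_mshc(p, test_reduced_spec(), dummy_spacing = 10,
                  correction = "none")
  f5 <- fit_mshc(p, test_reduced_spec(), dummy_spacing = 5,
                 correction = "none")
  expect_lt(abs(f10$logPL - f5$logPL) / abs(f5$logPL), 0.05)
})

test_that("the interaction strength is recovered on synthetic data", {
  # truth gamma_AK = 3 with (h, r) = (1, 5); fit with true irregulars
  truth <- test_full_model(gamma = c(0.2, 0.5, 3))
  spec <- test_full_spec(h_cross = 1)
  w <- rect_window(c(0, 160), c(0, 120))
  set.seed(29)
  lg <- replicate(100, {
    p <- simulate_mshc_fixed_n(truth, w, c(K = 20, A = 80), nprop = 2.5e4)
    f <- fit_mshc(p, spec, correction = "none")
    ia <- f$model$interactions
    log(ia$gamma[ia$type1 == "A" & ia$type2 == "K"])
  })
  expect_gt(mean(exp(lg) > 1), 0.95)
  expect_lt(abs(median(lg) - log(3)) / log(3), 0.5)
})

test_that("profiling the irregulars finds the generating interaction range", {
  truth <- test_full_model(gamma = c(0.2, 0.5, 3.5), h_cross = 1)
  w <- rect_window(c(0, 160), c(0, 120))
  spec <- test_full_spec(h_cross = 1)
  set.seed(37)
  hits <- replicate(25, {
    p <- simulate_mshc_fixed_n(truth, w, c(K = 20, A = 80), nprop = 2.5e4)
    pr <- profile_irregulars(p, spec, c("A", "K"), h_values = 1,
                             r_values = c(3, 4, 5, 6, 7),
                             correction = "none")
    abs(pr$r - 5) <= 1
  })
  expect_gte(mean(hits), 0.8)

  # single-point grid returns that point; enlarging a grid never lowers max
  p <- simulate_mshc_fixed_n(truth, w, c(K = 20, A = 80), nprop = 2.5e4)
  pr1 <- profile_irregulars(p, spec, c("A", "K"), h_values = 1,
                            r_values = 5, correction = "none")
  expect_equal(pr1$r, 5)
  pr2 <- profile_irregulars(p, spec, c("A", "K"), h_values = 1,
                            r_values = c(4, 5, 6), correction = "none")
  expect_gte(max(pr2$grid$logPL), max(pr1$grid$logPL) - 1e-9)
})

test_that("the Monte Carlo ratio test is consistent with its parts", {
  p <- simulate_mshc_fixed_n(test_reduced_model(), w100,
                             c(K = 10, A = 30), nprop = 1.2e4, seed = 41)
  res <- mc_lr_test(p, test_reduced_spec(), test_full_spec(), nsim = 19,
                    dummy_spacing = 10, correction = "none", nprop = 1e4,
                    fixed_n = TRUE, seed = 43)
  fr <- fit_mshc(p, test_reduced_spec(), correction = "none")
  ff <- fit_mshc(p, test_full_spec(), correction = "none")
  expect_equal(res$delta_obs, pl_ratio(ff, fr), tolerance = 1e-10)
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
})
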