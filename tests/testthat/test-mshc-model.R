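w100 <- rect_window(c(0, 100), c(0, 100))

test_that("model construction enforces the parameter invariants", {
  expect_error(mshc_model(beta = c(K = -1, A = 1)), "positive")
  expect_error(
    mshc_model(interactions = data.frame(type1 = "K", type2 = "A",
                                         h = 5, r = 3, gamma = 2)),
    "must exceed")
  expect_error(
    mshc_model(interactions = data.frame(type1 = "K", type2 = "A",
                                         h = 1, r = 5, gamma = -0.5)),
    "gamma")
  # pure hard core (gamma = 1) may have r == h
  expect_silent(
    mshc_model(interactions = data.frame(type1 = "K", type2 = "K",
                                         h = 10, r = 10, gamma = 1)))
  # pairs are symmetric: KA and AK are the same row
  m <- mshc_model(interactions = data.frame(type1 = "A", type2 = "K",
                                            h = 1, r = 5, gamma = 2))
  expect_equal(m$interactions$type1, "A")
  expect_equal(m$interactions$type2, "K")
})

test_that("annulus pair counts follow the open-closed convention", {
  p <- tpp(c(50, 50.5, 53, 57), c(50, 50, 50, 50),
           c("K", "A", "A", "A"), w100)
  # opposing points at d = 0.5, 3, 7 from (50,50); (h, r) = (1, 5): count 1
  expect_equal(pair_count(50, 50, "K", p, c("K", "A"), 1, 5), 1)
  # boundary conventions: d = h excluded, d = r included
  expect_equal(pair_count(50, 50, "K", p, c("K", "A"), 0.5, 3), 1)
  expect_equal(pair_count(50, 50, "K", p, c("K", "A"), 0.4, 7), 3)
  # no opposing points
  expect_equal(pair_count(50, 50, "A", p, c("K", "A"), 1, 5), 0)

  p2 <- rpat(20, 30, w100, seed = 12)
  for (i in 1:10) {
    u <- runif(2, 0, 100)
    for (pair in list(c("K", "A"), c("A", "A")))
      expect_equal(pair_count(u[1], u[2], pair[1], p2, pair, 2, 15),
                   naive_pair_count(u[1], u[2], pair[1], p2, pair, 2, 15))
  }
})

test_that("conditional intensity follows the MSHC formula", {
  m <- mshc_model(beta = c(K = 0.01, A = 0.02),
                  interactions = data.frame(type1 = "A", type2 = "K",
                                            h = 1, r = 5, gamma = 3))
  # no neighbours anywhere near: lambda = beta
  p0 <- tpp(90, 90, factor("A", levels = c("K", "A")), w100)
  expect_equal(conditional_intensity(m, p0, 10, 10, "K"), 0.01)
  # one cross neighbour at d = 4 inside the annulus: lambda = beta * gamma
  p1 <- tpp(54, 50, factor("A", levels = c("K", "A")), w100)
  expect_equal(conditional_intensity(m, p1, 50, 50, "K"), 0.03)
  # neighbour inside the hard core: lambda = 0
  p2 <- tpp(50.5, 50, factor("A", levels = c("K", "A")), w100)
  expect_equal(conditional_intensity(m, p2, 50, 50, "K"), 0)
  # log-linearity: two annulus neighbours multiply by gamma^2
  p3 <- tpp(c(54, 46), c(50, 50), rep("A", 2), w100)
  p3$type <- factor(rep("A", 2), levels = c("K", "A"))
  expect_equal(conditional_intensity(m, p3, 50, 50, "K"), 0.01 * 9)
  # gamma = 0 with an occupied annulus is the valid limit 0, not an error
  m0 <- mshc_model(beta = c(K = 0.01, A = 0.02),
                   interactions = data.frame(type1 = "A", type2 = "K",
                                             h = 1, r = 5, gamma = 0))
  expect_equal(conditional_intensity(m0, p1, 50, 50, "K"), 0)
  expect_equal(conditional_intensity(m0, p0, 10, 10, "K"), 0.01)
})

test_that("covariates enter the conditional intensity log-linearly", {
  dc <- distance_covariate(0, 0)
  m <- mshc_model(beta = c(K = 0.01, A = 0.02),
                  covariates = list(d0 = list(cov = dc, types = "A",
                                              coef = -0.1)))
  p0 <- tpp(90, 90, factor("K", levels = c("K", "A")), w100)
  expect_equal(conditional_intensity(m, p0, 3, 4, "A"),
               0.02 * exp(-0.1 * 5))
  # covariate restricted to type A leaves K unchanged
  expect_equal(conditional_intensity(m, p0, 3, 4, "K"), 0.01)
})

test_that("the Poisson special case of the sampler has the right moments", {
  # gamma absent, beta * |W| = 50 expected points of each type
  m <- mshc_model(types = "A", beta = c(A = 50 / 1e4))
  set.seed(55)
  counts <- replicate(200, npoints(simulate_mshc(m, w100, nprop = 1e4)))
  se <- sqrt(50 / 200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.7)
  expect_lt(disp, 1.4)
})

test_that("sampled counts pass a chi-square goodness-of-fit against Poisson", {
  m <- mshc_model(types = "A", beta = c(A = 30 / 1e4))
  set.seed(91)
  counts <- replicate(500, npoints(simulate_mshc(m, w100, nprop = 8e3)))
  breaks <- c(-Inf, 22, 26, 30, 34, 38, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-Inf, 22, 26, 30, 34, 38, Inf), 30))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("hard cores are respected exactly by both samplers", {
  m <- test_full_model()
  set.seed(77)
  p <- simulate_mshc(
    mshc_model(beta = c(K = 3e-3, A = 6e-3),
               interactions = m$interactions), w100, nprop = 3e4)
  dk <- pairdist_matrix(p, "K", "K"); diag(dk) <- Inf
  da <- pairdist_matrix(p, "A", "A"); diag(da) <- Inf
  dx <- pairdist_matrix(p, "K", "A")
  expect_gt(min(dk), 5)
  expect_gt(min(da), 2)
  expect_gt(min(dx), 1)

  p2 <- simulate_mshc_fixed_n(m, w100, c(K = 8, A = 25), nprop = 2e4)
  dk2 <- pairdist_matrix(p2, "K", "K"); diag(dk2) <- Inf
  expect_gt(min(dk2), 5)
  expect_equal(npoints(p2, "K"), 8)
  expect_equal(npoints(p2, "A"), 25)
})

test_that("simulation is reproducible under a fixed seed", {
  m <- test_full_model()
  mb <- mshc_model(beta = c(K = 2e-3, A = 4e-3),
                   interactions = m$interactions)
  p1 <- simulate_mshc(mb, w100, nprop = 1e4, seed = 123)
  p2 <- simulate_mshc(mb, w100, nprop = 1e4, seed = 123)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
  expect_identical(p1$type, p2$type)
  q1 <- simulate_mshc_fixed_n(m, w100, c(K = 5, A = 10), nprop = 5e3,
                              seed = 9)
  q2 <- simulate_mshc_fixed_n(m, w100, c(K = 5, A = 10), nprop = 5e3,
                              seed = 9)
  expect_identical(q1$x, q2$x)
})

test_that("conditional simulation with one free point is uniform", {
  m <- mshc_model(types = "A", beta = c(A = 1))
  set.seed(101)
  xs <- replicate(200, {
    p <- simulate_mshc_fixed_n(m, w100, c(A = 1), nprop = 500)
    p$x
  })
  ks <- suppressWarnings(stats::ks.test(xs / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cross-type attraction shortens nearest-neighbour distances", {
  base <- test_reduced_model()
  attract <- test_full_model()
  set.seed(202)
  nn1 <- replicate(15, mean(nndist_type(
    simulate_mshc_fixed_n(attract, w100, c(K = 10, A = 30), nprop = 1.2e4),
    "A", "K")))
  nn0 <- replicate(15, mean(nndist_type(
    simulate_mshc_fixed_n(base, w100, c(K = 10, A = 30), nprop = 1.2e4),
    "A", "K")))
  expect_lt(mean(nn1), mean(nn0))
})

test_that("infeasible packings are detected", {
  m <- mshc_model(types = "K", beta = c(K = 1),
                  interactions = data.frame(type1 = "K", type2 = "K",
                                            h = 40, r = 40, gamma = 1))
  expect_error(
    simulate_mshc_fixed_n(m, w100, c(K = 30), nprop = 100, seed = 1,
                          max_tries = 200),
    "pack")
})
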