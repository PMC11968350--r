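test_that("Wald ratios follow the ratio formula and reject zero denominators", {
  pair <- toy_pair(
    gamma = c(0.5, -0.5), Gamma = c(0.25, 0.25),
    se_gamma = c(0.05, 0.05), se_Gamma = c(0.05, 0.05)
  )
  wr <- wald_ratios(pair)
  expect_equal(wr$beta, c(0.5, -0.5))
  expect_equal(wr$se, c(0.1, 0.1))
  bad <- toy_pair(gamma = c(0.5, 0), Gamma = c(0.1, 0.1))
  expect_error(wald_ratios(bad), "snp_2")
})

test_that("IVW matches an independent weighted-regression oracle", {
  set.seed(10)
  for (i in 1:10) {
    pair <- sim_pair(J = sample(3:20, 1), beta = runif(1, -0.5, 0.5))
    est <- mr_ivw(pair)
    oracle <- lm_ivw_oracle(pair)
    expect_equal(est$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(est$extras$se_fixed, oracle$se_fixed, tolerance = 1e-12)
    # normal-equation residual is zero
    w <- 1 / pair$se_Gamma^2
    expect_lt(abs(sum(w * pair$gamma * (pair$Gamma - est$beta * pair$gamma))), 1e-10)
  }
})

test_that("IVW handles homogeneity and never under-disperses", {
  # identical Wald ratios: beta recovered exactly, sigma = 0, SE = fixed SE
  g <- c(0.1, 0.2, 0.4)
  pair <- toy_pair(gamma = g, Gamma = 0.3 * g)
  est <- mr_ivw(pair)
  expect_equal(est$beta, 0.3)
  expect_equal(est$extras$sigma, 0)
  expect_equal(est$se, est$extras$se_fixed)
  # under-dispersed noisy data still floors at the fixed-effect SE
  set.seed(3)
  for (i in 1:20) {
    pair <- sim_pair(J = 10, beta = 0.2)
    est <- mr_ivw(pair)
    expect_gte(est$se, est$extras$se_fixed)
  }
  expect_error(mr_ivw(toy_pair(0.1, 0.1)), "at least 2")
})

test_that("Egger recovers a noiseless line and matches the lm oracle", {
  g <- seq(0.05, 0.5, length.out = 8)
  pair <- toy_pair(gamma = g, Gamma = 0.1 + 0.2 * g)
  est <- mr_egger(pair)
  expect_equal(est$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$extras$intercept, 0.1, tolerance = 1e-10)
  expect_equal(est$extras$sigma, 0, tolerance = 1e-6)

  set.seed(11)
  for (i in 1:10) {
    pair <- sim_pair(J = 15, beta = 0.3)
    est <- mr_egger(pair)
    oracle <- lm_egger_oracle(pair)
    expect_equal(est$beta, oracle$slope, tolerance = 1e-10)
    expect_equal(est$extras$intercept, oracle$intercept, tolerance = 1e-10)
  }
  expect_error(mr_egger(toy_pair(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("the weighted median interpolates the cumulative-weight midpoints", {
  # equal weights at {0.1, 0.2, 0.3}: S hits 0.5 exactly at the middle ratio
  pair <- toy_pair(
    gamma = c(1, 1, 1), Gamma = c(0.1, 0.2, 0.3),
    se_gamma = rep(0.01, 3), se_Gamma = rep(0.05, 3)
  )
  est <- mr_weighted_median(pair, n_boot = 0)
  expect_equal(est$beta, 0.2)
  # deterministic bootstrap SE under a fixed seed
  e1 <- mr_weighted_median(pair, n_boot = 200, seed = 42)
  e2 <- mr_weighted_median(pair, n_boot = 200, seed = 42)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se, 0)
  expect_error(mr_weighted_median(toy_pair(c(1, 1), c(1, 1))), "at least 3")
})

test_that("the weighted median resists 30% shifted instruments where IVW fails", {
  set.seed(77)
  hits <- 0
  for (i in 1:20) {
    J <- 30
    gamma_true <- rep(0.1, J)
    shift <- c(rep(0.8 * 0.1, 9), rep(0, 21)) # ratio moves to 1.0 for 30%
    g <- rnorm(J, gamma_true, 0.001)
    G <- rnorm(J, 0.2 * gamma_true + shift, 0.001)
    pair <- mr_pair(g, rep(0.001, J), G, rep(0.001, J))
    wm <- mr_weighted_median(pair, n_boot = 0)
    ivw <- mr_ivw(pair)
    if (abs(wm$beta - 0.2) < 0.05 && abs(ivw$beta - 0.2) > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the weighted mode finds the dominant cluster and stays in range", {
  pair <- toy_pair(
    gamma = rep(1, 4), Gamma = rep(0.25, 4),
    se_gamma = rep(0.01, 4), se_Gamma = rep(0.05, 4)
  )
  expect_equal(mr_weighted_mode(pair, n_boot = 0)$beta, 0.25)

  set.seed(12)
  ratios <- c(rnorm(12, 0.2, 0.01), runif(8, -1, 1)) # 60% tight cluster at 0.2
  g <- rep(1, 20)
  pair <- mr_pair(g, rep(0.01, 20), ratios, rep(0.05, 20))
  est <- mr_weighted_mode(pair, n_boot = 0)
  expect_lt(abs(est$beta - 0.2), 0.05)
  # doubling phi never leaves [min ratio, max ratio]
  for (phi in c(0.5, 1, 2, 4)) {
    b <- mr_weighted_mode(pair, phi = phi, n_boot = 0)$beta
    expect_gte(b, min(ratios))
    expect_lte(b, max(ratios))
  }
})

test_that("odds-ratio reporting exponentiates the estimate and its CI", {
  est <- mr_ivw(toy_pair(c(0.1, 0.2, 0.3), c(0, 0, 0)))
  est$beta <- 0
  est$se <- 0.05
  or0 <- to_odds_ratio(est)
  expect_equal(or0$or_, 1)
  expect_equal(or0$or_ci_low * or0$or_ci_high, 1, tolerance = 1e-12)

  est$beta <- 0.1
  or1 <- to_odds_ratio(est)
  expect_equal(or1$or_, exp(0.1))
  expect_equal(or1$or_ci_low, 1.00210, tolerance = 1e-3)
  expect_equal(or1$or_ci_high, 1.21885, tolerance = 1e-3)
  expect_true(or1$or_ci_low > 0 && or1$or_ci_high > 0)
})

test_that("all estimators agree on a single shared Wald ratio", {
  g <- c(0.1, 0.25, 0.4, 0.6)
  pair <- toy_pair(gamma = g, Gamma = 0.37 * g)
  expect_equal(mr_ivw(pair)$beta, 0.37)
  expect_equal(mr_egger(pair)$beta, 0.37, tolerance = 1e-10)
  expect_equal(mr_weighted_median(pair, n_boot = 0)$beta, 0.37)
  expect_equal(mr_weighted_mode(pair, n_boot = 0)$beta, 0.37)
})

test_that("estimators are scale-equivariant in the outcome", {
  set.seed(13)
  pair <- sim_pair(J = 12, beta = 0.25)
  cc <- 3.7
  scaled <- mr_pair(
    pair$gamma, pair$se_gamma, cc * pair$Gamma, cc * pair$se_Gamma,
    variant_id = pair$variant_id
  )
  for (f in list(
    function(p) mr_ivw(p),
    function(p) mr_egger(p),
    function(p) mr_weighted_median(p, n_boot = 100, seed = 5),
    function(p) mr_weighted_mode(p, n_boot = 100, seed = 5)
  )) {
    base <- f(pair)
    sc <- f(scaled)
    expect_equal(sc$beta, cc * base$beta, tolerance = 1e-8)
    expect_equal(sc$se, cc * base$se, tolerance = 1e-8)
  }
})
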