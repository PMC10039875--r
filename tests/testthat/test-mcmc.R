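test_that("the Hamiltonian sampler recovers a known bivariate normal
           posterior", {
  # independent N(1, 0.5^2) and N(-2, 2^2)
  lp <- function(q) {
    list(value = -0.5 * ((q[1] - 1) / 0.5)^2 - 0.5 * ((q[2] + 2) / 2)^2,
         grad = c(-(q[1] - 1) / 0.25, -(q[2] + 2) / 4))
  }
  fit <- hmc_sample(lp, c(0, 0), n_tune = 800, n_draws = 1500, chains = 2,
                    seed = 5)
  expect_lt(abs(mean(fit$draws[, 1]) - 1), 0.05)
  expect_lt(abs(mean(fit$draws[, 2]) + 2), 0.2)
  expect_lt(abs(sd(fit$draws[, 1]) - 0.5), 0.06)
  expect_lt(abs(sd(fit$draws[, 2]) - 2), 0.25)
  expect_true(all(fit$rhat < 1.05))
  expect_equal(fit$divergences, 0)
})

test_that("the sampler matches a conjugate gamma-Poisson posterior", {
  set.seed(11)
  y <- rpois(40, 3)
  a0 <- 2; b0 <- 1   # Gamma(shape, rate) prior
  lp <- function(q) {   # q = log rate
    lam <- exp(q)
    list(value = sum(y) * q - 40 * lam + a0 * q - b0 * lam,
         grad = sum(y) + a0 - (40 + b0) * lam)
  }
  fit <- hmc_sample(lp, 0, n_tune = 600, n_draws = 1500, chains = 2, seed = 2)
  lam_draws <- exp(fit$draws[, 1])
  a_post <- a0 + sum(y); b_post <- b0 + 40
  expect_lt(abs(mean(lam_draws) - a_post / b_post), 0.03)
  expect_lt(abs(sd(lam_draws) - sqrt(a_post) / b_post), 0.02)
})

test_that("PSIS-LOO reproduces reference values on a frozen fixture", {
  # fixture: Poisson data, lognormal posterior draws for the rate;
  # expected numbers computed with the reference PSIS-LOO implementation
  # in the arviz library on the identical matrix
  set.seed(42)
  y <- rpois(30, 3)
  lam <- exp(rnorm(500, log(3), 0.2))
  ll1 <- sapply(y, function(yy) dpois(yy, lam, log = TRUE))
  lam2 <- exp(rnorm(500, log(4), 0.2))
  ll2 <- sapply(y, function(yy) dpois(yy, lam2, log = TRUE))
  r1 <- psis_loo(ll1); r2 <- psis_loo(ll2)
  expect_equal(r1$elpd, -67.746992, tolerance = 1e-6)
  expect_equal(r2$elpd, -66.069358, tolerance = 1e-6)
  expect_equal(range(r1$khat), c(0.2113, 0.4626), tolerance = 1e-3)
})

test_that("pseudo-BMA weights are normalized, favour the better model,
           and agree with the reference implementation", {
  set.seed(42)
  y <- rpois(30, 3)
  lam <- exp(rnorm(500, log(3), 0.2))
  ll1 <- sapply(y, function(yy) dpois(yy, lam, log = TRUE))
  lam2 <- exp(rnorm(500, log(4), 0.2))
  ll2 <- sapply(y, function(yy) dpois(yy, lam2, log = TRUE))
  e1 <- psis_loo(ll1)$pointwise; e2 <- psis_loo(ll2)$pointwise
  w <- pseudo_bma_weights(list(e1, e2), seed = 9)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # reference value 0.6773 for the second model (bootstrap-stochastic)
  expect_lt(abs(w[2] - 0.6773), 0.05)
  # strongly separated models give near-degenerate weights
  w2 <- pseudo_bma_weights(list(e1 - 5, e1), seed = 9)
  expect_gt(w2[2], 0.99)
})

test_that("generalized Pareto tail fit recovers known shapes", {
  set.seed(13)
  for (k_true in c(0.2, 0.5)) {
    x <- (runif(4000)^(-k_true) - 1) / k_true   # GPD(sigma = 1, k)
    fit <- synaptomap:::gpd_fit(x)
    expect_lt(abs(fit$k - k_true), 0.1)
    expect_lt(abs(fit$sigma - 1), 0.15)
  }
})
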