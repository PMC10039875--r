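test_that("feature preprocessing applies the stated transforms and
           rejects out-of-domain rows", {
  t <- tibble::tibble(r_in_mohm = c(100, 150, -5),
                      sag_ratio = c(0.5, 1, 0.3),
                      dist_um = c(10, 20, 30),
                      connected = c(0, 1, 0))
  out <- preprocess_features(t)
  expect_equal(nrow(out), 1)
  expect_equal(out$r_in_mohm, log(100))
  expect_equal(out$sag_ratio, 0)         # logit(0.5)
  expect_equal(out$dist_um, 10)          # untouched
  rej <- attr(out, "rejected")
  expect_equal(nrow(rej), 2)
  expect_true(any(grepl("sag_ratio", rej$reason)))
  expect_true(any(grepl("r_in_mohm", rej$reason)))
})

test_that("robust ZCA whitening removes a known 2-feature correlation and
           is near-identity on uncorrelated data", {
  set.seed(31)
  n <- 10000
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  X <- MASS::mvrnorm(n, c(0, 0), S)
  wh <- robust_zca_whiten(X)
  cw <- cor(as.matrix(wh$whitened))
  expect_lt(abs(cw[1, 2]), 0.05)
  expect_lt(abs(sd(wh$whitened[[1]]) - 1), 0.1)
  # closed-form 2x2 ZCA of the true correlation for comparison
  ed <- eigen(S)
  W_true <- ed$vectors %*% diag(1 / sqrt(ed$values)) %*% t(ed$vectors)
  expect_lt(norm(wh$W - W_true, "F") / norm(W_true, "F"), 0.1)

  X0 <- matrix(rnorm(n * 4), n, 4)
  wh0 <- robust_zca_whiten(X0)
  off <- wh0$W - diag(4)
  expect_lt(max(abs(off)), 0.05)
})

test_that("MCD-based whitening resists 5% gross outliers", {
  set.seed(32)
  n <- 4000
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  X <- MASS::mvrnorm(n, rep(0, 3), S)
  W_clean <- robust_zca_whiten(X)$W
  Xc <- X
  idx <- sample(n, n * 0.05)
  Xc[idx, ] <- matrix(rnorm(length(idx) * 3, 0, 20), ncol = 3)
  W_cont <- robust_zca_whiten(Xc)$W
  expect_lt(norm(W_cont - W_clean, "F") / norm(W_clean, "F"), 0.1)
  expect_error(robust_zca_whiten(X[1:5, ]), "observations per feature")
})

test_that("cross-entropy controls match their closed forms", {
  y <- c(rep(1, 25), rep(0, 975))
  ch <- function(yy, pp) {
    pp <- pmin(pmax(pp, 1e-12), 1 - 1e-12)
    mean(-yy * log(pp) - (1 - yy) * log(1 - pp))
  }
  expect_equal(ch(y, rep(0.5, 1000)), log(2))
  expect_equal(ch(y, rep(0.025, 1000)),
               -(0.025 * log(0.025) + 0.975 * log(0.975)), tolerance = 1e-12)
  expect_equal(ch(y, y), 1e-12, tolerance = 1e-10)
})

test_that("cross-validated cross-entropy separates a real logistic signal
           from shuffled labels and shares folds across subsets", {
  set.seed(33)
  d <- simulate_pair_features(2000, c(0, 1.5, -1.5, rep(0, 4)), rho = 0,
                              n_binary = 0, prevalence = 0.15, seed = 33)
  X <- d[, 1:6]; y <- d$connected
  res <- cv_cross_entropy(X, y, n_folds = 30, n_shuffles = 30, seed = 5)
  expect_true(all(res$h_shuffle >= 0))
  expect_gt(mean(res$h_shuffle), res$h_full)
  expect_lt(res$h_cv, res$h_constant)   # informative features beat constant
  # folds depend only on the seed, so subsets share them
  res2 <- cv_cross_entropy(X[, 1:2], y, n_folds = 30, n_shuffles = 0,
                           seed = 5)
  expect_identical(res$folds, res2$folds)
  # pure-noise extra features do not shrink the overfitting gap
  gap_small <- res2$h_cv - with(res2, h_full)
  expect_gte(res$h_cv, res$h_full)      # CV never beats training fit here
})

test_that("whitening + regression predictions are invariant to affine
           feature rescaling", {
  set.seed(34)
  d <- simulate_pair_features(3000, c(0, 1, -1, 0, 0), rho = 0,
                              n_binary = 0, prevalence = 0.2, seed = 34)
  X <- as.matrix(d[, 1:4]); y <- d$connected
  fit1 <- suppressWarnings(glm(y ~ ., data = as.data.frame(scale(X)),
                               family = binomial()))
  X2 <- X
  X2[, 1] <- X2[, 1] * 7 - 3
  fit2 <- suppressWarnings(glm(y ~ ., data = as.data.frame(scale(X2)),
                               family = binomial()))
  expect_equal(fitted(fit1), fitted(fit2), tolerance = 1e-8)
})

test_that("the compiled Horseshoe log-posterior matches the reference R
           implementation and its finite-difference gradient", {
  set.seed(35)
  X <- matrix(rnorm(400 * 6), 400, 6)
  y <- rbinom(400, 1, 0.15)
  lp_r <- synaptomap:::make_horseshoe_lp(X, y)
  par <- rnorm(3 * 6 + 3, 0, 0.5)
  a <- lp_r(par)
  b <- synaptomap:::horseshoe_lp_grad(par, X, as.numeric(y), 3, -3.67, 1)
  expect_lt(abs(a$value - b$value), 1e-10)
  expect_lt(max(abs(a$grad - b$grad)), 1e-10)
  fd <- vapply(seq_along(par), function(i) {
    e <- 1e-6; pp <- par; pm <- par
    pp[i] <- pp[i] + e; pm[i] <- pm[i] - e
    (lp_r(pp)$value - lp_r(pm)$value) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(b$grad - fd)), 1e-6)
})
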