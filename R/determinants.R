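#' Variance-stabilizing transforms for cell-pair features
#'
#' Log-transforms strictly positive features (adaptation index, bursting
#' index, membrane capacitance, output gain, input resistance, spike
#' half-width by default) and logit-transforms features bounded in (0, 1)
#' (sag ratio); all other columns, including the binary connection-type
#' indicators and the label, pass through untouched. Rows violating a
#' transform's domain are rejected with the reason recorded.
#'
#' @param pairs cell-pair feature table (one row per pair).
#' @param log_features,logit_features character vectors of column names to
#'   transform; defaults are the features named above, intersected with
#'   the columns present.
#' @return The transformed tibble, with attribute `rejected` (tibble of
#'   dropped rows and reasons).
#' @export
preprocess_features <- function(pairs,
                                log_features = c("adaptation_index",
                                                 "bursting_index", "c_m_pf",
                                                 "gain_hz_pa", "r_in_mohm",
                                                 "spike_half_width_ms"),
                                logit_features = "sag_ratio") {
  pairs <- tibble::as_tibble(pairs)
  log_features <- intersect(log_features, names(pairs))
  logit_features <- intersect(logit_features, names(pairs))
  reason <- rep(NA_character_, nrow(pairs))
  for (cn in log_features) {
    bad <- !is.finite(pairs[[cn]]) | pairs[[cn]] <= 0
    reason[bad & is.na(reason)] <- paste0("non-positive ", cn)
  }
  for (cn in logit_features) {
    bad <- !is.finite(pairs[[cn]]) | pairs[[cn]] <= 0 | pairs[[cn]] >= 1
    reason[bad & is.na(reason)] <- paste0(cn, " outside (0,1)")
  }
  rejected <- dplyr::mutate(pairs[!is.na(reason), ],
                            reason = reason[!is.na(reason)])
  kept <- pairs[is.na(reason), ]
  for (cn in log_features) kept[[cn]] <- log(kept[[cn]])
  for (cn in logit_features) kept[[cn]] <- qlogis(kept[[cn]])
  structure(kept, rejected = rejected)
}

#' Robust ZCA whitening of a feature matrix
#'
#' Removes multicollinearity while keeping each whitened column maximally
#' similar to its original: features are standardized with robust
#' location/scale, the correlation matrix is estimated by the minimum
#' covariance determinant (MCD) method, and the symmetric whitening map
#' \eqn{W = U \Lambda^{-1/2} U^\top} from its eigendecomposition is
#' applied, so the whitened data have (robust) identity correlation and
#' unit variance per column.
#'
#' @param x numeric matrix or data frame of transformed features.
#' @param mcd_fraction fraction of observations in the MCD subsets
#'   (default 0.75).
#' @param seed seed for the MCD subsampling.
#' @return A list of class `zca_whitening`: `whitened` (tibble), `W`
#'   (whitening matrix), `center`, `scale`, `correlation`, `eigenvalues`.
#' @export
robust_zca_whiten <- function(x, mcd_fraction = 0.75, seed = 1) {
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  n <- nrow(xm); p <- ncol(xm)
  if (n <= 2 * p) abort("need more than 2 observations per feature")
  qu <- max(floor(mcd_fraction * n), p + 1)
  rob <- with_seed(derive_seed(seed, "mcd"), {
    MASS::cov.rob(xm, method = "mcd", quantile.used = qu)
  })
  ctr <- rob$center
  sc <- sqrt(diag(rob$cov))
  corr <- rob$cov / tcrossprod(sc)
  ed <- eigen(corr, symmetric = TRUE)
  if (min(ed$values) < 1e-8) {
    abort(sprintf("rank-deficient correlation: smallest eigenvalue %.3e",
                  min(ed$values)))
  }
  W <- ed$vectors %*% diag(1 / sqrt(ed$values), p) %*% t(ed$vectors)
  xs <- sweep(sweep(xm, 2, ctr), 2, sc, "/")
  wh <- xs %*% W
  colnames(wh) <- colnames(xm) %||% paste0("f", seq_len(p))
  structure(list(whitened = tibble::as_tibble(wh), W = W, center = ctr,
                 scale = sc, correlation = corr, eigenvalues = ed$values),
            class = "zca_whitening")
}

# --- Horseshoe-prior logistic regression ---------------------------------
# Non-centered formulation: beta = z * lambda * tau with
#   z, r_local, r_global ~ N(0,1)
#   rho_local ~ InvGamma(v/2, v/2) (v = 3), rho_global ~ InvGamma(0.5, 0.5)
#   lambda = r_local * sqrt(rho_local), tau = r_global * sqrt(rho_global)
#   beta0 ~ N(-3.67, 1)
# rho's are sampled on the log scale.
make_horseshoe_lp <- function(X, y, v = 3, beta0_mu = -3.67, beta0_sd = 1) {
  n <- nrow(X); p <- ncol(X)
  a_l <- v / 2; b_l <- v / 2
  a_g <- 0.5; b_g <- 0.5
  # parameter layout: z[p], r_local[p], log rho_local[p], r_global,
  #                   log rho_global, beta0
  function(par) {
    z <- par[1:p]
    rl <- par[(p + 1):(2 * p)]
    lrho_l <- par[(2 * p + 1):(3 * p)]
    rg <- par[3 * p + 1]
    lrho_g <- par[3 * p + 2]
    b0 <- par[3 * p + 3]
    rho_l <- exp(lrho_l); rho_g <- exp(lrho_g)
    lambda <- rl * sqrt(rho_l)
    tau <- rg * sqrt(rho_g)
    beta <- z * lambda * tau
    eta <- X %*% beta
    eta <- eta + b0
    pr <- 1 / (1 + exp(-eta))
    # numerically stable softplus without branching allocations
    softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    lp <- sum(y * eta) - sum(softplus) -
      0.5 * sum(z^2) - 0.5 * sum(rl^2) - 0.5 * rg^2 -
      sum(a_l * lrho_l + b_l / rho_l) - (a_g * lrho_g + b_g / rho_g) -
      0.5 * ((b0 - beta0_mu) / beta0_sd)^2
    resid <- y - pr                    # d loglik / d eta
    gbeta <- crossprod(X, resid)
    dim(gbeta) <- NULL
    gz <- gbeta * lambda * tau - z
    grl <- gbeta * z * sqrt(rho_l) * tau - rl
    glrho_l <- gbeta * z * rl * sqrt(rho_l) * tau * 0.5 - a_l + b_l / rho_l
    grg <- sum(gbeta * z * lambda) * sqrt(rho_g) - rg
    glrho_g <- sum(gbeta * beta) * 0.5 - a_g + b_g / rho_g
    gb0 <- sum(resid) - (b0 - beta0_mu) / beta0_sd^2
    list(value = lp, grad = c(gz, grl, glrho_l, grg, glrho_g, gb0))
  }
}

#' Sparse logistic regression with Horseshoe priors
#'
#' Bayesian logistic regression of the binary connection label on whitened
#' features under the Horseshoe shrinkage prior (non-centered
#' formulation: \eqn{\beta = z \lambda \tau} with half-Cauchy-type local
#' and global scales built from normal and inverse-gamma factors, and
#' \eqn{\beta_0 \sim N(-3.67, 1)}), sampled with Hamiltonian Monte Carlo.
#' Features whose posterior-median coefficient exceeds
#' `selection_threshold` in absolute value are selected.
#'
#' @param X whitened feature matrix (or `zca_whitening` result).
#' @param y binary 0/1 labels.
#' @param config a [sampler_config()]; the reference profile uses 10000
#'   tuning steps, 2000 draws, 4 chains.
#' @param v local inverse-gamma degrees of freedom (default 3).
#' @param selection_threshold absolute posterior-median cut (default 0.05,
#'   i.e. a 5% change in odds per SD of the feature).
#' @param seed integer seed.
#' @return A list of class `horseshoe_fit`: `beta` (draws matrix),
#'   `beta0` (draws), `summary` tibble (`feature`, `median`, `q05`,
#'   `q95`, `selected`), `selected` (character vector), diagnostics.
#' @export
fit_horseshoe_logistic <- function(X, y, config = sampler_config("fast"),
                                   v = 3, selection_threshold = 0.05,
                                   seed = 1) {
  if (inherits(X, "zca_whitening")) X <- X$whitened
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  p <- ncol(Xm)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  # compiled kernel; the R reference implementation (make_horseshoe_lp) is
  # kept and cross-checked against it in the tests
  lp <- function(par) horseshoe_lp_grad(par, Xm, y, v, -3.67, 1)
  init <- c(rep(0, p), rep(0.5, p), rep(0, p), 0.5, 0, qlogis(mean(y)))
  # the horseshoe funnel needs long trajectories and a high acceptance
  # target; short jittered trajectories under-explore the scale hierarchy
  fit <- hmc_sample(lp, init, n_tune = config$n_tune,
                    n_draws = config$n_draws, chains = config$chains,
                    seed = derive_seed(seed, "hs"),
                    target_accept = max(config$target_accept, 0.95),
                    max_leapfrog = 30, min_leapfrog = 15,
                    init_jitter = 0.05)
  dr <- fit$draws
  z <- dr[, 1:p, drop = FALSE]
  rl <- dr[, (p + 1):(2 * p), drop = FALSE]
  rho_l <- exp(dr[, (2 * p + 1):(3 * p), drop = FALSE])
  tau <- dr[, 3 * p + 1] * sqrt(exp(dr[, 3 * p + 2]))
  beta <- z * rl * sqrt(rho_l) * tau
  colnames(beta) <- colnames(Xm) %||% paste0("f", seq_len(p))
  med <- apply(beta, 2, median)
  summary <- tibble::tibble(
    feature = colnames(beta),
    median = med,
    q05 = apply(beta, 2, quantile, 0.05, names = FALSE),
    q95 = apply(beta, 2, quantile, 0.95, names = FALSE),
    selected = abs(med) > selection_threshold
  )
  beta_rhat <- split_rhat(lapply(fit$chain_draws, function(m) {
    zz <- m[, 1:p, drop = FALSE] * m[, (p + 1):(2 * p), drop = FALSE] *
      sqrt(exp(m[, (2 * p + 1):(3 * p), drop = FALSE])) *
      (m[, 3 * p + 1] * sqrt(exp(m[, 3 * p + 2])))
    zz
  }))
  structure(list(beta = beta, beta0 = dr[, 3 * p + 3], summary = summary,
                 selected = summary$feature[summary$selected],
                 accept_rate = fit$accept_rate,
                 divergences = fit$divergences,
                 max_rhat = max(beta_rhat, na.rm = TRUE),
                 reliable = max(beta_rhat, na.rm = TRUE) < 1.05),
            class = "horseshoe_fit")
}

#' Cross-validated cross-entropy of an unregularized logistic model
#'
#' Quantifies the predictive information of a feature subset: stratified
#' folds with exactly one positive pair per fold (negatives split evenly),
#' an unregularized logistic regression per fold, and the held-out
#' cross-entropy
#' \deqn{H = (1/n) \sum_i [-y_i \log \hat y_i - (1-y_i)\log(1-\hat y_i)]}
#' in nats, with probabilities clipped to `[1e-12, 1-1e-12]`. Also
#' returns the non-cross-validated H, a shuffled-label control, and the
#' constant-probability control. Fold assignment depends only on `seed`,
#' so different feature subsets evaluated with the same seed share folds
#' and can be compared pairwise.
#'
#' @param X feature matrix/data frame.
#' @param y binary 0/1 labels.
#' @param features optional character vector of columns to use (default
#'   all).
#' @param n_folds number of folds; default one per positive label.
#' @param n_shuffles shuffled-label control fits (default 200).
#' @param constant_p constant-probability control (default the label
#'   prevalence).
#' @param seed integer seed (controls folds and shuffles).
#' @return A list of class `cv_cross_entropy`: `cv` (per-fold tibble),
#'   `h_cv` (mean held-out H), `h_full` (no cross-validation),
#'   `h_shuffle` (vector), `h_constant`, `folds` (assignment), `skipped`.
#' @export
cv_cross_entropy <- function(X, y, features = NULL, n_folds = NULL,
                             n_shuffles = 200, constant_p = NULL, seed = 1) {
  X <- tibble::as_tibble(as.data.frame(X))
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- as.numeric(y)
  n <- length(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) abort("labels must contain both classes")
  n_folds <- n_folds %||% length(pos)
  if (n_folds > length(pos)) abort("more folds than positive labels")

  folds <- with_seed(derive_seed(seed, "folds"), {
    f <- integer(n)
    f[sample(pos)] <- rep_len(seq_len(n_folds), length(pos))
    f[sample(neg)] <- rep_len(seq_len(n_folds), length(neg))
    f
  })
  dat <- dplyr::mutate(X, .y = y)
  cross_h <- function(yy, pp) {
    pp <- pmin(pmax(pp, 1e-12), 1 - 1e-12)
    mean(-yy * log(pp) - (1 - yy) * log(1 - pp))
  }
  cv <- purrr::map_dfr(seq_len(n_folds), function(k) {
    tr <- dat[folds != k, ]; te <- dat[folds == k, ]
    if (length(unique(tr$.y)) < 2) {
      return(tibble::tibble(fold = k, h = NA_real_, n_test = nrow(te),
                            skipped = TRUE))
    }
    fit <- suppressWarnings(glm(.y ~ ., data = tr, family = binomial()))
    ph <- suppressWarnings(predict(fit, newdata = te, type = "response"))
    tibble::tibble(fold = k, h = cross_h(te$.y, ph), n_test = nrow(te),
                   skipped = FALSE)
  })
  full_fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  h_full <- cross_h(y, stats::fitted(full_fit))
  h_shuffle <- with_seed(derive_seed(seed, "shuffle"), {
    vapply(seq_len(n_shuffles), function(b) {
      ys <- sample(y)
      sf <- suppressWarnings(glm(ys ~ ., data = X, family = binomial()))
      cross_h(y, stats::fitted(sf))
    }, numeric(1))
  })
  p0 <- constant_p %||% mean(y)
  h_const <- cross_h(y, rep(p0, n))
  structure(list(cv = cv, h_cv = mean(cv$h, na.rm = TRUE), h_full = h_full,
                 h_shuffle = h_shuffle, h_constant = h_const,
                 folds = folds, skipped = sum(cv$skipped)),
            class = "cv_cross_entropy")
}
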