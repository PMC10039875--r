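#' Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO)
#'
#' Computes the expected log pointwise predictive density of a fitted
#' Bayesian model by leave-one-out cross-validation approximated with
#' Pareto-smoothed importance sampling: per-observation importance ratios
#' are tail-stabilized by fitting a generalized Pareto distribution to
#' their largest 20% and replacing them with expected order statistics.
#'
#' @param loglik matrix of pointwise log-likelihood values, one row per
#'   posterior draw and one column per observation.
#' @return A list: `elpd` (total), `pointwise` (per-observation elpd),
#'   `khat` (Pareto shape diagnostics).
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2)
  n <- ncol(loglik)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw - log_sum_exp(sm$lw)
    pointwise[i] <- log_sum_exp(lw + ll)
    khat[i] <- sm$khat
  }
  list(elpd = sum(pointwise), pointwise = pointwise, khat = khat)
}

# Smooth one vector of log importance ratios; returns log weights and khat.
psis_smooth <- function(lr) {
  s <- length(lr)
  lr <- lr - max(lr)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (m < 5 || length(unique(lr)) < 5) {
    return(list(lw = lr, khat = NA_real_))
  }
  ord <- order(lr)
  tail_ids <- ord[(s - m + 1):s]
  cutoff <- exp(lr[ord[s - m]])
  exc <- exp(lr[tail_ids]) - cutoff
  if (all(exc <= 0)) return(list(lw = lr, khat = NA_real_))
  fit <- gpd_fit(exc)
  if (!is.finite(fit$k)) return(list(lw = lr, khat = NA_real_))
  p <- (seq_len(m) - 0.5) / m
  smoothed <- if (abs(fit$k) < 1e-12) {
    cutoff - fit$sigma * log1p(-p)
  } else {
    cutoff + fit$sigma * expm1(-fit$k * log1p(-p)) / fit$k
  }
  lw <- lr
  lw[tail_ids[order(exc)]] <- log(pmin(smoothed, 1))  # ratios capped at max (=1 after shift)
  list(lw = lw, khat = fit$k)
}

# Zhang & Stephens (2009) empirical-Bayes generalized Pareto fit, with the
# weak prior regularization used in standard PSIS implementations.
gpd_fit <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3; prior_k <- 10
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[floor(n / 4 + 0.5)]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) mean(log1p(-b * x)), numeric(1))
  l_b <- n * (log(-(bs / ks)) - ks - 1)
  l_b[!is.finite(l_b)] <- -Inf
  w <- exp(l_b - log_sum_exp(l_b))
  b_hat <- sum(bs * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma <- -k_hat / b_hat
  k_hat <- (n * k_hat + prior_k * 0.5) / (n + prior_k)
  list(k = k_hat, sigma = sigma)
}

#' Bayesian-bootstrap pseudo-BMA model weights
#'
#' Converts the pointwise PSIS-LOO expected log predictive densities of
#' competing models into normalized model weights: each Bayesian-bootstrap
#' replicate draws Dirichlet(1, ..., 1) observation weights, computes each
#' model's weighted total elpd, and softmax-normalizes; weights are
#' averaged over replicates.
#'
#' @param pointwise list (or matrix columns) of per-observation elpd
#'   vectors, one per model, all the same length.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return Numeric vector of model weights summing to 1.
#' @export
pseudo_bma_weights <- function(pointwise, n_boot = 1000, seed = 1) {
  if (is.matrix(pointwise)) {
    pointwise <- lapply(seq_len(ncol(pointwise)), function(j) pointwise[, j])
  }
  k <- length(pointwise)
  n <- length(pointwise[[1]])
  stopifnot(all(lengths(pointwise) == n))
  if (n == 0) return(rep(1 / k, k))
  el <- do.call(cbind, pointwise)
  with_seed(derive_seed(seed, "bb"), {
    acc <- numeric(k)
    for (b in seq_len(n_boot)) {
      g <- rexp(n)
      wts <- g / sum(g)
      z <- n * drop(crossprod(wts, el))
      ww <- exp(z - max(z))
      acc <- acc + ww / sum(ww)
    }
    acc / n_boot
  })
}
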