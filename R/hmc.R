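#' Adaptive Hamiltonian Monte Carlo sampler
#'
#' A compact gradient-based MCMC sampler used by all Bayesian models in the
#' package: leapfrog integration with dual-averaging step-size adaptation
#' to a target acceptance rate, diagonal mass-matrix adaptation from the
#' middle of the warmup, and jittered trajectory lengths. Parameters are
#' sampled on an unconstrained scale supplied by the caller.
#'
#' @param lp_fun function of the parameter vector returning
#'   `list(value = log-posterior, grad = gradient vector)`.
#' @param init numeric initial parameter vector (unconstrained scale).
#' @param n_tune warmup iterations (discarded).
#' @param n_draws posterior draws kept per chain.
#' @param chains number of independent chains.
#' @param seed integer seed.
#' @param target_accept dual-averaging acceptance target (default 0.9).
#' @param max_leapfrog maximum leapfrog steps per trajectory.
#' @param min_leapfrog minimum leapfrog steps; each trajectory's length is
#'   drawn uniformly from `min_leapfrog..max_leapfrog`.
#' @param init_jitter sd of Gaussian jitter applied to `init` per chain.
#' @return A list of class `hmc_fit`: `draws` (matrix, all chains stacked),
#'   `chain_draws` (list of per-chain matrices), `accept_rate`,
#'   `divergences`, `rhat` (split-R-hat per parameter).
#' @export
hmc_sample <- function(lp_fun, init, n_tune = 1000, n_draws = 500,
                       chains = 2, seed = 1, target_accept = 0.9,
                       max_leapfrog = 12, min_leapfrog = 1, init_jitter = 0.1) {
  d <- length(init)
  chain_draws <- vector("list", chains)
  accepts <- 0; total <- 0; divergences <- 0

  for (ch in seq_len(chains)) {
    with_seed(derive_seed(seed, paste0("hmc", ch)), {
      q <- init + rnorm(d, 0, init_jitter)
      cur <- lp_fun(q)
      if (!is.finite(cur$value)) {
        q <- init
        cur <- lp_fun(q)
      }
      inv_mass <- rep(1, d)
      # reasonable initial step size
      eps <- 0.1 / sqrt(d)
      for (k in 1:30) {
        p <- rnorm(d) / sqrt(inv_mass)
        st <- leapfrog(q, p, eps, 1, lp_fun, inv_mass)
        a <- exp(min(0, st$h_new - st$h_old))
        if (is.finite(a) && a > 0.9) eps <- eps * 2
        else if (!is.finite(a) || a < 0.6) eps <- eps / 2
        else break
      }
      # dual averaging state
      mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
      gamma0 <- 0.05; t0 <- 10; kappa <- 0.75; m_adapt <- 0
      mass_lo <- floor(n_tune * 0.25); mass_hi <- floor(n_tune * 0.75)
      warm_qs <- matrix(NA_real_, max(mass_hi - mass_lo, 1), d)
      draws <- matrix(NA_real_, n_draws, d)

      for (it in seq_len(n_tune + n_draws)) {
        tuning <- it <= n_tune
        L <- if (max_leapfrog > min_leapfrog) {
          sample.int(max_leapfrog - min_leapfrog + 1, 1) + min_leapfrog - 1
        } else max_leapfrog
        p <- rnorm(d) / sqrt(inv_mass)
        st <- leapfrog(q, p, if (tuning) eps else exp(log_eps_bar),
                       L, lp_fun, inv_mass)
        delta_h <- st$h_new - st$h_old
        a <- if (is.finite(delta_h)) min(1, exp(delta_h)) else 0
        if (!tuning) {
          total <- total + 1
          if (is.finite(delta_h) && delta_h < -1000) {
            divergences <- divergences + 1
          }
          if (!is.finite(delta_h)) divergences <- divergences + 1
        }
        if (runif(1) < a) {
          q <- st$q; cur <- st$lp
          if (!tuning) accepts <- accepts + 1
        }
        if (tuning) {
          m_adapt <- m_adapt + 1
          frac <- 1 / (m_adapt + t0)
          h_bar <- (1 - frac) * h_bar + frac * (target_accept - a)
          log_eps <- mu - sqrt(m_adapt) / gamma0 * h_bar
          w <- m_adapt^(-kappa)
          log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
          eps <- exp(log_eps)
          if (it > mass_lo && it <= mass_hi) {
            warm_qs[it - mass_lo, ] <- q
          }
          if (it == mass_hi && mass_hi - mass_lo > 10) {
            v <- apply(warm_qs, 2, var)
            inv_mass <- pmax(v, 1e-8)
            # restart step-size adaptation for the new metric
            mu <- log(10 * exp(log_eps_bar)); m_adapt <- 0; h_bar <- 0
          }
        } else {
          draws[it - n_tune, ] <- q
        }
      }
      chain_draws[[ch]] <- draws
    })
  }
  all_draws <- do.call(rbind, chain_draws)
  structure(list(draws = all_draws, chain_draws = chain_draws,
                 accept_rate = accepts / max(total, 1),
                 divergences = divergences,
                 rhat = split_rhat(chain_draws)),
            class = "hmc_fit")
}

leapfrog <- function(q, p, eps, L, lp_fun, inv_mass) {
  lp <- lp_fun(q)
  h_old <- lp$value - 0.5 * sum(p^2 * inv_mass)
  g <- lp$grad
  for (l in seq_len(L)) {
    p <- p + 0.5 * eps * g
    q <- q + eps * (p * inv_mass)
    lp <- lp_fun(q)
    if (!is.finite(lp$value) || any(!is.finite(lp$grad))) {
      return(list(q = q, lp = lp, h_old = h_old, h_new = -Inf))
    }
    g <- lp$grad
    p <- p + 0.5 * eps * g
  }
  list(q = q, lp = lp, h_old = h_old,
       h_new = lp$value - 0.5 * sum(p^2 * inv_mass))
}

# split-R-hat (each chain halved), Gelman et al. style
split_rhat <- function(chain_draws) {
  halves <- list()
  for (m in chain_draws) {
    n2 <- floor(nrow(m) / 2)
    if (n2 < 2) return(rep(NA_real_, ncol(m)))
    halves <- c(halves, list(m[1:n2, , drop = FALSE]),
                list(m[(n2 + 1):(2 * n2), , drop = FALSE]))
  }
  vapply(seq_len(ncol(chain_draws[[1]])), function(j) {
    xs <- lapply(halves, function(m) m[, j])
    n <- length(xs[[1]]); k <- length(xs)
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, var, numeric(1))
    b <- n * var(means)
    w <- mean(vars)
    if (w < 1e-300) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
}
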