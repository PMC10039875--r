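#' Prior and sampler configuration for the connectivity models
#'
#' Gamma priors are parameterized by mean and standard deviation. Defaults:
#' the spontaneous-rate prior mean is the empirical spontaneous rate of the
#' recording (sd equal to the mean); the evoked-per-trial prior has mean
#' 0.5 and sd 0.5 events/stimulus; the fixed latency bump of the
#' connected/not-connected comparison has center 12.96 ms and width 6.33 ms
#' (the moments of the population latency gamma fit); the variable-bump
#' model uses a Gamma(mean 13, sd 5) prior on the center and a Gamma(mean
#' 5.5, sd 2) prior on the width truncated to [3, 8] ms.
#'
#' @param rate_mu,rate_sigma spontaneous-rate prior (events/ms); `NULL`
#'   means "use the empirical rate of the data".
#' @param ep_mu,ep_sigma evoked-events-per-trial prior.
#' @param bump_center_ms,bump_width_ms fixed bump used in models that test
#'   for a connection.
#' @param center_mu,center_sigma,width_mu,width_sigma,width_lo,width_hi
#'   variable-bump priors.
#' @return A list of class `connectivity_priors`.
#' @export
connectivity_priors <- function(rate_mu = NULL, rate_sigma = NULL,
                                ep_mu = 0.5, ep_sigma = 0.5,
                                bump_center_ms = 12.96, bump_width_ms = 6.33,
                                center_mu = 13, center_sigma = 5,
                                width_mu = 5.5, width_sigma = 2,
                                width_lo = 3, width_hi = 8) {
  structure(as.list(environment()), class = "connectivity_priors")
}

#' Sampler profiles for the connectivity models
#'
#' `"paper"` is the reference configuration (5000 tuning steps, 2000
#' draws, 4 chains, acceptance target 0.95); `"fast"` (1000 tuning steps,
#' 500 draws, 2 chains) is for routine use and tests.
#'
#' @param profile `"fast"` or `"paper"`.
#' @param ... overrides for `n_tune`, `n_draws`, `chains`, `target_accept`.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(profile = c("fast", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(n_tune = 5000, n_draws = 2000, chains = 4, target_accept = 0.95)
  } else {
    list(n_tune = 1000, n_draws = 500, chains = 2, target_accept = 0.9)
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "sampler_config")
}

# --- internal: assemble flat data vectors from stim_epoch_data ------------
epoch_vectors <- function(data) {
  reps <- sort(unique(c(data$spont$rep, data$evoked$rep)))
  list(
    reps = reps,
    sp_rep = match(data$spont$rep, reps),
    sp_t = data$spont$duration_ms,
    sp_n = data$spont$n_events,
    ev_rep = match(data$evoked$rep, reps),
    ev_t = data$evoked$duration_ms,
    ev_n = data$evoked$n_events,
    tm_rep = match(data$event_times$rep, reps),
    tm = data$event_times$latency_ms,
    window = data$evoked_ms %||% 90
  )
}

# Log-posterior + gradient factories. Parameters are unconstrained:
# log rates (one per repetition), log evoked-per-trial, and for the
# variable-bump model log center and a logit-box width.
make_rate_time_lp <- function(v, pr, connected, use_rates = TRUE,
                              use_times = TRUE, variable_bump = FALSE) {
  R <- length(v$reps)
  gr_rate <- gamma_mean_sd(pr$rate_mu, pr$rate_sigma)
  gr_ep <- gamma_mean_sd(pr$ep_mu, pr$ep_sigma)
  gb <- gamma_mean_sd(pr$bump_center_ms, pr$bump_width_ms)
  g_t <- if (use_times && length(v$tm)) {
    dgamma(v$tm, shape = gb$shape, scale = gb$scale)
  } else numeric(0)
  gr_c <- gamma_mean_sd(pr$center_mu, pr$center_sigma)
  gr_w <- gamma_mean_sd(pr$width_mu, pr$width_sigma)
  u0 <- 1 / v$window

  function(par) {
    i <- 0
    rate <- exp(par[seq_len(R)]); i <- R
    grad <- numeric(length(par))
    lp <- 0
    # priors on rates (incl. log Jacobian)
    lp <- lp + sum((gr_rate$shape - 1) * log(rate) - rate / gr_rate$scale +
                     par[seq_len(R)])
    grad[seq_len(R)] <- gr_rate$shape - rate / gr_rate$scale
    ep <- 0
    if (connected) {
      i <- i + 1
      ep <- exp(par[i])
      lp <- lp + (gr_ep$shape - 1) * log(ep) - ep / gr_ep$scale + par[i]
      grad[i] <- gr_ep$shape - ep / gr_ep$scale
    }
    i_ep <- if (connected) R + 1 else NA
    if (variable_bump) {
      cc <- exp(par[i + 1])
      sig <- stats::plogis(par[i + 2])
      wd <- pr$width_lo + (pr$width_hi - pr$width_lo) * sig
      lp <- lp + (gr_c$shape - 1) * log(cc) - cc / gr_c$scale + par[i + 1]
      grad[i + 1] <- gr_c$shape - cc / gr_c$scale
      dwd <- (wd - pr$width_lo) * (pr$width_hi - wd) /
        (pr$width_hi - pr$width_lo)
      lp <- lp + (gr_w$shape - 1) * log(wd) - wd / gr_w$scale + log(dwd)
      grad[i + 2] <- ((gr_w$shape - 1) / wd - 1 / gr_w$scale) * dwd +
        (1 - 2 * sig)
      g_t <- dnorm(v$tm, cc, wd)
    }

    if (use_rates) {
      lam_s <- rate[v$sp_rep] * v$sp_t
      lp <- lp + sum(v$sp_n * log(lam_s) - lam_s - lgamma(v$sp_n + 1))
      gs <- (v$sp_n - lam_s)   # d/d log rate contribution per obs
      for (r in seq_len(R)) {
        grad[r] <- grad[r] + sum(gs[v$sp_rep == r])
      }
      lam_e <- rate[v$ev_rep] * v$ev_t + ep
      lp <- lp + sum(v$ev_n * log(lam_e) - lam_e - lgamma(v$ev_n + 1))
      ge <- (v$ev_n / lam_e - 1)
      for (r in seq_len(R)) {
        sel <- v$ev_rep == r
        grad[r] <- grad[r] + sum(ge[sel] * rate[r] * v$ev_t[sel])
      }
      if (connected) grad[i_ep] <- grad[i_ep] + sum(ge) * ep
    }
    if (use_times && length(v$tm)) {
      if (connected) {
        denom <- ep + rate[v$tm_rep] * v$window
        w <- ep / denom
        f <- w * g_t + (1 - w) * u0
        lp <- lp + sum(log(f))
        dfdw <- (g_t - u0) / f
        # dw/d log rate_r = -ep * rate_r * window / denom^2
        for (r in seq_len(R)) {
          sel <- v$tm_rep == r
          if (any(sel)) {
            grad[r] <- grad[r] -
              sum(dfdw[sel] * ep * rate[r] * v$window / denom[sel]^2)
          }
        }
        grad[i_ep] <- grad[i_ep] +
          sum(dfdw * rate[v$tm_rep] * v$window * ep / denom^2)
        if (variable_bump) {
          dc <- sum(w * g_t * (v$tm - cc) / wd^2 / f) * cc
          dw_ <- sum(w * g_t * ((v$tm - cc)^2 / wd^3 - 1 / wd) / f) * dwd
          grad[i + 1] <- grad[i + 1] + dc
          grad[i + 2] <- grad[i + 2] + dw_
        }
      } else {
        lp <- lp + length(v$tm) * log(u0)
      }
    }
    list(value = lp, grad = grad)
  }
}

# time-only connected model: single mixture weight with Beta(2, 2) prior
make_time_only_lp <- function(v, alpha = 2, beta = 2) {
  gb <- gamma_mean_sd(12.96, 6.33)
  force(v)
  function(par, g_t, u0) {
    w <- stats::plogis(par)
    f <- w * g_t + (1 - w) * u0
    lp <- sum(log(f)) + (alpha - 1) * log(w) + (beta - 1) * log(1 - w) +
      log(w * (1 - w))
    grad <- (sum((g_t - u0) / f) + (alpha - 1) / w - (beta - 1) / (1 - w)) *
      w * (1 - w) + (1 - 2 * w)
    list(value = lp, grad = grad)
  }
}

# pointwise log-likelihood matrices (draws x observations)
pointwise_loglik <- function(draws, v, pr, connected, kind,
                             variable_bump = FALSE) {
  R <- length(v$reps)
  rate <- exp(draws[, seq_len(R), drop = FALSE])
  ep <- if (connected) exp(draws[, R + 1]) else rep(0, nrow(draws))
  gb <- gamma_mean_sd(pr$bump_center_ms, pr$bump_width_ms)
  u0 <- 1 / v$window
  out <- NULL
  if (kind %in% c("rate_time", "rate")) {
    lam_s <- rate[, v$sp_rep, drop = FALSE] *
      matrix(v$sp_t, nrow(draws), length(v$sp_t), byrow = TRUE)
    ll_s <- matrix(v$sp_n, nrow(draws), length(v$sp_n), byrow = TRUE)
    ll_s <- ll_s * log(lam_s) - lam_s -
      matrix(lgamma(v$sp_n + 1), nrow(draws), length(v$sp_n), byrow = TRUE)
    lam_e <- rate[, v$ev_rep, drop = FALSE] *
      matrix(v$ev_t, nrow(draws), length(v$ev_t), byrow = TRUE) + ep
    ll_e <- matrix(v$ev_n, nrow(draws), length(v$ev_n), byrow = TRUE)
    ll_e <- ll_e * log(lam_e) - lam_e -
      matrix(lgamma(v$ev_n + 1), nrow(draws), length(v$ev_n), byrow = TRUE)
    out <- cbind(ll_s, ll_e)
  }
  if (kind %in% c("rate_time", "time") && length(v$tm)) {
    g_t <- dgamma(v$tm, shape = gb$shape, scale = gb$scale)
    gmat <- matrix(g_t, nrow(draws), length(v$tm), byrow = TRUE)
    if (connected) {
      denom <- rate[, v$tm_rep, drop = FALSE] * v$window + ep
      w <- ep / denom
      ll_t <- log(w * gmat + (1 - w) * u0)
    } else {
      ll_t <- matrix(log(u0), nrow(draws), length(v$tm))
    }
    out <- cbind(out, ll_t)
  }
  out
}

#' Fit the connected/not-connected model comparisons for one target
#'
#' Fits the three Bayesian model pairs for a stimulated cell -- the
#' rate-and-time pair (Poisson segment counts plus the latency mixture),
#' the time-only pair (latency mixture alone, with a Beta(2,2) prior on
#' the bump weight in the connected variant and a parameter-free uniform
#' null), and the rate-only pair (Poisson counts alone) -- by Hamiltonian
#' Monte Carlo, scores each pair by PSIS-LOO, and converts the scores to
#' pseudo-BMA weights of the connected variant.
#'
#' @param data a [segment_epochs()] result.
#' @param priors a [connectivity_priors()] list.
#' @param config a [sampler_config()] list.
#' @param seed integer seed.
#' @return One-row tibble: `target_id`, `w_rt`, `w_t`, `w_r`, `connected`
#'   (the decision-rule verdict), sampler diagnostics (`max_rhat`,
#'   `divergences`, `reliable`), and the empirical spontaneous rate.
#' @export
fit_connectivity_models <- function(data, priors = connectivity_priors(),
                                    config = sampler_config("fast"),
                                    seed = 1) {
  stopifnot(inherits(data, "stim_epoch_data"))
  v <- epoch_vectors(data)
  if (!length(v$sp_t) || !length(v$ev_t)) {
    abort("epoch data must contain spontaneous and evoked segments")
  }
  pr <- priors
  emp_rate <- (sum(v$sp_n) + 1e-3) / sum(v$sp_t)  # events/ms, floored
  pr$rate_mu <- pr$rate_mu %||% emp_rate
  pr$rate_sigma <- pr$rate_sigma %||% pr$rate_mu
  R <- length(v$reps)
  init_rate <- rep(log(pr$rate_mu), R)

  run <- function(lp, init, stream) {
    hmc_sample(lp, init, n_tune = config$n_tune, n_draws = config$n_draws,
               chains = config$chains, seed = derive_seed(seed, stream),
               target_accept = config$target_accept)
  }
  max_rhat <- 0; ndiv <- 0
  note <- function(fit) {
    max_rhat <<- max(max_rhat, fit$rhat, na.rm = TRUE)
    ndiv <<- ndiv + fit$divergences
  }

  # rate-and-time pair (not-connected vs connected)
  f1 <- run(make_rate_time_lp(v, pr, connected = FALSE), init_rate, "m1")
  f2 <- run(make_rate_time_lp(v, pr, connected = TRUE),
            c(init_rate, log(pr$ep_mu)), "m2")
  note(f1); note(f2)
  ll1 <- pointwise_loglik(f1$draws, v, pr, FALSE, "rate_time")
  ll2 <- pointwise_loglik(f2$draws, v, pr, TRUE, "rate_time")
  w_rt <- pair_weight(ll1, ll2, seed)

  # time-only pair
  if (length(v$tm)) {
    gb <- gamma_mean_sd(pr$bump_center_ms, pr$bump_width_ms)
    g_t <- dgamma(v$tm, shape = gb$shape, scale = gb$scale)
    u0 <- 1 / v$window
    lp4_raw <- make_time_only_lp(v)
    lp4 <- function(par) lp4_raw(par, g_t, u0)
    f4 <- run(lp4, 0, "m4")
    note(f4)
    w_draws <- stats::plogis(f4$draws[, 1])
    ll4 <- log(outer(w_draws, g_t) + outer(1 - w_draws, rep(u0, length(g_t))))
    ll3 <- matrix(log(u0), nrow(ll4), ncol(ll4))
    w_t <- pair_weight(ll3, ll4, seed)
  } else {
    w_t <- 0.5
  }

  # rate-only pair
  f5 <- run(make_rate_time_lp(v, pr, connected = FALSE, use_times = FALSE),
            init_rate, "m5")
  f6 <- run(make_rate_time_lp(v, pr, connected = TRUE, use_times = FALSE),
            c(init_rate, log(pr$ep_mu)), "m6")
  note(f5); note(f6)
  ll5 <- pointwise_loglik(f5$draws, v, pr, FALSE, "rate")
  ll6 <- pointwise_loglik(f6$draws, v, pr, TRUE, "rate")
  w_r <- pair_weight(ll5, ll6, seed)

  tibble::tibble(
    target_id = data$target_id,
    w_rt = w_rt, w_t = w_t, w_r = w_r,
    connected = decide_connected(tibble::tibble(w_rt = w_rt, w_t = w_t,
                                                w_r = w_r))$connected,
    max_rhat = max_rhat, divergences = ndiv,
    reliable = max_rhat < 1.05,
    spont_rate_ms = emp_rate
  )
}

pair_weight <- function(ll_null, ll_conn, seed) {
  e0 <- psis_loo(ll_null)$pointwise
  e1 <- psis_loo(ll_conn)$pointwise
  w <- pseudo_bma_weights(list(e0, e1), seed = derive_seed(seed, "bma"))
  w[2]
}

#' Connection decision rule
#'
#' A stimulated cell is called putatively connected when all three
#' connected-model weights pass their thresholds:
#' \eqn{(w_{rt} \ge 0.5) \wedge (w_t \ge 0.4) \wedge (w_r \ge 0.4)}
#' (inclusive).
#'
#' @param weights data frame with columns `w_rt`, `w_t`, `w_r`.
#' @param thresholds numeric length-3 vector of thresholds.
#' @return The input with a logical `connected` column added.
#' @export
decide_connected <- function(weights, thresholds = c(0.5, 0.4, 0.4)) {
  stopifnot(all(c("w_rt", "w_t", "w_r") %in% names(weights)))
  with(weights, {
    if (any(c(w_rt, w_t, w_r) < 0 | c(w_rt, w_t, w_r) > 1)) {
      abort("model weights must lie in [0, 1]")
    }
  })
  dplyr::mutate(tibble::as_tibble(weights),
                connected = .data$w_rt >= thresholds[1] &
                  .data$w_t >= thresholds[2] &
                  .data$w_r >= thresholds[3])
}

#' Estimate the latency bump of a connected target
#'
#' Fits the variable-bump model: the connected rate-and-time model with a
#' normal latency bump whose center and width carry priors (width
#' truncated to [3, 8] ms), sampled by Hamiltonian Monte Carlo.
#'
#' @inheritParams fit_connectivity_models
#' @return A list of class `bump_fit` with posterior summary tibble
#'   (`parameter`, `median`, `mean`, `q05`, `q95`), the posterior draws,
#'   and diagnostics.
#' @export
fit_bump <- function(data, priors = connectivity_priors(),
                     config = sampler_config("fast"), seed = 1) {
  stopifnot(inherits(data, "stim_epoch_data"))
  v <- epoch_vectors(data)
  pr <- priors
  emp_rate <- (sum(v$sp_n) + 1e-3) / sum(v$sp_t)
  pr$rate_mu <- pr$rate_mu %||% emp_rate
  pr$rate_sigma <- pr$rate_sigma %||% pr$rate_mu
  R <- length(v$reps)
  lp <- make_rate_time_lp(v, pr, connected = TRUE, variable_bump = TRUE)
  init <- c(rep(log(pr$rate_mu), R), log(pr$ep_mu), log(pr$center_mu), 0)
  fit <- hmc_sample(lp, init, n_tune = config$n_tune,
                    n_draws = config$n_draws, chains = config$chains,
                    seed = derive_seed(seed, "m7"),
                    target_accept = config$target_accept)
  draws <- fit$draws
  nat <- cbind(exp(draws[, seq_len(R), drop = FALSE]),
               exp(draws[, R + 1]),
               exp(draws[, R + 2]),
               pr$width_lo + (pr$width_hi - pr$width_lo) *
                 stats::plogis(draws[, R + 3]))
  colnames(nat) <- c(paste0("spont_rate_ms_rep", v$reps),
                     "evoked_per_trial", "bump_center_ms", "bump_width_ms")
  summary <- purrr::map_dfr(colnames(nat), function(p) {
    x <- nat[, p]
    tibble::tibble(parameter = p, median = median(x), mean = mean(x),
                   q05 = quantile(x, 0.05, names = FALSE),
                   q95 = quantile(x, 0.95, names = FALSE))
  })
  structure(list(summary = summary, draws = nat,
                 target_id = data$target_id,
                 max_rhat = max(fit$rhat, na.rm = TRUE),
                 divergences = fit$divergences),
            class = "bump_fit")
}

#' Connectivity calls for every stimulated target of a recording
#'
#' Convenience driver: segments epochs, fits the model comparisons, applies
#' the decision rule, and for connected targets fits the latency bump and
#' computes connection strengths.
#'
#' @param events EPSC event table (`onset_ms`, `height_pa`).
#' @param schedule stimulation schedule.
#' @param targets target ids to process (default all in the schedule).
#' @param priors a [connectivity_priors()].
#' @param config a [sampler_config()].
#' @param strength_window_ms window for [stimulation_strengths()].
#' @param seed integer seed.
#' @param verbose print progress.
#' @return Tibble with one row per target: model weights, decision,
#'   diagnostics, and for connected targets `strength_pa`,
#'   `bump_center_ms`, `bump_width_ms` (posterior medians).
#' @export
infer_connectivity <- function(events, schedule, targets = NULL,
                               priors = connectivity_priors(),
                               config = sampler_config("fast"),
                               strength_window_ms = c(2, 30),
                               seed = 1, verbose = FALSE) {
  targets <- targets %||% sort(unique(schedule$target_id))
  if (is.null(priors$rate_mu)) {
    # rate prior centered on the pooled spontaneous rate of the recording
    pooled <- empirical_spont_rate(events, schedule)
    priors$rate_mu <- pooled
    priors$rate_sigma <- priors$rate_sigma %||% pooled
  }
  purrr::map_dfr(targets, function(tid) {
    ep <- segment_epochs(events, schedule, tid)
    call <- fit_connectivity_models(ep, priors, config,
                                    seed = derive_seed(seed, tid))
    call$strength_pa <- 0
    call$bump_center_ms <- NA_real_
    call$bump_width_ms <- NA_real_
    if (call$connected) {
      bf <- fit_bump(ep, priors, config, seed = derive_seed(seed, tid))
      st <- stimulation_strengths(events, schedule, tid, bf,
                                  window_ms = strength_window_ms)
      call$strength_pa <- st$strength_pa
      s <- bf$summary
      call$bump_center_ms <- s$median[s$parameter == "bump_center_ms"]
      call$bump_width_ms <- s$median[s$parameter == "bump_width_ms"]
    }
    if (verbose) {
      message(sprintf("target %s: w_rt=%.2f w_t=%.2f w_r=%.2f -> %s",
                      tid, call$w_rt, call$w_t, call$w_r, call$connected))
    }
    call
  })
}
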