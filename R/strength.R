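#' Per-stimulation synaptic strengths of a connected target
#'
#' The strength of a connection at each stimulation is the weighted
#' average of the EPSC amplitudes in a 2--30 ms window after the stimulus,
#' weighted by the posterior-median latency bump (a normal pdf at the
#' fitted bump center and width); spontaneous events far from the bump
#' therefore contribute little. Stimulations with no in-window events
#' contribute strength 0, and the connection strength is the mean over
#' stimulations.
#'
#' @param events EPSC event table with `onset_ms` and `height_pa`.
#' @param schedule the stimulation schedule.
#' @param target_id which stimulated cell.
#' @param bump a [fit_bump()] result (or a list with `bump_center_ms` and
#'   `bump_width_ms` scalars).
#' @param window_ms strength window after each stimulus (default c(2, 30)).
#' @return A list: `per_stimulation` tibble (`rep`, `pulse`, `time_ms`,
#'   `strength_pa`, `n_events`) and `strength_pa` (the per-connection
#'   mean).
#' @export
stimulation_strengths <- function(events, schedule, target_id, bump,
                                  window_ms = c(2, 30)) {
  if (inherits(bump, "bump_fit")) {
    s <- bump$summary
    center <- s$median[s$parameter == "bump_center_ms"]
    width <- s$median[s$parameter == "bump_width_ms"]
  } else {
    center <- bump$bump_center_ms
    width <- bump$bump_width_ms
  }
  stim <- schedule[schedule$target_id == target_id, ]
  if (!nrow(stim)) abort(sprintf("target %s not in schedule", target_id))
  per <- purrr::pmap_dfr(list(stim$rep, stim$pulse, stim$time_ms),
    function(rp, pl, s0) {
      lat <- events$onset_ms - s0
      sel <- lat >= window_ms[1] & lat <= window_ms[2]
      if (!any(sel)) {
        return(tibble::tibble(rep = rp, pulse = pl, time_ms = s0,
                              strength_pa = 0, n_events = 0L))
      }
      phi <- dnorm(lat[sel], center, width)
      if (sum(phi) < 1e-300) phi <- rep(1, sum(sel))
      tibble::tibble(rep = rp, pulse = pl, time_ms = s0,
                     strength_pa = sum(events$height_pa[sel] * phi) / sum(phi),
                     n_events = sum(sel))
    })
  list(per_stimulation = per, strength_pa = mean(per$strength_pa))
}

#' Fit a gamma + uniform mixture to pooled EPSC latencies
#'
#' Maximum-likelihood fit of the peristimulus latency density
#' \deqn{f(t) = w \, \mathrm{Gamma}(t; k, \theta) + (1 - w)/T}
#' on a window of length `window_ms` (the gamma component is renormalized
#' to the window so the density integrates to exactly 1). Confidence
#' intervals come from the observed information (inverted Hessian on the
#' unconstrained scale, delta method back).
#'
#' @param latencies_ms event latencies in (0, `window_ms`).
#' @param window_ms analysis window (default 90 ms).
#' @param conf confidence level (default 0.95).
#' @return A list of class `psth_mixture_fit`: `w`, `shape`, `scale`,
#'   their `conf` intervals (`ci` tibble), `loglik`, `n`, `window_ms`,
#'   `identified` (FALSE when w collapsed to ~0 so shape/scale are
#'   unidentified).
#' @export
fit_psth_mixture <- function(latencies_ms, window_ms = 90, conf = 0.95) {
  t <- latencies_ms[latencies_ms > 0 & latencies_ms < window_ms]
  if (length(t) < 100) abort("need at least 100 latencies for a stable fit")

  nll <- function(par) {
    w <- plogis(par[1]); k <- exp(par[2]); th <- exp(par[3])
    norm <- pgamma(window_ms, shape = k, scale = th)
    if (!is.finite(norm) || norm < 1e-12) return(1e10)
    if (!all(is.finite(c(w, k, th)))) return(1e10)
    g <- dgamma(t, shape = k, scale = th) / norm
    val <- -sum(log(w * g + (1 - w) / window_ms))
    if (!is.finite(val)) 1e10 else val
  }
  start <- c(qlogis(0.1), log(4), log(3))
  fit <- suppressWarnings(optim(start, nll, method = "BFGS", hessian = TRUE,
                                control = list(maxit = 500,
                                               reltol = 1e-12)))
  par <- fit$par
  w <- plogis(par[1]); k <- exp(par[2]); th <- exp(par[3])

  # delta method: d(nat)/d(unconstrained) is diagonal
  se_u <- rep(NA_real_, 3)
  cov_ok <- all(is.finite(fit$hessian))
  if (cov_ok) {
    ev <- eigen(fit$hessian, symmetric = TRUE, only.values = TRUE)$values
    cov_ok <- min(ev) > 1e-10
  }
  if (cov_ok) se_u <- sqrt(diag(solve(fit$hessian)))
  zc <- qnorm(1 - (1 - conf) / 2)
  jac <- c(w * (1 - w), k, th)
  se_nat <- se_u * jac
  ci <- tibble::tibble(
    parameter = c("w", "shape", "scale"),
    estimate = c(w, k, th),
    lower = c(w, k, th) - zc * se_nat,
    upper = c(w, k, th) + zc * se_nat
  )
  identified <- w > 1e-4 && cov_ok
  structure(list(w = w, shape = k, scale = th, ci = ci,
                 loglik = -fit$value, n = length(t), window_ms = window_ms,
                 conf = conf, identified = identified),
            class = "psth_mixture_fit")
}

#' Density of the fitted gamma + uniform latency mixture
#'
#' @param x latencies (ms).
#' @param fit a [fit_psth_mixture()] result.
#' @return Density values; zero outside (0, window).
#' @export
dpsth_mixture <- function(x, fit) {
  norm <- pgamma(fit$window_ms, shape = fit$shape, scale = fit$scale)
  g <- dgamma(x, shape = fit$shape, scale = fit$scale) / norm
  d <- fit$w * g + (1 - fit$w) / fit$window_ms
  ifelse(x > 0 & x < fit$window_ms, d, 0)
}

#' Sample from a gamma + uniform latency mixture
#'
#' @param n number of latencies.
#' @param w gamma-component weight.
#' @param shape,scale gamma parameters (ms).
#' @param window_ms window length (default 90).
#' @return Numeric vector of latencies in (0, window).
#' @export
rpsth_mixture <- function(n, w, shape, scale, window_ms = 90) {
  from_gamma <- runif(n) < w
  x <- numeric(n)
  ng <- sum(from_gamma)
  if (ng) {
    g <- rgamma(ng, shape = shape, scale = scale)
    # re-draw the rare samples beyond the window (truncated gamma)
    while (any(g >= window_ms)) {
      idx <- g >= window_ms
      g[idx] <- rgamma(sum(idx), shape = shape, scale = scale)
    }
    x[from_gamma] <- g
  }
  x[!from_gamma] <- runif(n - ng, 0, window_ms)
  x
}

#' Estimate the fraction of connected cells from the pooled EPSC latency
#' distribution
#'
#' Balances the total number of evoked events against the expected yield
#' of connected cells: with `E` total events, a fraction `f` of them in
#' the evoked bump, `N` stimulated cells, `n` stimulations per cell and
#' `e_p` evoked events per stimulation of a connected cell,
#' \deqn{\hat c = E f / (N \, n \, e_p).}
#'
#' @param total_events `E`, pooled EPSC count.
#' @param bump_fraction `f`, the gamma-component weight of the latency
#'   mixture, in `[0, 1]`.
#' @param n_cells `N`, number of stimulated cells.
#' @param mean_stimulations `n`, average stimulations per cell.
#' @param e_p assumed evoked events per stimulation for a connected cell.
#' @return The estimated connected fraction (scalar).
#' @examples
#' estimate_connected_fraction(151797, 0.046, 10445, 27.2, 0.5)  # ~0.049
#' @export
estimate_connected_fraction <- function(total_events, bump_fraction,
                                        n_cells, mean_stimulations, e_p) {
  assert_positive(total_events, "total_events")
  if (bump_fraction < 0 || bump_fraction > 1) {
    abort("`bump_fraction` must lie in [0, 1]")
  }
  denom <- n_cells * mean_stimulations * e_p
  if (!is.finite(denom) || denom <= 0) {
    abort("N * n * e_p must be positive")
  }
  total_events * bump_fraction / denom
}
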