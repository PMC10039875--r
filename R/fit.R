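#' Fit a cluster of putative events with a sum of synaptic kernels
#'
#' Decomposes a segment of the zero-baseline trace into a sum of
#' two-exponential EPSC waveforms plus a constant offset. The objective is
#' \deqn{RMS(S - \tilde s)/\widehat{SD} + RMS(o - \hat o)/5} with onsets in
#' ms: the residual misfit in noise units plus a penalty tying fitted
#' onsets to their provisional estimates. Heights and time constants are
#' optimized on the log scale inside the search boxes
#' \eqn{h \in [\hat h/15, 3\hat h]}, \eqn{o \in [\hat o - 10, \hat o + 10]},
#' \eqn{\tau_{decay} \in (0.5, 50)}, \eqn{\tau_{rise} \in (0.1, 10)} with
#' \eqn{\tau_{decay} > \tau_{rise}}. A simulated-annealing global search
#' (effort growing linearly with the number of events) is refined by a
#' derivative-free local polish.
#'
#' @param z a [detrend_and_noise()] result.
#' @param cluster one row of a [cluster_events()] table.
#' @param events the [detect_putative_events()] table the cluster indexes.
#' @param anneal_base,anneal_per_event simulated-annealing evaluation
#'   budget: `anneal_base + anneal_per_event * n_events`.
#' @param seed seed for the stochastic global search.
#' @return Tibble of fitted events: `onset_ms`, `height_pa`, `tau_rise_ms`,
#'   `tau_decay_ms`, `cluster_id`, `onset_hat_ms`, `height_hat_pa`,
#'   `fit_ok`.
#' @export
fit_cluster <- function(z, cluster, events, anneal_base = 1500,
                        anneal_per_event = 1500, seed = 1) {
  stopifnot(inherits(z, "zero_baseline_trace"))
  idx <- cluster$event_idx[[1]]
  ne <- length(idx)
  stopifnot(ne >= 1)
  dt_ms <- 1000 / z$rate_hz
  n <- length(z$samples)
  i0 <- max(1, floor(cluster$start_ms / dt_ms) + 1)
  i1 <- min(n, ceiling(cluster$end_ms / dt_ms) + 1)
  seg <- z$samples[i0:i1]
  t_ms <- (seq(i0, i1) - 1) * dt_ms
  sd_hat <- max(z$noise_sd, 1e-9)

  o_hat <- events$onset_hat_ms[idx]
  h_hat <- pmax(events$height_hat_pa[idx], 1e-3)

  lo_h <- h_hat / 15; hi_h <- 3 * h_hat
  lo_o <- o_hat - 10; hi_o <- o_hat + 10

  # box transform: p = lo + (hi-lo) * sigmoid(u); h, taus on log scale
  to_par <- function(u) {
    m <- matrix(u[seq_len(4 * ne)], ncol = 4)
    list(
      h   = exp(log(lo_h) + (log(hi_h) - log(lo_h)) * plogis(m[, 1])),
      o   = lo_o + (hi_o - lo_o) * plogis(m[, 2]),
      td  = exp(log(0.5) + (log(50) - log(0.5)) * plogis(m[, 3])),
      tr  = exp(log(0.1) + (log(10) - log(0.1)) * plogis(m[, 4])),
      c   = u[4 * ne + 1]
    )
  }
  model_trace <- function(p) {
    s <- rep(p$c, length(seg))
    for (i in seq_len(ne)) {
      tt <- t_ms - p$o[i]
      s <- s + p$h[i] * synaptic_kernel(tt, p$tr[i], p$td[i], normalize = TRUE)
    }
    s
  }
  objective <- function(u) {
    p <- to_par(u)
    if (any(p$td <= p$tr)) return(1e6)
    resid <- seg - model_trace(p)
    sqrt(mean(resid^2)) / sd_hat + sqrt(mean((p$o - o_hat)^2)) / 5
  }

  inv_sig <- function(x) qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6))
  u0 <- c(
    inv_sig((log(h_hat) - log(lo_h)) / (log(hi_h) - log(lo_h))),
    inv_sig((o_hat - lo_o) / (hi_o - lo_o)),
    rep(inv_sig((log(3.5) - log(0.5)) / (log(50) - log(0.5))), ne),
    rep(inv_sig((log(0.7) - log(0.1)) / (log(10) - log(0.1))), ne),
    0
  )

  fit <- with_seed(derive_seed(seed, paste0("fit", cluster$cluster_id)), {
    glob <- optim(u0, objective, method = "SANN",
                  control = list(maxit = anneal_base + anneal_per_event * ne,
                                 temp = 2, tmax = 10, parscale = rep(0.8, length(u0))))
    start <- if (glob$value < objective(u0)) glob$par else u0
    loc <- optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = 400 * (4 * ne + 1), reltol = 1e-9))
    if (loc$value <= glob$value) loc else glob
  })
  ok <- is.finite(fit$value) && fit$value < 1e6
  p <- to_par(fit$par)
  if (!ok) {
    p <- list(h = h_hat, o = o_hat, tr = rep(0.7, ne), td = rep(3.5, ne))
  }
  tibble::tibble(
    onset_ms = p$o, height_pa = p$h,
    tau_rise_ms = p$tr, tau_decay_ms = p$td,
    cluster_id = cluster$cluster_id,
    onset_hat_ms = o_hat, height_hat_pa = h_hat,
    fit_ok = ok
  )
}

#' Detect and model all EPSCs in a recording trace
#'
#' Runs the full six-step pipeline -- detrend, deconvolve, detect, cluster,
#' fit, threshold -- and returns the event table of all EPSCs whose fitted
#' height exceeds `height_threshold_sd` times \eqn{\widehat{SD}}.
#'
#' @param trace numeric current trace (pA) or a `sweep_trace`.
#' @param rate_hz sampling rate of a bare numeric trace.
#' @param height_threshold_sd final amplitude threshold in
#'   \eqn{\widehat{SD}} units (default 2.5).
#' @param seed seed for the stochastic cluster fits.
#' @param verbose print per-stage progress.
#' @inheritParams deconvolve
#' @inheritParams detect_putative_events
#' @return Tibble of EPSCs sorted by onset (`onset_ms`, `height_pa`,
#'   `tau_rise_ms`, `tau_decay_ms`, `cluster_id`, `fit_ok`), with
#'   attributes `noise_sd` and `n_prethreshold`.
#' @examples
#' \donttest{
#' sched <- make_stim_schedule(1, seed = 2)
#' truth <- make_ground_truth(sched, connected = FALSE, seed = 2)
#' rec <- simulate_trace(sched, truth, duration_ms = 4000, seed = 2)
#' detect_epscs(rec)
#' }
#' @export
detect_epscs <- function(trace, rate_hz = 5000, height_threshold_sd = 2.5,
                         threshold_sd = 0.5, segment_sd = 1.8, seed = 1,
                         verbose = FALSE) {
  z <- detrend_and_noise(trace, rate_hz)
  d <- deconvolve(z)
  ev <- detect_putative_events(d, threshold_sd = threshold_sd)
  empty <- tibble::tibble(onset_ms = numeric(), height_pa = numeric(),
                          tau_rise_ms = numeric(), tau_decay_ms = numeric(),
                          cluster_id = integer(), fit_ok = logical())
  if (!nrow(ev)) {
    return(structure(empty, noise_sd = z$noise_sd, n_prethreshold = 0L))
  }
  cl <- cluster_events(d, ev, segment_sd = segment_sd)
  if (verbose) message(nrow(ev), " putative events in ", nrow(cl), " clusters")
  fits <- purrr::map(seq_len(nrow(cl)), function(i) {
    fit_cluster(z, cl[i, ], ev, seed = derive_seed(seed, i))
  })
  fits <- dplyr::bind_rows(fits)
  n_pre <- nrow(fits)
  fits <- fits[fits$height_pa > height_threshold_sd * z$noise_sd, ]
  fits <- dplyr::arrange(fits, .data$onset_ms)
  fits <- dplyr::select(fits, "onset_ms", "height_pa", "tau_rise_ms",
                        "tau_decay_ms", "cluster_id", "fit_ok")
  structure(fits, noise_sd = z$noise_sd, n_prethreshold = n_pre)
}
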