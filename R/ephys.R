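#' Passive membrane properties from a current-step protocol
#'
#' From hyperpolarizing steps: input resistance from the peak voltage
#' deflection at the smallest negative current; the membrane time constant
#' from an exponential fit \eqn{a (1 - e^{-t/\tau_m}) + c} over the 10--90%
#' rise to peak hyperpolarization; capacitance as \eqn{C_m = \tau_m/R_{in}};
#' and the sag ratio \eqn{(V_{min} - V_{ss})/(V_{min} - V_{bl})} from the
#' strongest hyperpolarizing sweep, with \eqn{V_{min}} taken during the
#' first 30% of the pulse.
#'
#' @param sweeps tibble with one row per sweep: `current_pa` (step
#'   amplitude), and a list-column `voltage_mv` of voltage traces (mV).
#' @param rate_hz sampling rate of the voltage traces.
#' @param step_start_ms,step_end_ms step onset/offset within each sweep.
#' @return One-row tibble: `r_in_mohm`, `tau_m_ms`, `c_m_pf`,
#'   `sag_ratio`, `ok` (FALSE with NAs when no hyperpolarizing sweep).
#' @export
passive_properties <- function(sweeps, rate_hz = 5000, step_start_ms = 100,
                               step_end_ms = 600) {
  hyper <- sweeps[sweeps$current_pa < 0, ]
  if (!nrow(hyper)) {
    return(tibble::tibble(r_in_mohm = NA_real_, tau_m_ms = NA_real_,
                          c_m_pf = NA_real_, sag_ratio = NA_real_,
                          ok = FALSE))
  }
  dt_ms <- 1000 / rate_hz
  i0 <- round(step_start_ms / dt_ms) + 1
  i1 <- round(step_end_ms / dt_ms)

  smallest <- hyper[which.min(abs(hyper$current_pa)), ]
  v <- smallest$voltage_mv[[1]]
  v_bl <- mean(v[seq_len(i0 - 1)])
  seg <- v[i0:i1]
  pk <- which.min(seg)
  dv_peak <- v_bl - seg[pk]                       # mV, positive
  r_in <- dv_peak / abs(smallest$current_pa) * 1e3  # mV/pA = GOhm -> MOhm

  # tau_m: fit a(1 - exp(-t/tau)) + c on the 10-90% stretch of the decay
  drop <- v_bl - seg[seq_len(pk)]
  j10 <- which(drop >= 0.1 * dv_peak)[1]
  j90 <- which(drop >= 0.9 * dv_peak)[1]
  tau_m <- NA_real_
  if (!is.na(j10) && !is.na(j90) && j90 > j10 + 3) {
    tt <- (seq(j10, j90) - 1) * dt_ms
    yy <- drop[j10:j90]
    fit <- try(suppressWarnings(
      stats::nls(yy ~ a * (1 - exp(-tt / tau)) + c0,
                 start = list(a = dv_peak, tau = 20, c0 = 0),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      tau_m <- abs(coef(fit)[["tau"]])
    }
  }
  if (is.na(tau_m)) {
    # fall back to the 63% crossing of the rise
    j63 <- which(drop >= (1 - exp(-1)) * dv_peak)[1]
    tau_m <- (j63 - j10) * dt_ms
  }
  c_m <- tau_m / r_in * 1e3  # ms/MOhm -> nF*? : tau[ms]/R[MOhm] = nF -> pF x1e3

  strongest <- hyper[which.max(abs(hyper$current_pa)), ]
  vs <- strongest$voltage_mv[[1]]
  v_bl_s <- mean(vs[seq_len(i0 - 1)])
  seg_s <- vs[i0:i1]
  first30 <- seg_s[seq_len(max(1, floor(length(seg_s) * 0.3)))]
  v_min <- min(first30)
  v_ss <- mean(seg_s[floor(length(seg_s) * 0.7):length(seg_s)])
  sag <- if (abs(v_min - v_bl_s) < 1e-12) 0 else {
    (v_min - v_ss) / (v_min - v_bl_s)
  }
  tibble::tibble(r_in_mohm = r_in, tau_m_ms = tau_m, c_m_pf = c_m,
                 sag_ratio = min(max(sag, 0), 1), ok = TRUE)
}

detect_spikes <- function(v, rate_hz, threshold_mv = 0) {
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv)
  up
}

spike_features_one <- function(v, rate_hz, dvdt_thresh = 20) {
  dt_ms <- 1000 / rate_hz
  crossings <- detect_spikes(v, rate_hz)
  if (!length(crossings)) return(NULL)
  c1 <- crossings[1]
  # peak after the first crossing
  seg_end <- min(length(v), c1 + round(5 / dt_ms))
  pk <- c1 - 1 + which.max(v[c1:seg_end])
  # threshold: where dV/dt first exceeds dvdt_thresh before the peak
  dvdt <- c(0, diff(v)) / dt_ms
  back <- max(1, pk - round(5 / dt_ms))
  th_idx <- which(dvdt[back:pk] > dvdt_thresh)
  th_idx <- if (length(th_idx)) back + th_idx[1] - 1 else c1
  v_thresh <- v[th_idx]
  amp <- v[pk] - v_thresh
  half <- v_thresh + amp / 2
  above <- which(v >= half)
  above <- above[above >= th_idx & above <= min(length(v), pk + round(5 / dt_ms))]
  hw <- if (length(above) >= 2) (max(above) - min(above)) * dt_ms else NA_real_
  list(threshold_mv = v_thresh, amplitude_mv = amp, half_width_ms = hw)
}

#' Firing properties from a current-step protocol
#'
#' Spike counts per sweep give the input-output (f-I) curve; the output
#' gain is the regression slope of firing rate on injected current over
#' the sweeps between the minimal and maximal nonzero firing rates (the
#' two-point slope is available via `gain_method`). The bursting index is
#' the ratio of the second to the first inter-spike interval and the
#' adaptation index the ratio of the last to the second, both measured on
#' the sweep with firing rate closest to 80% of the maximum (ties broken
#' toward the lower current). Spike waveform features come from the first
#' spike of the lowest-rate spiking sweep; the threshold is where dV/dt
#' first exceeds 20 mV/ms before the peak.
#'
#' @inheritParams passive_properties
#' @param gain_method `"regression"` (default) or `"two_point"`.
#' @param dvdt_thresh spike-threshold criterion (mV/ms, default 20).
#' @return One-row tibble: `max_rate_hz`, `gain_hz_pa`, `bursting_index`,
#'   `adaptation_index`, `spike_threshold_mv`, `spike_amplitude_mv`,
#'   `spike_half_width_ms`, `ok`.
#' @export
active_properties <- function(sweeps, rate_hz = 5000, step_start_ms = 100,
                              step_end_ms = 600,
                              gain_method = c("regression", "two_point"),
                              dvdt_thresh = 20) {
  gain_method <- match.arg(gain_method)
  dt_ms <- 1000 / rate_hz
  dur_s <- (step_end_ms - step_start_ms) / 1000
  i0 <- round(step_start_ms / dt_ms) + 1
  i1 <- round(step_end_ms / dt_ms)

  info <- purrr::map_dfr(seq_len(nrow(sweeps)), function(i) {
    v <- sweeps$voltage_mv[[i]][i0:i1]
    sp <- detect_spikes(v, rate_hz)
    tibble::tibble(current_pa = sweeps$current_pa[i], n_spikes = length(sp),
                   rate_hz_fire = length(sp) / dur_s)
  })
  spiking <- info[info$n_spikes > 0, ]
  na_row <- tibble::tibble(max_rate_hz = NA_real_, gain_hz_pa = NA_real_,
                           bursting_index = NA_real_,
                           adaptation_index = NA_real_,
                           spike_threshold_mv = NA_real_,
                           spike_amplitude_mv = NA_real_,
                           spike_half_width_ms = NA_real_, ok = FALSE)
  if (nrow(spiking) < 2) return(na_row)

  max_rate <- max(spiking$rate_hz_fire)
  rng <- spiking[spiking$rate_hz_fire >= min(spiking$rate_hz_fire) &
                   spiking$rate_hz_fire <= max_rate, ]
  gain <- if (gain_method == "regression" && nrow(rng) >= 2) {
    unname(coef(lm(rate_hz_fire ~ current_pa, data = rng))[2])
  } else {
    lo <- rng[which.min(rng$rate_hz_fire), ]
    hi <- rng[which.max(rng$rate_hz_fire), ]
    (hi$rate_hz_fire - lo$rate_hz_fire) / (hi$current_pa - lo$current_pa)
  }

  # indices on the sweep closest to 80% of max rate (lower current on ties)
  tgt <- 0.8 * max_rate
  dists <- abs(spiking$rate_hz_fire - tgt)
  cand <- which(dists == min(dists))
  sel <- cand[which.min(spiking$current_pa[cand])]
  row80 <- which(sweeps$current_pa == spiking$current_pa[sel])[1]
  v80 <- sweeps$voltage_mv[[row80]][i0:i1]
  sp80 <- detect_spikes(v80, rate_hz)
  burst <- adapt <- NA_real_
  if (length(sp80) >= 3) {
    isi <- diff(sp80) * dt_ms
    burst <- isi[2] / isi[1]
    adapt <- isi[length(isi)] / isi[2]
  }

  lowest <- which(sweeps$current_pa ==
                    spiking$current_pa[which.min(spiking$rate_hz_fire)])[1]
  wf <- spike_features_one(sweeps$voltage_mv[[lowest]][i0:i1], rate_hz,
                           dvdt_thresh)
  tibble::tibble(
    max_rate_hz = max_rate, gain_hz_pa = gain,
    bursting_index = burst, adaptation_index = adapt,
    spike_threshold_mv = wf$threshold_mv %||% NA_real_,
    spike_amplitude_mv = wf$amplitude_mv %||% NA_real_,
    spike_half_width_ms = wf$half_width_ms %||% NA_real_,
    ok = !is.na(burst)
  )
}

#' Validate spiking of a stimulated target from its fluorescence train
#'
#' A stimulated cell is accepted as having spiked when the ordinary
#' least-squares slope of its raw calcium-indicator fluorescence across
#' the stimulus train has a lower 95% confidence bound of at least zero;
#' cells with a negative lower bound are excluded. \eqn{\Delta F/F_0} uses
#' the first stimulus as baseline.
#'
#' @param fluorescence per-stimulus fluorescence values (>= 5).
#' @param conf confidence level (default 0.95).
#' @return One-row tibble: `validated`, `slope`, `lower`, `upper`,
#'   `dff` (list-column with the \eqn{\Delta F/F_0} vector).
#' @export
gcamp_spike_validation <- function(fluorescence, conf = 0.95) {
  f <- as.numeric(fluorescence)
  if (length(f) < 5) abort("need at least 5 per-stimulus values")
  idx <- seq_along(f)
  if (var(f) < 1e-24) {
    return(tibble::tibble(validated = FALSE, slope = 0,
                          lower = NA_real_, upper = NA_real_,
                          dff = list(rep(0, length(f)))))
  }
  fit <- lm(f ~ idx)
  ci <- confint(fit, "idx", level = conf)
  f0 <- f[1]
  tibble::tibble(validated = ci[1] >= 0,
                 slope = unname(coef(fit)[2]),
                 lower = ci[1], upper = ci[2],
                 dff = list((f - f0) / f0))
}
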