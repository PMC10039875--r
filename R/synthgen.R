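#' Build a stimulation schedule for sequential single-cell mapping
#'
#' Emulates the sequential spiral-scan protocol: each target cell receives
#' trains of brief pulses at a fixed inter-pulse interval, optionally
#' repeated; trains of distinct targets never overlap. Each target also
#' gets a random 3-D position inside the scanned volume.
#'
#' @param n_targets number of stimulated (candidate presynaptic) cells.
#' @param n_pulses pulses per train (default 10, as in a 10-spiral train).
#' @param ipi_ms inter-pulse interval (ms; default 100, i.e. 10 Hz).
#' @param pulse_ms pulse (spiral) duration in ms (default 7.2).
#' @param repetitions number of protocol repetitions per target (1--3).
#' @param gap_ms silent gap between consecutive trains (ms).
#' @param volume_um extent (x, y, z) of the scanned volume in um.
#' @param seed master seed; the schedule is deterministic given the seed.
#' @return A `stim_schedule`: a tibble with one row per stimulation
#'   (`target_id`, `rep`, `pulse`, `time_ms`, `x_um`, `y_um`, `z_um`,
#'   `pulse_ms`), plus attributes `n_targets` and `duration_ms`.
#' @examples
#' sched <- make_stim_schedule(3, n_pulses = 10, repetitions = 2, seed = 1)
#' dplyr::count(sched, target_id)  # 20 stimulations per target
#' @export
make_stim_schedule <- function(n_targets, n_pulses = 10, ipi_ms = 100,
                               pulse_ms = 7.2, repetitions = 1,
                               gap_ms = 500,
                               volume_um = c(420, 420, 300), seed = 1) {
  n_targets <- assert_count(n_targets, "n_targets")
  n_pulses <- assert_count(n_pulses, "n_pulses")
  repetitions <- assert_count(repetitions, "repetitions")
  assert_positive(ipi_ms, "ipi_ms")
  assert_positive(gap_ms, "gap_ms")

  pos <- with_seed(derive_seed(seed, "schedule_pos"), {
    tibble::tibble(
      target_id = seq_len(n_targets),
      x_um = runif(n_targets, 0, volume_um[1]),
      y_um = runif(n_targets, 0, volume_um[2]),
      z_um = runif(n_targets, 0, volume_um[3])
    )
  })

  train_len <- (n_pulses - 1) * ipi_ms + pulse_ms
  # interleave repetitions the way the protocol does: full pass over all
  # targets, then repeat the pass
  order_tbl <- tidyr::expand_grid(rep = seq_len(repetitions),
                                  target_id = seq_len(n_targets))
  order_tbl$train_start <- (seq_len(nrow(order_tbl)) - 1) * (train_len + gap_ms)

  sched <- tidyr::expand_grid(order_tbl, pulse = seq_len(n_pulses))
  sched <- dplyr::mutate(sched,
    time_ms = .data$train_start + (.data$pulse - 1) * ipi_ms,
    pulse_ms = pulse_ms
  )
  sched <- dplyr::left_join(sched, pos, by = "target_id")
  sched <- dplyr::select(sched, "target_id", "rep", "pulse", "time_ms",
                         "x_um", "y_um", "z_um", "pulse_ms")
  sched <- dplyr::arrange(sched, .data$time_ms)
  structure(
    tibble::new_tibble(sched, class = "stim_schedule"),
    n_targets = n_targets,
    duration_ms = max(sched$time_ms) + train_len + gap_ms
  )
}

#' Ground-truth specification for a simulated recording
#'
#' Collects everything the generator needs to render a recording with known
#' truth: which targets are connected, the evoked-event rate per stimulus
#' (`e_p`), the latency bump, the spontaneous EPSC rate, amplitude
#' distribution, noise and drift, and optional direct photocurrents.
#'
#' @param schedule a [make_stim_schedule()] result.
#' @param connected logical vector (one per target) or a fraction in (0,1)
#'   interpreted as the connection probability.
#' @param e_p mean number of evoked EPSCs per stimulation for connected
#'   targets (events/stimulus).
#' @param bump_center_ms,bump_width_ms mean and sd of the evoked-latency
#'   bump. Defaults are the moments of the population latency gamma fit
#'   (shape 4.1896, scale 3.0942 ms): mean 12.96 ms, sd 6.33 ms.
#' @param bump_family `"gamma"` (default) or `"normal"` latency bump.
#' @param spont_rate_hz spontaneous EPSC rate (Hz).
#' @param amp_meanlog,amp_sdlog lognormal amplitude distribution (pA) for
#'   both spontaneous and evoked events.
#' @param noise_sd_pa white-noise standard deviation (pA).
#' @param drift_amp_pa,drift_freq_hz amplitude (pA) and corner frequency of
#'   the slow sinusoid-like baseline drift; `drift_amp_pa = 0` disables it.
#' @param photocurrent_pa named numeric vector: direct photocurrent
#'   amplitude (pA) per target id (absent targets get none).
#' @param seed master seed used to draw the connected flags when
#'   `connected` is a fraction.
#' @return A `ground_truth` list.
#' @export
make_ground_truth <- function(schedule,
                              connected = 0.5,
                              e_p = 0.5,
                              bump_center_ms = 12.96,
                              bump_width_ms = 6.33,
                              bump_family = c("gamma", "normal"),
                              spont_rate_hz = 2,
                              amp_meanlog = log(15) - 0.5 * 0.4^2,
                              amp_sdlog = 0.4,
                              noise_sd_pa = 2,
                              drift_amp_pa = 0,
                              drift_freq_hz = 0.5,
                              photocurrent_pa = NULL,
                              seed = 1) {
  bump_family <- match.arg(bump_family)
  n_targets <- attr(schedule, "n_targets")
  assert_positive(e_p, "e_p", strict = FALSE)
  assert_positive(spont_rate_hz, "spont_rate_hz", strict = FALSE)
  if (bump_center_ms <= 0 || bump_center_ms >= 90) {
    abort("`bump_center_ms` must lie in (0, 90) ms")
  }
  if (length(connected) == 1 && !is.logical(connected)) {
    stopifnot(connected >= 0, connected <= 1)
    connected <- with_seed(derive_seed(seed, "connected"),
                           runif(n_targets) < connected)
  }
  if (!length(connected) %in% c(1L, n_targets)) {
    abort("`connected` must be a scalar or one flag per target")
  }
  connected <- rep_len(connected, n_targets)
  structure(list(
    connected = as.logical(connected),
    e_p = rep_len(e_p, n_targets) * as.numeric(connected),
    bump_center_ms = bump_center_ms,
    bump_width_ms = bump_width_ms,
    bump_family = bump_family,
    spont_rate_hz = spont_rate_hz,
    amp_meanlog = amp_meanlog,
    amp_sdlog = amp_sdlog,
    noise_sd_pa = noise_sd_pa,
    drift_amp_pa = drift_amp_pa,
    drift_freq_hz = drift_freq_hz,
    photocurrent_pa = photocurrent_pa
  ), class = "ground_truth")
}

draw_bump_latency <- function(n, truth) {
  if (truth$bump_family == "gamma") {
    rgamma_mean_sd(n, truth$bump_center_ms, truth$bump_width_ms)
  } else {
    rnorm(n, truth$bump_center_ms, truth$bump_width_ms)
  }
}

#' Simulate the ground-truth event stream of a recording
#'
#' Draws every synaptic event of a simulated experiment without rendering a
#' current trace: spontaneous events as a homogeneous Poisson process over
#' the recording, and evoked events per stimulation as Poisson(`e_p`)
#' counts with latencies from the ground-truth bump distribution.
#'
#' @inheritParams make_ground_truth
#' @param truth a [make_ground_truth()] specification.
#' @param duration_ms total recording duration (defaults to the schedule's).
#' @param seed master seed.
#' @return Tibble with columns `onset_ms`, `height_pa`, `provenance`
#'   (`"spontaneous"`/`"evoked"`), `target_id` (NA for spontaneous) and
#'   `latency_ms` (evoked only), sorted by onset.
#' @export
simulate_event_stream <- function(schedule, truth, duration_ms = NULL,
                                  seed = 1) {
  duration_ms <- duration_ms %||% attr(schedule, "duration_ms")
  if (max(schedule$time_ms) >= duration_ms) {
    abort("schedule extends beyond the requested trace duration")
  }
  spont <- with_seed(derive_seed(seed, "spont"), {
    n_sp <- rpois(1, truth$spont_rate_hz * duration_ms / 1000)
    tibble::tibble(
      onset_ms = sort(runif(n_sp, 0, duration_ms)),
      height_pa = stats::rlnorm(n_sp, truth$amp_meanlog, truth$amp_sdlog),
      provenance = "spontaneous",
      target_id = NA_integer_,
      latency_ms = NA_real_
    )
  })
  evoked <- with_seed(derive_seed(seed, "evoked"), {
    ep <- truth$e_p[schedule$target_id]
    n_ev <- rpois(nrow(schedule), ep)
    idx <- rep(seq_len(nrow(schedule)), n_ev)
    lat <- draw_bump_latency(sum(n_ev), truth)
    tibble::tibble(
      onset_ms = schedule$time_ms[idx] + lat,
      height_pa = stats::rlnorm(sum(n_ev), truth$amp_meanlog, truth$amp_sdlog),
      provenance = "evoked",
      target_id = schedule$target_id[idx],
      latency_ms = lat
    )
  })
  out <- dplyr::bind_rows(spont, evoked)
  out <- out[out$onset_ms >= 0 & out$onset_ms < duration_ms, ]
  dplyr::arrange(out, .data$onset_ms)
}

#' Render a current trace from an event table
#'
#' Deterministic, noiseless rendering: each event contributes a unit-peak
#' two-exponential kernel scaled by its height; inward currents are
#' negative, so the rendered trace is the negated sum of kernels. Linear
#' summation of overlapping events is assumed.
#'
#' @param events tibble with `onset_ms` and `height_pa`.
#' @param duration_ms trace duration (ms).
#' @param rate_hz sampling rate (default 5000).
#' @param tau_rise,tau_decay kernel time constants (ms).
#' @return Numeric vector of length `duration_ms/1000 * rate_hz` (pA).
#' @export
render_events <- function(events, duration_ms, rate_hz = 5000,
                          tau_rise = 0.7, tau_decay = 3.5) {
  n <- round(duration_ms / 1000 * rate_hz)
  trace <- numeric(n)
  if (!nrow(events)) return(trace)
  kern <- discretize_kernel(rate_hz, tau_rise, tau_decay)
  lk <- length(kern)
  dt_ms <- 1000 / rate_hz
  for (i in seq_len(nrow(events))) {
    # sub-sample onset handled by evaluating the kernel on the shifted grid
    o <- events$onset_ms[i]
    i0 <- floor(o / dt_ms) + 1
    if (i0 > n) next
    tt <- (seq(i0, min(n, i0 + lk)) - 1) * dt_ms - o
    trace[seq(i0, min(n, i0 + lk))] <-
      trace[seq(i0, min(n, i0 + lk))] +
      events$height_pa[i] *
        synaptic_kernel(tt, tau_rise, tau_decay, normalize = TRUE)
  }
  -trace
}

#' Simulate a full voltage-clamp recording
#'
#' Renders the event stream into a continuous current trace and adds
#' Gaussian noise, optional slow baseline drift, and optional per-target
#' direct photocurrent artifacts time-locked to the stimulus pulses.
#'
#' @inheritParams simulate_event_stream
#' @param rate_hz sampling rate (samples/s, >= 5000).
#' @return A list of class `sweep_trace`: `current_pa` (numeric vector),
#'   `rate_hz`, `schedule`, and `events` (the ground-truth event table).
#' @examples
#' sched <- make_stim_schedule(2, seed = 1)
#' truth <- make_ground_truth(sched, connected = c(TRUE, FALSE), seed = 1)
#' rec <- simulate_trace(sched, truth, seed = 1)
#' range(rec$current_pa)
#' @export
simulate_trace <- function(schedule, truth, rate_hz = 5000,
                           duration_ms = NULL, seed = 1) {
  if (rate_hz < 5000) abort("`rate_hz` must be at least 5000 samples/s")
  duration_ms <- duration_ms %||% attr(schedule, "duration_ms")
  events <- simulate_event_stream(schedule, truth, duration_ms, seed)
  trace <- render_events(events, duration_ms, rate_hz)
  n <- length(trace)
  tt_s <- (seq_len(n) - 1) / rate_hz

  if (!is.null(truth$photocurrent_pa)) {
    ids <- as.integer(names(truth$photocurrent_pa))
    for (j in seq_along(ids)) {
      amp <- truth$photocurrent_pa[j]
      stim <- schedule[schedule$target_id == ids[j], ]
      if (!nrow(stim) || amp == 0) next
      pc_events <- tibble::tibble(onset_ms = stim$time_ms + 0.5,
                                  height_pa = amp)
      trace <- trace + render_events(pc_events, duration_ms, rate_hz,
                                     tau_rise = 1.0, tau_decay = 8.0)
    }
  }
  trace <- trace + with_seed(derive_seed(seed, "noise"), {
    drift <- if (truth$drift_amp_pa > 0) {
      phase <- runif(1, 0, 2 * pi)
      truth$drift_amp_pa * sin(2 * pi * truth$drift_freq_hz * tt_s + phase)
    } else 0
    drift + rnorm(n, 0, truth$noise_sd_pa)
  })
  structure(list(current_pa = trace, rate_hz = rate_hz,
                 schedule = schedule, events = events,
                 duration_ms = duration_ms),
            class = "sweep_trace")
}

#' Simulate a cell-pair feature table with a known connectivity model
#'
#' Draws correlated Gaussian features, appends two binary connection-type
#' indicators, and labels each pair via a logistic model with known
#' coefficients -- the ground truth against which whitening and sparse
#' regression are validated.
#'
#' @param n_pairs number of candidate (presynaptic, postsynaptic) pairs.
#' @param coefficients numeric vector: intercept followed by one weight per
#'   feature (default 20 features).
#' @param correlation optional feature correlation matrix (default: AR(1)
#'   with `rho`); must be positive definite.
#' @param rho AR(1) correlation decay used when `correlation` is NULL.
#' @param n_binary how many trailing features are 0/1 connection-type
#'   indicators (default 2, prevalence 0.2 each).
#' @param prevalence optional target marginal prevalence; when given, the
#'   intercept is re-calibrated so that the population mean of
#'   `plogis(X beta + b0)` equals it (the supplied intercept is ignored).
#' @param seed master seed.
#' @return Tibble with feature columns `f1..fK` and a 0/1 `connected`
#'   column; attribute `prevalence` records the realized positive rate.
#' @export
simulate_pair_features <- function(n_pairs, coefficients, correlation = NULL,
                                   rho = 0.3, n_binary = 2,
                                   prevalence = NULL, seed = 1) {
  n_pairs <- assert_count(n_pairs, "n_pairs")
  k <- length(coefficients) - 1
  if (k < 1) abort("`coefficients` must be intercept + feature weights")
  if (is.null(correlation)) {
    correlation <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) abort("requested correlation matrix is singular")
  with_seed(derive_seed(seed, "pairs"), {
    X <- MASS::mvrnorm(n_pairs, mu = rep(0, k), Sigma = correlation)
    if (n_binary > 0) {
      bin_cols <- seq(k - n_binary + 1, k)
      X[, bin_cols] <- (X[, bin_cols] > qnorm(0.8)) * 1
    }
    eta0 <- drop(X %*% coefficients[-1])
    b0 <- coefficients[1]
    if (!is.null(prevalence)) {
      stopifnot(prevalence > 0, prevalence < 1)
      b0 <- stats::uniroot(function(b) mean(plogis(eta0 + b)) - prevalence,
                           c(-30, 30))$root
    }
    eta <- eta0 + b0
    y <- rbinom(n_pairs, 1, plogis(eta))
    out <- tibble::as_tibble(as.data.frame(X),
                             .name_repair = ~ paste0("f", seq_len(k)))
    out$connected <- y
    attr(out, "prevalence") <- mean(y)
    out
  })
}

#' Simulate labeled cell positions in a tissue volume
#'
#' Homogeneous Poisson point process in a rectangular box, emulating the
#' registered positions of opsin-expressing cells in a scanned slice
#' volume.
#'
#' @param density cells per mm^3.
#' @param volume_um box extent (x, y, z) in um (default the typical
#'   420 x 420 x 300 um^3 scan volume).
#' @param seed master seed.
#' @return Tibble with `cell_id`, `x_um`, `y_um`, `z_um`.
#' @export
simulate_cell_volume <- function(density, volume_um = c(420, 420, 300),
                                 seed = 1) {
  assert_positive(density, "density")
  assert_positive(volume_um, "volume_um")
  vol_mm3 <- prod(volume_um) / 1e9
  with_seed(derive_seed(seed, "volume"), {
    n <- rpois(1, density * vol_mm3)
    tibble::tibble(
      cell_id = seq_len(n),
      x_um = runif(n, 0, volume_um[1]),
      y_um = runif(n, 0, volume_um[2]),
      z_um = runif(n, 0, volume_um[3])
    )
  })
}
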