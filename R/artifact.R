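#' Align a recording trace to the stimulations of one target
#'
#' Cuts stimulus-aligned snippets spanning `pre_ms` before to `post_ms`
#' after each stimulation of the target.
#'
#' @param trace numeric current trace (pA) or `sweep_trace`.
#' @param schedule stimulation schedule.
#' @param target_id target to align to.
#' @param rate_hz sampling rate of a bare numeric trace.
#' @param pre_ms,post_ms window around the pulse (defaults 20 / 90 ms).
#' @return A list of class `aligned_traces`: `snippets` (matrix, one row
#'   per stimulation), `t_ms` (common time axis, 0 = pulse onset),
#'   `target_id`, `rate_hz`.
#' @export
align_to_stimulation <- function(trace, schedule, target_id, rate_hz = 5000,
                                 pre_ms = 20, post_ms = 90) {
  if (inherits(trace, "sweep_trace")) {
    rate_hz <- trace$rate_hz
    trace <- trace$current_pa
  }
  stim <- schedule[schedule$target_id == target_id, ]
  if (!nrow(stim)) abort(sprintf("target %s not in schedule", target_id))
  dt_ms <- 1000 / rate_hz
  offs <- seq(-round(pre_ms / dt_ms), round(post_ms / dt_ms))
  rows <- purrr::map(stim$time_ms, function(s0) {
    idx <- round(s0 / dt_ms) + 1 + offs
    out <- rep(NA_real_, length(offs))
    ok <- idx >= 1 & idx <= length(trace)
    out[ok] <- trace[idx[ok]]
    out
  })
  structure(list(snippets = do.call(rbind, rows), t_ms = offs * dt_ms,
                 target_id = target_id, rate_hz = rate_hz),
            class = "aligned_traces")
}

#' Classify a direct photocurrent in stimulus-aligned traces
#'
#' Operationalizes the hallmarks of a direct photocurrent (as opposed to a
#' synaptic response): minimal onset latency and jitter, near-perfect
#' reliability, and a reproducible waveform. A deflection present in at
#' least `reliability` of trials, with onset latency below `max_latency_ms`,
#' onset jitter below `max_jitter_ms`, and mean trial-to-trial waveform
#' correlation of at least `min_waveform_cor`, is classified as a
#' photocurrent; its amplitude is the absolute extremum of the mean trace
#' in [0, 30] ms. Amplitudes above `exclude_above_pa` flag the target for
#' exclusion from connectivity analysis.
#'
#' @param a an [align_to_stimulation()] result.
#' @param onset_sd deflection threshold in units of the pre-stimulus
#'   noise SD (default 4).
#' @param max_latency_ms,max_jitter_ms,reliability,min_waveform_cor
#'   classification thresholds (defaults 2 ms, 0.5 ms, 0.9, 0.9).
#' @param exclude_above_pa exclusion threshold (default 20 pA).
#' @return A list of class `photocurrent_call`: `status` (`"none"`,
#'   `"photocurrent"`, or `"indeterminate"`), `amplitude_pa`, `excluded`,
#'   and the per-trial `latency_ms`.
#' @export
classify_direct_photocurrent <- function(a, onset_sd = 4,
                                         max_latency_ms = 2,
                                         max_jitter_ms = 0.5,
                                         reliability = 0.9,
                                         min_waveform_cor = 0.9,
                                         exclude_above_pa = 20) {
  stopifnot(inherits(a, "aligned_traces"))
  x <- a$snippets
  if (nrow(x) < 5) {
    return(structure(list(status = "indeterminate", amplitude_pa = NA_real_,
                          excluded = FALSE, latency_ms = rep(NA_real_, nrow(x))),
                     class = "photocurrent_call"))
  }
  pre <- a$t_ms < 0
  win <- a$t_ms >= 0 & a$t_ms <= 30
  noise <- apply(x[, pre, drop = FALSE], 1, stats::sd)
  base <- rowMeans(x[, pre, drop = FALSE])
  thr <- pmax(onset_sd * noise, 1e-9)

  latency <- vapply(seq_len(nrow(x)), function(i) {
    dev <- abs(x[i, win] - base[i])
    j <- which(dev > thr[i])
    if (!length(j)) NA_real_ else a$t_ms[win][j[1]]
  }, numeric(1))

  responding <- !is.na(latency)
  frac <- mean(responding)
  early <- responding & latency < max_latency_ms
  jitter <- if (sum(early) >= 2) stats::sd(latency[early]) else Inf

  wf_cor <- if (sum(responding) >= 2) {
    cm <- stats::cor(t(x[responding, win, drop = FALSE]))
    mean(cm[upper.tri(cm)])
  } else 0

  is_pc <- frac >= reliability && mean(early) >= reliability &&
    jitter < max_jitter_ms && wf_cor >= min_waveform_cor
  if (!is_pc) {
    return(structure(list(status = "none", amplitude_pa = NA_real_,
                          excluded = FALSE, latency_ms = latency),
                     class = "photocurrent_call"))
  }
  m <- colMeans(x) - mean(base)
  amp <- max(abs(m[win]))
  structure(list(status = "photocurrent", amplitude_pa = amp,
                 excluded = amp > exclude_above_pa, latency_ms = latency),
            class = "photocurrent_call")
}

#' Subtract a photocurrent template from stimulus-aligned traces
#'
#' Rows with no detected EPSC in the 30 ms after stimulation define the
#' photocurrent template (their mean); the template is subtracted from all
#' rows, isolating the EPSCs of compound photocurrent + EPSC responses.
#' If a blocker-condition trace set is supplied (recordings repeated under
#' glutamate-receptor blockade), its mean is used as the template instead.
#'
#' @param a an [align_to_stimulation()] result.
#' @param epsc_rows logical vector: which rows contain an EPSC within
#'   `epsc_window_ms` after stimulation (from the event table; not
#'   re-detected here).
#' @param epsc_window_ms window defining "no-EPSC" rows (default 30 ms).
#' @param blocker an optional `aligned_traces` recorded under blockers.
#' @return The input with `snippets` template-subtracted and a `template`
#'   element added.
#' @export
subtract_photocurrent <- function(a, epsc_rows, epsc_window_ms = 30,
                                  blocker = NULL) {
  stopifnot(inherits(a, "aligned_traces"))
  if (!is.null(blocker)) {
    template <- colMeans(blocker$snippets)
  } else {
    stopifnot(length(epsc_rows) == nrow(a$snippets))
    clean <- !epsc_rows
    if (!any(clean)) abort("no EPSC-free rows to define the template")
    template <- colMeans(a$snippets[clean, , drop = FALSE])
  }
  a$snippets <- sweep(a$snippets, 2, template)
  a$template <- template
  a
}

#' Window-based response amplitude of one aligned snippet
#'
#' Baseline mean over [-20, +2] ms minus the minimum over [+2, +25] ms:
#' positive for inward (downward) responses, and invariant to constant
#' offsets.
#'
#' @param row one aligned snippet (numeric vector).
#' @param t_ms matching time axis (0 = pulse onset).
#' @param baseline_ms,response_ms the two windows.
#' @return Amplitude in pA.
#' @export
window_amplitude <- function(row, t_ms, baseline_ms = c(-20, 2),
                             response_ms = c(2, 25)) {
  bl <- t_ms >= baseline_ms[1] & t_ms <= baseline_ms[2]
  rs <- t_ms >= response_ms[1] & t_ms <= response_ms[2]
  if (!any(bl) || !any(rs)) abort("snippet does not span both windows")
  mean(row[bl]) - min(row[rs])
}
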