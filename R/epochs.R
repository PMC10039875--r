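#' Segment detected events into evoked and spontaneous epochs for a target
#'
#' For one stimulated target, builds the data the connectivity models fit:
#' evoked segments are the 90 ms following each stimulus of the target
#' (disregarding the last 10 ms before the next pulse of a 10 Hz train);
#' spontaneous segments are stretches within +-5 s of the target's trains
#' during which no cell was being stimulated, chopped into pieces of at
#' most 90 ms. Every event is assigned to at most one segment.
#'
#' @param events an EPSC event table with `onset_ms` (trace time).
#' @param schedule the [make_stim_schedule()] used for the recording.
#' @param target_id the stimulated cell to segment for.
#' @param evoked_ms evoked-segment duration (default 90).
#' @param context_ms how far around the target's trains spontaneous
#'   segments may be taken (default 5000).
#' @return A list of class `stim_epoch_data`: `spont` (tibble `rep`,
#'   `duration_ms`, `n_events`), `evoked` (tibble `rep`, `pulse`,
#'   `duration_ms`, `n_events`), `event_times` (tibble `rep`,
#'   `latency_ms`), and `target_id`.
#' @export
segment_epochs <- function(events, schedule, target_id, evoked_ms = 90,
                           context_ms = 5000) {
  stim <- schedule[schedule$target_id == target_id, ]
  if (!nrow(stim)) abort(sprintf("target %s not in schedule", target_id))
  onsets <- sort(events$onset_ms)

  evoked <- dplyr::mutate(
    tibble::tibble(rep = stim$rep, pulse = stim$pulse, start = stim$time_ms),
    duration_ms = evoked_ms,
    n_events = vapply(.data$start, function(s) {
      sum(onsets >= s & onsets < s + evoked_ms)
    }, numeric(1))
  )
  event_times <- purrr::pmap_dfr(
    list(stim$rep, stim$time_ms), function(rp, s) {
      lat <- onsets[onsets >= s & onsets < s + evoked_ms] - s
      tibble::tibble(rep = rep(rp, length(lat)), latency_ms = lat)
    })

  # complement of all evoked windows (any target), near this target's trains
  all_busy <- cbind(schedule$time_ms, schedule$time_ms + evoked_ms)
  all_busy <- all_busy[order(all_busy[, 1]), , drop = FALSE]
  merged <- all_busy[1, , drop = FALSE]
  for (i in seq_len(nrow(all_busy))[-1]) {
    if (all_busy[i, 1] <= merged[nrow(merged), 2]) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], all_busy[i, 2])
    } else merged <- rbind(merged, all_busy[i, ])
  }

  spont <- purrr::map_dfr(unique(stim$rep), function(rp) {
    tr <- stim[stim$rep == rp, ]
    lo <- min(tr$time_ms) - context_ms
    hi <- max(tr$time_ms) + evoked_ms + context_ms
    # gaps between merged busy windows, clipped to [lo, hi]
    bounds <- rbind(c(-Inf, lo), merged, c(hi, Inf))
    gaps <- cbind(bounds[-nrow(bounds), 2], bounds[-1, 1])
    gaps[, 1] <- pmax(gaps[, 1], lo)
    gaps[, 2] <- pmin(gaps[, 2], hi)
    gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
    if (!nrow(gaps)) return(tibble::tibble())
    purrr::map_dfr(seq_len(nrow(gaps)), function(g) {
      cuts <- seq(gaps[g, 1], gaps[g, 2], by = evoked_ms)
      if (cuts[length(cuts)] < gaps[g, 2]) cuts <- c(cuts, gaps[g, 2])
      tibble::tibble(
        rep = rp,
        duration_ms = diff(cuts),
        n_events = vapply(seq_len(length(cuts) - 1), function(j) {
          sum(onsets >= cuts[j] & onsets < cuts[j + 1])
        }, numeric(1))
      )
    })
  })
  structure(list(spont = spont, evoked = evoked, event_times = event_times,
                 target_id = target_id, evoked_ms = evoked_ms),
            class = "stim_epoch_data")
}

#' Pooled spontaneous EPSC rate of a recording
#'
#' The empirical spontaneous rate used to center the rate priors of the
#' connectivity models: events falling outside every evoked window of the
#' schedule, divided by the total unstimulated time.
#'
#' @inheritParams segment_epochs
#' @param duration_ms recording duration (defaults to the schedule's).
#' @return Rate in events/ms.
#' @export
empirical_spont_rate <- function(events, schedule, evoked_ms = 90,
                                 duration_ms = NULL) {
  duration_ms <- duration_ms %||% attr(schedule, "duration_ms")
  onsets <- events$onset_ms
  in_evoked <- vapply(onsets, function(t) {
    any(t >= schedule$time_ms & t < schedule$time_ms + evoked_ms)
  }, logical(1))
  # busy time from merged evoked windows
  w <- cbind(schedule$time_ms, pmin(schedule$time_ms + evoked_ms,
                                    duration_ms))
  w <- w[order(w[, 1]), , drop = FALSE]
  busy <- 0; cur <- w[1, ]
  for (i in seq_len(nrow(w))[-1]) {
    if (w[i, 1] <= cur[2]) cur[2] <- max(cur[2], w[i, 2]) else {
      busy <- busy + cur[2] - cur[1]; cur <- w[i, ]
    }
  }
  busy <- busy + cur[2] - cur[1]
  free <- duration_ms - busy
  if (free <= 0) abort("no unstimulated time in the recording")
  (sum(!in_evoked) + 1e-3) / free
}
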