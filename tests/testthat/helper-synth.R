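# shared fixtures built in code

# greedy 1-1 matching of detected to true events within a tolerance (ms)
match_events <- function(detected_ms, truth_ms, tol_ms = 1) {
  used <- rep(FALSE, length(detected_ms))
  pairs <- integer(0)
  for (i in seq_along(truth_ms)) {
    d <- abs(detected_ms - truth_ms[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_ms) {
      used[j] <- TRUE
      pairs <- c(pairs, j)
    } else {
      pairs <- c(pairs, NA_integer_)
    }
  }
  list(match = pairs,
       recall = mean(!is.na(pairs)),
       precision = sum(!is.na(pairs)) / max(length(detected_ms), 1))
}

# ideal RC + integrate-and-fire current-step sweeps with known parameters
make_step_sweeps <- function(r_mohm = 100, tau_ms = 20, v_rest = -70,
                             currents_pa = c(-100, -50, 50, 100, 150, 200),
                             rheobase_pa = 40, gain_hz_pa = 0.2,
                             rate_hz = 5000, step_start_ms = 100,
                             step_end_ms = 600, total_ms = 700,
                             sag_frac = 0) {
  dt <- 1000 / rate_hz
  tt <- seq(0, total_ms - dt, by = dt)
  during <- tt >= step_start_ms & tt < step_end_ms
  tibble::tibble(
    current_pa = currents_pa,
    voltage_mv = lapply(currents_pa, function(ii) {
      v <- rep(v_rest, length(tt))
      if (ii < 0) {
        dv <- r_mohm * ii / 1000   # mV
        td <- tt[during] - step_start_ms
        resp <- dv * (1 - exp(-td / tau_ms))
        if (sag_frac > 0) {   # partial recovery toward steady state
          resp <- resp * (1 - sag_frac * pmax(0, 1 - exp(-(td - 100) / 80)) *
                            (td > 100))
        }
        v[during] <- v_rest + resp
        after <- tt >= step_end_ms
        v[after] <- v_rest + resp[length(resp)] *
          exp(-(tt[after] - step_end_ms) / tau_ms)
      } else if (ii > rheobase_pa) {
        rate <- gain_hz_pa * (ii - rheobase_pa)
        if (rate > 0) {
          isi_ms <- 1000 / rate
          spike_times <- seq(step_start_ms + 2, step_end_ms - 2, by = isi_ms)
          v[during] <- v_rest + 10
          for (st in spike_times) {
            sel <- tt >= st & tt < st + 2
            prof <- 80 * exp(-((tt[sel] - st - 0.5) / 0.4)^2)
            v[sel] <- v_rest + 10 + prof
          }
        } else v[during] <- v_rest + 5
      } else {
        v[during] <- v_rest + r_mohm * ii / 1000
      }
      v
    })
  )
}
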