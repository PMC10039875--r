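#' Detrend a recording trace and estimate its noise level
#'
#' Standardizes a voltage-clamp trace for event detection: the trace is
#' inverted (inward currents become positive deflections), resampled to
#' 5000 Hz if needed, and a slow baseline is removed. The baseline is a
#' 10th-percentile filter of 50 ms width evaluated on a 200 Hz grid,
#' median-filtered with a 15 ms window, and interpolated back to the full
#' rate. The result is shifted to zero median, and the noise is
#' characterized by the robust standard deviation
#' \eqn{\widehat{SD} = 1.4826 \times MAD}.
#'
#' @param trace numeric current trace (pA) or a `sweep_trace`.
#' @param rate_hz sampling rate of `trace` (ignored for `sweep_trace`).
#' @param percentile baseline percentile (default 0.10).
#' @param window_ms percentile-filter width (default 50 ms).
#' @param smooth_ms median-filter width on the 200 Hz baseline grid
#'   (default 15 ms).
#' @return A list of class `zero_baseline_trace`: `samples` (inverted,
#'   baseline-subtracted, zero-median trace at 5000 Hz), `noise_sd`
#'   (\eqn{\widehat{SD}} in pA), `rate_hz`, and `baseline` (the subtracted
#'   baseline on the inverted trace).
#' @export
detrend_and_noise <- function(trace, rate_hz = 5000, percentile = 0.10,
                              window_ms = 50, smooth_ms = 15) {
  if (inherits(trace, "sweep_trace")) {
    rate_hz <- trace$rate_hz
    trace <- trace$current_pa
  }
  if (!all(is.finite(trace))) abort("trace contains non-finite samples")
  if (rate_hz < 5000) abort("sampling rate must be >= 5000 samples/s")
  if (rate_hz != 5000) {
    trace <- resample_polyphase(trace, rate_hz, 5000)
    rate_hz <- 5000
  }
  n <- length(trace)
  win <- round(window_ms / 1000 * rate_hz)
  if (n <= win) abort("trace shorter than the baseline filter width")

  inv <- -trace
  # percentile filter evaluated on a 200 Hz grid (filter-then-decimate)
  stride <- rate_hz / 200
  centers <- seq(1, n, by = stride)
  half <- win %/% 2
  base_coarse <- vapply(centers, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    quantile(inv[lo:hi], percentile, names = FALSE, type = 7)
  }, numeric(1))
  k_med <- max(1, round(smooth_ms / 1000 * 200))
  if (k_med %% 2 == 0) k_med <- k_med + 1
  if (length(base_coarse) > k_med) {
    base_coarse <- stats::runmed(base_coarse, k_med, endrule = "median")
  }
  baseline <- approx(centers, base_coarse, xout = seq_len(n),
                     rule = 2)$y
  s <- inv - baseline
  s <- s - median(s)
  structure(list(samples = s,
                 noise_sd = mad(s, constant = 1.4826),
                 rate_hz = rate_hz,
                 baseline = baseline),
            class = "zero_baseline_trace")
}

# Polyphase-style resampling via FFT (rational rate change); adequate for
# the integer downsampling factors used here.
resample_polyphase <- function(x, from_hz, to_hz) {
  if (from_hz == to_hz) return(x)
  n_out <- round(length(x) * to_hz / from_hz)
  # use stats::spline-free FFT resampling through signal-style decimation:
  # lowpass by truncating the spectrum, then inverse transform on the new grid
  X <- fft(x)
  n <- length(x)
  keep <- min(n, n_out)
  half <- keep %/% 2
  Y <- complex(n_out)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 0) Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  Re(fft(Y, inverse = TRUE)) / n
}
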