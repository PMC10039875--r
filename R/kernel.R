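#' Synaptic event waveform kernel
#'
#' The canonical EPSC template: a product of an exponential decay and an
#' exponential rise,
#' \deqn{k(t) = \exp(-t/\tau_{decay}) (1 - \exp(-t/\tau_{rise}))}
#' for \eqn{t \ge 0} and 0 before the onset. With `normalize = TRUE` the
#' kernel is scaled to unit peak so that an event's height equals its
#' amplitude in pA.
#'
#' @param t time from event onset (ms); may be a vector.
#' @param tau_rise rise time constant (ms).
#' @param tau_decay decay time constant (ms); must exceed `tau_rise`.
#' @param normalize scale the waveform to unit peak (default `FALSE`).
#' @return Numeric vector of kernel values (unitless).
#' @examples
#' synaptic_kernel(0:10, tau_rise = 0.7, tau_decay = 3.5)
#' @export
synaptic_kernel <- function(t, tau_rise = 0.7, tau_decay = 3.5,
                            normalize = FALSE) {
  check_kernel_taus(tau_rise, tau_decay)
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) * (1 - exp(-t / tau_rise)))
  if (normalize) k <- k / kernel_peak_value(tau_rise, tau_decay)
  k
}

check_kernel_taus <- function(tau_rise, tau_decay) {
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise) {
    abort("kernel time constants must satisfy tau_decay > tau_rise > 0")
  }
  invisible(TRUE)
}

#' Peak time of the synaptic kernel
#'
#' Closed form from the stationarity condition of the two-exponential
#' waveform: \eqn{t^* = \tau_{rise} \log(1 + \tau_{decay}/\tau_{rise})}.
#'
#' @inheritParams synaptic_kernel
#' @return Peak time in ms.
#' @export
kernel_peak_time <- function(tau_rise = 0.7, tau_decay = 3.5) {
  check_kernel_taus(tau_rise, tau_decay)
  tau_rise * log(1 + tau_decay / tau_rise)
}

kernel_peak_value <- function(tau_rise, tau_decay) {
  tp <- kernel_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) * (1 - exp(-tp / tau_rise))
}

# Discretized unit-peak kernel at a given sampling rate, truncated where the
# tail falls below `tol` of the peak (bounded support keeps convolutions fast).
discretize_kernel <- function(rate_hz = 5000, tau_rise = 0.7, tau_decay = 3.5,
                              tol = 1e-4) {
  dt_ms <- 1000 / rate_hz
  t_max <- -tau_decay * log(tol)  # decay envelope bound
  tt <- seq(0, t_max, by = dt_ms)
  k <- synaptic_kernel(tt, tau_rise, tau_decay, normalize = TRUE)
  keep <- seq_len(max(which(k >= tol)))
  k[keep]
}
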