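#' Plot a recording trace with detected events
#'
#' @param rec a `sweep_trace` (or numeric trace with `rate_hz`).
#' @param events optional EPSC event table to mark.
#' @param window_ms optional c(from, to) window to display.
#' @param rate_hz sampling rate for a bare numeric trace.
#' @return A ggplot object.
#' @export
plot_trace <- function(rec, events = NULL, window_ms = NULL, rate_hz = 5000) {
  if (inherits(rec, "sweep_trace")) {
    tr <- rec$current_pa
    rate_hz <- rec$rate_hz
  } else {
    tr <- as.numeric(rec)
  }
  df <- tibble::tibble(t_ms = (seq_along(tr) - 1) * 1000 / rate_hz,
                       current_pa = tr)
  if (!is.null(window_ms)) {
    df <- df[df$t_ms >= window_ms[1] & df$t_ms <= window_ms[2], ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$current_pa)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- events
    if (!is.null(window_ms)) {
      ev <- ev[ev$onset_ms >= window_ms[1] & ev$onset_ms <= window_ms[2], ]
    }
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$onset_ms),
                                 colour = "firebrick", alpha = 0.5,
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Peristimulus latency histogram with the fitted mixture density
#'
#' @param object a [fit_psth_mixture()] result.
#' @param latencies_ms the latencies that were fitted (for the histogram).
#' @param binwidth_ms histogram bin width (default 1 ms).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psth_mixture_fit <- function(object, latencies_ms = NULL,
                                      binwidth_ms = 1, ...) {
  xx <- seq(0.01, object$window_ms - 0.01, length.out = 400)
  dens <- tibble::tibble(t_ms = xx, density = dpsth_mixture(xx, object))
  p <- ggplot2::ggplot()
  if (!is.null(latencies_ms)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(t_ms = latencies_ms),
      ggplot2::aes(.data$t_ms, ggplot2::after_stat(.data$density)),
      binwidth = binwidth_ms, fill = "grey80", colour = "grey60")
  }
  p + ggplot2::geom_line(data = dens,
                         ggplot2::aes(.data$t_ms, .data$density),
                         colour = "firebrick") +
    ggplot2::labs(x = "latency after stimulation (ms)", y = "density") +
    ggplot2::theme_minimal()
}

#' Posterior coefficient intervals of a Horseshoe regression
#'
#' @param object a [fit_horseshoe_logistic()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.horseshoe_fit <- function(object, ...) {
  s <- dplyr::arrange(object$summary, .data$median)
  s$feature <- factor(s$feature, levels = s$feature)
  ggplot2::ggplot(s, ggplot2::aes(.data$median, .data$feature,
                                  colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q05,
                                         xmax = .data$q95), height = 0.2) +
    ggplot2::geom_vline(xintercept = c(-0.05, 0.05), linetype = "dotted") +
    ggplot2::labs(x = "posterior coefficient (log-odds per SD)",
                  y = NULL, colour = "selected") +
    ggplot2::theme_minimal()
}

#' Spatial connectivity map around the recorded cell
#'
#' @param map tibble with `ml_um`, `dv_um`, `responsive`, `connected`,
#'   `strength_pa`.
#' @param recorded the recorded cell's `ml_um`, `dv_um`.
#' @return A ggplot object.
#' @export
plot_connectivity_map <- function(map, recorded) {
  ggplot2::ggplot(map, ggplot2::aes(.data$ml_um, .data$dv_um)) +
    ggplot2::geom_point(data = map[!map$connected, ],
                        colour = "grey70", size = 1.5) +
    ggplot2::geom_point(data = map[map$connected, ],
                        ggplot2::aes(size = .data$strength_pa),
                        colour = "firebrick", alpha = 0.8) +
    ggplot2::annotate("point", x = recorded$ml_um, y = recorded$dv_um,
                      shape = 4, size = 4, stroke = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (um)", y = "DV (um)", size = "strength (pA)") +
    ggplot2::theme_minimal()
}
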