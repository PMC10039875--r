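#' Detect putative EPSCs in a deconvolved trace
#'
#' Smooths the deconvolved trace with a triangular kernel of 2.5 ms width
#' and takes local maxima with height and prominence of at least
#' `threshold_sd` times \eqn{\widehat{SD}} and a pairwise spacing of at
#' least 2.0 ms. Each peak location is the provisional onset estimate
#' \eqn{\hat o}; the provisional height \eqn{\hat h} is the deconvolved
#' mass in the window \eqn{[\hat o - 0.4, \hat o + 0.8]} ms, which for the
#' unit-peak kernel is on the pA scale of event amplitudes.
#'
#' @param d a [deconvolve()] result.
#' @param threshold_sd height/prominence threshold in \eqn{\widehat{SD}}
#'   units (default 0.5).
#' @param min_distance_ms minimum peak spacing (default 2.0 ms).
#' @param triangle_ms triangular smoothing width (default 2.5 ms).
#' @return Tibble with `onset_hat_ms` and `height_hat_pa`, sorted by onset.
#' @export
detect_putative_events <- function(d, threshold_sd = 0.5,
                                   min_distance_ms = 2.0,
                                   triangle_ms = 2.5) {
  stopifnot(inherits(d, "deconv_result"))
  x <- d$deconvolved
  rate <- d$rate_hz
  dt_ms <- 1000 / rate

  half <- max(1, round(triangle_ms / 2 / dt_ms))
  w <- 1 - abs(seq(-half, half)) / (half + 1)   # unit-peak triangle
  sm <- stats::filter(x, w, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)

  # floor keeps numerically silent (noise-free) traces from yielding
  # ripple-level detections; 1e-3 pA is far below any physiological event
  thr <- max(threshold_sd * d$noise_sd, 1e-3)
  peaks <- find_peaks(sm, min_height = thr, min_prominence = thr,
                      min_distance = round(min_distance_ms / dt_ms))
  if (!length(peaks)) {
    return(tibble::tibble(onset_hat_ms = numeric(), height_hat_pa = numeric()))
  }
  onset <- (peaks - 1) * dt_ms
  h <- vapply(seq_along(peaks), function(i) {
    lo <- max(1, peaks[i] - round(0.4 / dt_ms))
    hi <- min(length(x), peaks[i] + round(0.8 / dt_ms))
    sum(x[lo:hi])
  }, numeric(1))
  tibble::tibble(onset_hat_ms = onset, height_hat_pa = h)
}

# Local-maximum finder with height, prominence and minimum-distance rules
# (higher peaks keep priority when enforcing the distance).
find_peaks <- function(x, min_height = -Inf, min_prominence = 0,
                       min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer())
  dx <- diff(x)
  # rising-then-falling, with plateaus resolved to their first sample
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer())

  prom <- vapply(cand, function(p) {
    # walk left until a sample higher than the peak (or the edge)
    i <- p; left_min <- x[p]
    while (i > 1 && x[i - 1] <= x[p]) {
      i <- i - 1
      if (x[i] < left_min) left_min <- x[i]
    }
    if (i == 1) left_min <- min(x[1:p])
    i <- p; right_min <- x[p]
    while (i < n && x[i + 1] <= x[p]) {
      i <- i + 1
      if (x[i] < right_min) right_min <- x[i]
    }
    if (i == n) right_min <- min(x[p:n])
    x[p] - max(left_min, right_min)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer())

  ord <- cand[order(-x[cand])]
  keep <- logical(n + 1)
  sel <- integer()
  for (p in ord) {
    lo <- max(1, p - min_distance + 1); hi <- min(n, p + min_distance - 1)
    if (!any(keep[lo:hi])) {
      keep[p] <- TRUE
      sel <- c(sel, p)
    }
  }
  sort(sel)
}

#' Cluster detected events by temporal proximity
#'
#' Two consecutive events belong to the same cluster when the second starts
#' before the first has decayed back to baseline. Segments are taken where
#' the denoised trace exceeds `segment_sd` times \eqn{\widehat{SD}},
#' extended by 10 ms before their start and 20 ms after their end, extended
#' further by +-10 ms around member events, and merged where they overlap.
#' An event outside every supra-threshold segment gets a singleton segment
#' spanning \eqn{[\hat o - 10, \hat o + 30]} ms.
#'
#' @param d a [deconvolve()] result.
#' @param events a [detect_putative_events()] table.
#' @param segment_sd denoised-trace threshold in \eqn{\widehat{SD}} units
#'   (default 1.8).
#' @return Tibble with one row per cluster: `cluster_id`, `start_ms`,
#'   `end_ms`, and a list-column `event_idx` of member-row indices into
#'   `events`.
#' @export
cluster_events <- function(d, events, segment_sd = 1.8) {
  stopifnot(inherits(d, "deconv_result"))
  if (!nrow(events)) {
    return(tibble::tibble(cluster_id = integer(), start_ms = numeric(),
                          end_ms = numeric(), event_idx = list()))
  }
  stopifnot(!is.unsorted(events$onset_hat_ms))
  dt_ms <- 1000 / d$rate_hz
  # same absolute floor as detection, so noise-free traces segment sanely
  thr <- max(segment_sd * d$noise_sd, 1e-3)
  above <- d$denoised > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  seg <- cbind((starts[r$values] - 1) * dt_ms - 10,
               (ends[r$values] - 1) * dt_ms + 20)

  # extend around events that fall inside a segment; singleton otherwise
  if (nrow(seg)) {
    for (i in seq_len(nrow(events))) {
      o <- events$onset_hat_ms[i]
      j <- which(seg[, 1] <= o & o <= seg[, 2])
      if (length(j)) {
        j <- j[1]
        seg[j, 1] <- min(seg[j, 1], o - 10)
        seg[j, 2] <- max(seg[j, 2], o + 10)
      } else {
        seg <- rbind(seg, c(o - 10, o + 30))
      }
    }
  } else {
    seg <- cbind(events$onset_hat_ms - 10, events$onset_hat_ms + 30)
  }
  seg <- seg[order(seg[, 1]), , drop = FALSE]

  # merge overlapping segments
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg[i, 1] <= merged[last, 2]) {
        merged[last, 2] <- max(merged[last, 2], seg[i, 2])
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }

  idx <- purrr::map(seq_len(nrow(merged)), function(i) {
    which(events$onset_hat_ms >= merged[i, 1] &
          events$onset_hat_ms <= merged[i, 2])
  })
  out <- tibble::tibble(cluster_id = seq_len(nrow(merged)),
                        start_ms = merged[, 1], end_ms = merged[, 2],
                        event_idx = idx)
  out[lengths(out$event_idx) > 0, ]
}
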