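#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per parameter or
#' feature, `glance()` a one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.psth_mixture_fit <- function(x, ...) {
  x$ci
}

#' @rdname tidiers
#' @export
glance.psth_mixture_fit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, window_ms = x$window_ms,
                 identified = x$identified)
}

#' @rdname tidiers
#' @export
tidy.bump_fit <- function(x, ...) {
  x$summary
}

#' @rdname tidiers
#' @export
glance.bump_fit <- function(x, ...) {
  tibble::tibble(target_id = x$target_id, max_rhat = x$max_rhat,
                 divergences = x$divergences)
}

#' @rdname tidiers
#' @export
tidy.horseshoe_fit <- function(x, ...) {
  x$summary
}

#' @rdname tidiers
#' @export
glance.horseshoe_fit <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 accept_rate = x$accept_rate,
                 divergences = x$divergences,
                 max_rhat = x$max_rhat, reliable = x$reliable)
}

#' @rdname tidiers
#' @export
tidy.cv_cross_entropy <- function(x, ...) {
  x$cv
}

#' @rdname tidiers
#' @export
glance.cv_cross_entropy <- function(x, ...) {
  tibble::tibble(h_cv = x$h_cv, h_full = x$h_full,
                 h_shuffle_mean = mean(x$h_shuffle),
                 h_constant = x$h_constant, skipped = x$skipped)
}
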