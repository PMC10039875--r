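# build an aligned-trace set by hand
make_aligned <- function(rows, t_ms) {
  structure(list(snippets = rows, t_ms = t_ms, target_id = 1,
                 rate_hz = 5000), class = "aligned_traces")
}
t_ms <- seq(-20, 90, by = 0.2)

pc_template <- function(amp) {
  ifelse(t_ms >= 1, -amp * synaptic_kernel(t_ms - 1, 1.0, 8.0,
                                           normalize = TRUE), 0)
}

test_that("a reliable zero-jitter deflection is classified as a
           photocurrent and excluded above 20 pA", {
  set.seed(1)
  rows <- t(replicate(10, pc_template(30) + rnorm(length(t_ms), 0, 0.5)))
  call <- classify_direct_photocurrent(make_aligned(rows, t_ms))
  expect_equal(call$status, "photocurrent")
  expect_equal(call$amplitude_pa, 30, tolerance = 0.15 * 30)
  expect_true(call$excluded)

  rows_small <- t(replicate(10, pc_template(10) +
                              rnorm(length(t_ms), 0, 0.3)))
  call2 <- classify_direct_photocurrent(make_aligned(rows_small, t_ms))
  expect_equal(call2$status, "photocurrent")
  expect_false(call2$excluded)
})

test_that("jittered, unreliable EPSC-like responses and flat noise are
           not photocurrents", {
  set.seed(2)
  rows <- t(sapply(1:10, function(i) {
    x <- rnorm(length(t_ms), 0, 1)
    if (i <= 4) {   # EPSC on 40% of rows at 8-20 ms latency
      lat <- runif(1, 8, 20)
      x <- x - 25 * synaptic_kernel(t_ms - lat, 0.7, 3.5, normalize = TRUE)
    }
    x
  }))
  expect_equal(classify_direct_photocurrent(make_aligned(rows, t_ms))$status,
               "none")
  noise <- t(replicate(8, rnorm(length(t_ms), 0, 1)))
  expect_equal(classify_direct_photocurrent(make_aligned(noise, t_ms))$status,
               "none")
  few <- make_aligned(noise[1:3, ], t_ms)
  expect_equal(classify_direct_photocurrent(few)$status, "indeterminate")
})

test_that("template subtraction removes the photocurrent and recovers
           additive EPSC amplitudes", {
  set.seed(3)
  temp <- pc_template(15)
  epsc <- -20 * synaptic_kernel(t_ms - 10, 0.7, 3.5, normalize = TRUE)
  has_epsc <- rep(c(TRUE, FALSE), each = 10)
  rows <- t(sapply(has_epsc, function(e) {
    temp + (if (e) epsc else 0) + rnorm(length(t_ms), 0, 0.3)
  }))
  a <- make_aligned(rows, t_ms)
  cleaned <- subtract_photocurrent(a, epsc_rows = has_epsc)
  resp <- cleaned$snippets[has_epsc, , drop = FALSE]
  amps <- apply(resp, 1, window_amplitude, t_ms = t_ms)
  expect_lt(abs(mean(amps) - 20) / 20, 0.1)
  # template-only rows are flattened to the noise floor
  flat <- cleaned$snippets[!has_epsc, , drop = FALSE]
  expect_lt(sqrt(mean(flat^2)), 0.5)
  # idempotence on template-only data (no noise)
  pure <- make_aligned(t(replicate(6, temp)), t_ms)
  c1 <- subtract_photocurrent(pure, epsc_rows = rep(FALSE, 6))
  c2 <- subtract_photocurrent(make_aligned(c1$snippets, t_ms),
                              epsc_rows = rep(FALSE, 6))
  expect_lt(max(abs(c2$snippets - c1$snippets)), 1e-9)
  expect_error(subtract_photocurrent(a, epsc_rows = rep(TRUE, 20)),
               "no EPSC-free rows")
})

test_that("window amplitude is offset-invariant and zero on flat rows", {
  flat <- numeric(length(t_ms))
  expect_equal(window_amplitude(flat, t_ms), 0)
  pulse <- ifelse(t_ms >= 5 & t_ms <= 15, -10, 0)
  expect_equal(window_amplitude(pulse, t_ms), 10)
  expect_equal(window_amplitude(pulse - 5, t_ms),
               window_amplitude(pulse, t_ms), tolerance = 1e-9)
  expect_equal(window_amplitude(flat - 5, t_ms), 0)
})
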