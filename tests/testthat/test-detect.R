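test_that("pure noise below threshold yields no detections and events
           closer than 2 ms merge into one", {
  set.seed(7)
  z <- detrend_and_noise(rnorm(25000, 0, 2), rate_hz = 5000)
  d <- deconvolve(z)
  p <- detect_putative_events(d, threshold_sd = 3)  # well above noise mass
  expect_equal(nrow(p), 0)

  ev <- tibble::tibble(onset_ms = c(200, 201), height_pa = c(20, 15))
  set.seed(8)
  z2 <- detrend_and_noise(render_events(ev, 500) + rnorm(2500, 0, 1),
                          rate_hz = 5000)
  d2 <- deconvolve(z2)
  p2 <- detect_putative_events(d2)
  near <- p2[abs(p2$onset_hat_ms - 200) < 5, ]
  expect_equal(nrow(near), 1)
})

test_that("detection recalls injected events at SNR 10", {
  set.seed(9)
  n_ev <- 50
  onsets <- sort(runif(n_ev, 50, 24950))
  # enforce >= 10 ms separation for an unambiguous benchmark
  onsets <- onsets[c(TRUE, diff(onsets) > 10)]
  ev <- tibble::tibble(onset_ms = onsets, height_pa = 20)
  z <- detrend_and_noise(render_events(ev, 25000) + rnorm(125000, 0, 2),
                         rate_hz = 5000)
  d <- deconvolve(z)
  p <- detect_putative_events(d)
  strong <- p[p$height_hat_pa > 5, ]
  m <- match_events(strong$onset_hat_ms, ev$onset_ms, tol_ms = 1)
  expect_gte(m$recall, 0.9)
  expect_gte(sum(!is.na(m$match)) / nrow(strong), 0.9)  # precision
})

test_that("clusters split far-apart events, join overlapping ones, and
           tile the trace without overlap", {
  ev <- tibble::tibble(onset_ms = c(100, 200), height_pa = c(20, 20))
  z <- detrend_and_noise(render_events(ev, 400), rate_hz = 5000)
  d <- deconvolve(z)
  p <- detect_putative_events(d)
  cl <- cluster_events(d, p)
  expect_equal(nrow(cl), 2)

  ev2 <- tibble::tibble(onset_ms = c(100, 105), height_pa = c(20, 20))
  z2 <- detrend_and_noise(render_events(ev2, 400), rate_hz = 5000)
  d2 <- deconvolve(z2)
  p2 <- detect_putative_events(d2)
  cl2 <- cluster_events(d2, p2)
  expect_equal(nrow(cl2), 1)
  expect_equal(length(cl2$event_idx[[1]]), nrow(p2))

  # merged segments are ordered and disjoint
  set.seed(10)
  ev3 <- tibble::tibble(onset_ms = sort(runif(20, 50, 3950)),
                        height_pa = runif(20, 10, 30))
  z3 <- detrend_and_noise(render_events(ev3, 4000) + rnorm(20000, 0, 2),
                          rate_hz = 5000)
  d3 <- deconvolve(z3)
  p3 <- detect_putative_events(d3)
  cl3 <- cluster_events(d3, p3)
  expect_true(all(diff(cl3$start_ms) > 0))
  expect_true(all(cl3$start_ms[-1] > cl3$end_ms[-nrow(cl3)]))
  # every putative event lands in exactly one cluster
  expect_equal(sort(unlist(cl3$event_idx)), seq_len(nrow(p3)))
})
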