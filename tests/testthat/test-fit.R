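test_that("a single noiseless event is recovered with tight parameter
           error", {
  ev <- tibble::tibble(onset_ms = 100, height_pa = 20)
  set.seed(1)
  out <- detect_epscs(render_events(ev, 600) + rnorm(3000, 0, 0.5), seed = 1)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$height_pa - 20) / 20, 0.05)
  expect_lt(abs(out$onset_ms - 100), 0.2)
  expect_lt(abs(out$tau_decay_ms - 3.5) / 3.5, 0.25)
  expect_gt(out$tau_decay_ms, out$tau_rise_ms)
})

test_that("two overlapping events 4 ms apart are decomposed with both
           amplitudes within 20%", {
  ev <- tibble::tibble(onset_ms = c(200, 204), height_pa = c(15, 25))
  set.seed(2)
  out <- detect_epscs(render_events(ev, 600) + rnorm(3000, 0, 2), seed = 2)
  out <- out[out$onset_ms > 190 & out$onset_ms < 215, ]
  expect_equal(nrow(out), 2)
  out <- out[order(out$onset_ms), ]
  expect_lt(abs(out$height_pa[1] - 15) / 15, 0.2)
  expect_lt(abs(out$height_pa[2] - 25) / 25, 0.2)
})

test_that("fitted decay always exceeds rise across a random benchmark", {
  set.seed(3)
  ev <- tibble::tibble(onset_ms = sort(runif(12, 100, 5900)),
                       height_pa = runif(12, 8, 30))
  out <- detect_epscs(render_events(ev, 6000) + rnorm(30000, 0, 2), seed = 3)
  expect_true(all(out$tau_decay_ms > out$tau_rise_ms))
})

test_that("sub-threshold events are fitted then discarded", {
  ev <- tibble::tibble(onset_ms = 300, height_pa = 2)
  set.seed(4)
  out <- detect_epscs(render_events(ev, 600) + rnorm(3000, 0, 1.5), seed = 4)
  # 2 pA < 2.5 x 1.5 pA: nothing survives
  expect_equal(nrow(out), 0)
})

test_that("the pipeline is invariant to a constant holding-current offset
           and monotone in the final threshold", {
  set.seed(5)
  ev <- tibble::tibble(onset_ms = c(150, 400, 700), height_pa = c(12, 20, 28))
  base <- render_events(ev, 1000) + rnorm(5000, 0, 2)
  a <- detect_epscs(base, seed = 7)
  b <- detect_epscs(base - 55, seed = 7)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$onset_ms - b$onset_ms)), 1e-6)
  expect_lt(max(abs(a$height_pa - b$height_pa)), 1e-6)

  hi <- detect_epscs(base, height_threshold_sd = 4, seed = 7)
  expect_lte(nrow(hi), nrow(a))
})

test_that("noiseless well-separated events match ground truth within
           (0.4 ms, 5%)", {
  ev <- tibble::tibble(onset_ms = c(120, 350, 680),
                       height_pa = c(25, 14, 19))
  set.seed(6)
  out <- detect_epscs(render_events(ev, 900) + rnorm(4500, 0, 0.4), seed = 6)
  expect_equal(nrow(out), 3)
  out <- out[order(out$onset_ms), ]
  expect_true(all(abs(out$onset_ms - ev$onset_ms) < 0.4))
  expect_true(all(abs(out$height_pa - ev$height_pa) / ev$height_pa < 0.05))
})
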