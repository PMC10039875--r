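test_that("stimulation schedules have the right counts and are
           deterministic given the seed", {
  s1 <- make_stim_schedule(1, n_pulses = 10, repetitions = 2, seed = 3)
  expect_equal(nrow(s1), 20)
  s2 <- make_stim_schedule(100, n_pulses = 15, repetitions = 2, seed = 3)
  expect_equal(nrow(s2) / 100, 30)   # mean stimulations per target
  s3 <- make_stim_schedule(100, n_pulses = 15, repetitions = 2, seed = 3)
  expect_identical(s2, s3)
  expect_error(make_stim_schedule(0), "n_targets")
  # pulse times strictly increasing per target, trains non-overlapping
  expect_true(all(diff(s1$time_ms[order(s1$time_ms)]) > 0))
})

test_that("spontaneous-only simulation yields Poisson counts at the
           configured rate", {
  sched <- make_stim_schedule(1, seed = 4)
  truth <- make_ground_truth(sched, connected = FALSE, spont_rate_hz = 2,
                             seed = 4)
  counts <- vapply(1:30, function(i) {
    nrow(simulate_event_stream(sched, truth, duration_ms = 60000, seed = i))
  }, numeric(1))
  # expectation 120; total over 30 runs ~ Poisson(3600)
  expect_lt(abs(sum(counts) - 3600) / sqrt(3600), 4)
  ev <- simulate_event_stream(sched, truth, duration_ms = 60000, seed = 1)
  expect_true(all(ev$provenance == "spontaneous"))
})

test_that("evoked latencies follow the configured gamma bump", {
  sched <- make_stim_schedule(50, n_pulses = 10, repetitions = 2, seed = 8)
  truth <- make_ground_truth(sched, connected = TRUE, e_p = 10, seed = 8)
  ev <- simulate_event_stream(sched, truth, seed = 8)
  lat <- ev$latency_ms[ev$provenance == "evoked"]
  expect_gt(length(lat), 5000)
  se <- 6.33 / sqrt(length(lat))
  # bump truncated at the 90 ms window edge barely moves the mean
  expect_lt(abs(mean(lat) - 12.96), 3 * se + 0.05)
})

test_that("noiseless rendering is linear and consistent with the
           ground-truth table", {
  ev1 <- tibble::tibble(onset_ms = c(50, 200), height_pa = c(10, 25))
  ev2 <- tibble::tibble(onset_ms = 120, height_pa = 18)
  tr_union <- render_events(dplyr::bind_rows(ev1, ev2), 400)
  tr_sum <- render_events(ev1, 400) + render_events(ev2, 400)
  expect_lt(max(abs(tr_union - tr_sum)), 1e-9)

  # single noiseless event: trace minimum = -height at the kernel peak
  tr <- render_events(tibble::tibble(onset_ms = 100, height_pa = 20), 300)
  expect_equal(min(tr), -20, tolerance = 1e-2)

  # re-rendering the stored event table reproduces the trace exactly
  sched <- make_stim_schedule(2, seed = 5)
  truth <- make_ground_truth(sched, connected = TRUE, noise_sd_pa = 0,
                             seed = 5)
  rec <- simulate_trace(sched, truth, seed = 5)
  rerender <- render_events(rec$events, rec$duration_ms, rec$rate_hz)
  expect_lt(max(abs(rec$current_pa - rerender)), 1e-9)
})

test_that("trace simulation rejects schedules longer than the trace and
           low sampling rates", {
  sched <- make_stim_schedule(2, seed = 1)
  truth <- make_ground_truth(sched, seed = 1)
  expect_error(simulate_trace(sched, truth, duration_ms = 100, seed = 1),
               "duration")
  expect_error(simulate_trace(sched, truth, rate_hz = 1000, seed = 1),
               "5000")
})

test_that("pair-feature tables honour the logistic ground truth", {
  # intercept-only: prevalence matches within 3 SE
  b0 <- qlogis(0.025)
  d <- simulate_pair_features(1e5, c(b0, rep(0, 20)), rho = 0,
                              n_binary = 0, seed = 2)
  se <- sqrt(0.025 * 0.975 / 1e5)
  expect_lt(abs(mean(d$connected) - 0.025), 3 * se)
  # null effects: labels independent of features
  r <- abs(cor(d$f1, d$connected))
  expect_lt(r, 3 / sqrt(1e5) * 1.5)
  # sign recovery of two real effects by an unregularized fit
  d2 <- simulate_pair_features(5000, c(qlogis(0.2), 1, -1, rep(0, 3)),
                               rho = 0, n_binary = 0, seed = 3)
  fit <- glm(connected ~ ., data = d2, family = binomial())
  expect_gt(coef(fit)[["f1"]], 0)
  expect_lt(coef(fit)[["f2"]], 0)
  expect_error(
    simulate_pair_features(100, c(0, 1, 1),
                           correlation = matrix(1, 2, 2), seed = 1),
    "singular")
})

test_that("intercept calibration hits a requested prevalence", {
  d <- simulate_pair_features(5e4, c(0, 1, -1, rep(0, 8)), rho = 0,
                              n_binary = 0, prevalence = 0.025, seed = 7)
  expect_lt(abs(mean(d$connected) - 0.025), 3 * sqrt(0.025 * 0.975 / 5e4))
})

test_that("cell volumes are homogeneous Poisson in the box", {
  vol <- simulate_cell_volume(2000, c(420, 420, 300), seed = 1)
  lambda <- 2000 * 420 * 420 * 300 / 1e9  # ~106
  counts <- vapply(1:20, function(i) {
    nrow(simulate_cell_volume(2000, c(420, 420, 300), seed = i))
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 20))
  expect_true(all(vol$x_um >= 0 & vol$x_um <= 420))
  v2 <- simulate_cell_volume(2000, c(420, 420, 300), seed = 1)
  expect_identical(vol, v2)
  expect_error(simulate_cell_volume(-1), "density")
})

test_that("event counts in disjoint windows of a spontaneous-only
           simulation are Poisson (chi-square GOF)", {
  sched <- make_stim_schedule(1, seed = 10)
  truth <- make_ground_truth(sched, connected = FALSE, spont_rate_hz = 50,
                             seed = 10)
  ev <- simulate_event_stream(sched, truth, duration_ms = 120000, seed = 10)
  breaks <- seq(0, 120000, by = 1000)
  counts <- table(cut(ev$onset_ms, breaks))
  lam <- mean(counts)
  # bin observed counts, compare to Poisson pmf
  kmax <- max(counts)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  expected <- dpois(0:kmax, lam) * length(counts)
  keep <- expected > 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi2, df = sum(keep) - 2, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
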