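# a tiny sampler profile keeps these unit tests quick; the full fast
# profile is exercised in the acceptance suite
tiny_cfg <- sampler_config("fast", n_tune = 400, n_draws = 300)

test_that("the decision rule is an inclusive conjunction of the three
           weight thresholds", {
  w <- tibble::tibble(w_rt = c(0.6, 0.6, 0.5, 0.49, 0.9),
                      w_t = c(0.5, 0.39, 0.4, 0.9, 0.2),
                      w_r = c(0.5, 0.9, 0.4, 0.9, 0.9))
  out <- decide_connected(w)
  expect_equal(out$connected, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(decide_connected(tibble::tibble(w_rt = 1.2, w_t = 0,
                                               w_r = 0)), "0, 1")
})

test_that("model log-posterior gradients agree with finite differences", {
  sched <- make_stim_schedule(2, n_pulses = 10, repetitions = 2, seed = 7)
  truth <- make_ground_truth(sched, connected = c(TRUE, FALSE), e_p = 0.5,
                             seed = 7)
  evs <- simulate_event_stream(sched, truth, seed = 7)
  ep <- segment_epochs(evs, sched, 1)
  v <- synaptomap:::epoch_vectors(ep)
  pr <- connectivity_priors(rate_mu = 0.002, rate_sigma = 0.002)
  fd <- function(lp, par) {
    vapply(seq_along(par), function(i) {
      e <- 1e-6; pp <- par; pm <- par
      pp[i] <- pp[i] + e; pm[i] <- pm[i] - e
      (lp(pp)$value - lp(pm)$value) / (2 * e)
    }, numeric(1))
  }
  for (case in list(list(conn = FALSE, vb = FALSE, extra = NULL),
                    list(conn = TRUE, vb = FALSE, extra = log(0.4)),
                    list(conn = TRUE, vb = TRUE,
                         extra = c(log(0.4), log(12), 0.3)))) {
    lp <- synaptomap:::make_rate_time_lp(v, pr, connected = case$conn,
                                         variable_bump = case$vb)
    par <- c(log(0.003), log(0.002), case$extra)
    expect_lt(max(abs(lp(par)$grad - fd(lp, par))), 1e-6)
  }
})

test_that("a clearly connected and a clearly unconnected target are
           classified correctly with weights that are valid
           probabilities", {
  sched <- make_stim_schedule(2, n_pulses = 10, repetitions = 2, seed = 7)
  truth <- make_ground_truth(sched, connected = c(TRUE, FALSE), e_p = 0.7,
                             seed = 7)
  evs <- simulate_event_stream(sched, truth, seed = 7)
  res_c <- fit_connectivity_models(segment_epochs(evs, sched, 1),
                                   config = tiny_cfg, seed = 1)
  res_n <- fit_connectivity_models(segment_epochs(evs, sched, 2),
                                   config = tiny_cfg, seed = 1)
  for (r in list(res_c, res_n)) {
    expect_true(all(c(r$w_rt, r$w_t, r$w_r) >= 0 &
                      c(r$w_rt, r$w_t, r$w_r) <= 1))
  }
  expect_true(res_c$connected)
  expect_false(res_n$connected)
})

test_that("the variable-bump model recovers a planted latency bump and
           respects the width bounds", {
  sched <- make_stim_schedule(1, n_pulses = 15, repetitions = 2, seed = 9)
  truth <- make_ground_truth(sched, connected = TRUE, e_p = 1,
                             bump_center_ms = 10, bump_width_ms = 4,
                             bump_family = "normal", seed = 9)
  evs <- simulate_event_stream(sched, truth, seed = 9)
  bf <- fit_bump(segment_epochs(evs, sched, 1), config = tiny_cfg, seed = 2)
  s <- bf$summary
  center <- s$median[s$parameter == "bump_center_ms"]
  expect_gt(center, 8); expect_lt(center, 12)
  expect_true(all(bf$draws[, "bump_width_ms"] >= 3 &
                    bf$draws[, "bump_width_ms"] <= 8))
})

test_that("per-pair pseudo-BMA weights always sum to one", {
  set.seed(12)
  e1 <- rnorm(40, -1); e2 <- e1 + rnorm(40, 0.05)
  w <- pseudo_bma_weights(list(e1, e2), seed = 3)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("manual overrides replace model calls for listed targets only", {
  calls <- tibble::tibble(target_id = 1:3,
                          connected = c(TRUE, FALSE, FALSE))
  lab <- tibble::tibble(target_id = 2, connected = TRUE)
  out <- apply_manual_overrides(calls, lab)
  expect_equal(out$connected, c(TRUE, TRUE, FALSE))
  expect_equal(out$overridden, c(FALSE, TRUE, FALSE))
})

test_that("detection weight grows with the evoked-event rate", {
  ep_levels <- c(0.1, 0.3, 0.5, 1.0)
  sched <- make_stim_schedule(12, n_pulses = 10, repetitions = 2, seed = 15)
  truth <- make_ground_truth(sched, connected = rep(TRUE, 12),
                             e_p = rep(ep_levels, each = 3),
                             bump_family = "normal", bump_center_ms = 13,
                             bump_width_ms = 5, seed = 15)
  evs <- simulate_event_stream(sched, truth, seed = 15)
  pooled <- empirical_spont_rate(evs, sched)
  pr <- connectivity_priors(rate_mu = pooled, rate_sigma = pooled)
  w <- vapply(1:12, function(tid) {
    fit_connectivity_models(segment_epochs(evs, sched, tid), priors = pr,
                            config = tiny_cfg, seed = tid)$w_rt
  }, numeric(1))
  means <- tapply(w, rep(ep_levels, each = 3), mean)
  # monotone nondecreasing up to small Monte-Carlo slack
  expect_true(all(diff(means) > -0.05))
  expect_gt(means[["1"]], means[["0.1"]])
})
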