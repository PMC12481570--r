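test_that("baseline estimation is robust to events", {
  flat <- current_trace(rep(-10, 200), 50000)
  est <- estimate_baseline(flat)
  expect_identical(est$lvl0, -10)
  expect_identical(est$noise_sd, 0)

  # ~5% event occupancy, noise SD 0.05 nA
  spec <- simulation_spec(duration_s = 2, seed = 5, event_rate_per_s = 10,
                          dwell_tau_ms = 5, noise_sd_nA = 0.05,
                          filter_cutoff_hz = NULL)
  sim <- simulate_trace(spec)
  est <- estimate_baseline(sim$trace, exclude_fraction = 0.1)
  expect_lt(abs(est$lvl0 - spec$baseline_nA), 0.01)
  expect_lt(abs(est$noise_sd - 0.05), 0.01)

  short <- current_trace(rnorm(50), 50000)
  expect_error(estimate_baseline(short), "at least 100")
  expect_error(estimate_baseline(sim$trace, exclude_fraction = 0.6), "0.5")
})

test_that("a flat trace yields no events", {
  tr <- current_trace(rep(-13.6, 5000), 50000)
  ev <- detect_events(tr, detection_config(lvl0 = -13.6, lvl1 = 0.5,
                                           tolerance = 0.2))
  expect_equal(nrow(ev), 0L)
})

test_that("noise-free detection reproduces the ledger exactly", {
  for (s in c(3, 17, 101)) {
    spec <- noisefree_spec(s, shapes = c(square = 0.5, deep_first = 0.25,
                                         ramp_then_deep = 0.25))
    sim <- simulate_trace(spec)
    ev <- detect_events(sim$trace,
                        detection_config(lvl0 = -13.6, lvl1 = 0.4,
                                         tolerance = 0.15,
                                         min_event_samples = 2))
    expect_equal(nrow(ev), nrow(sim$ledger), info = paste("seed", s))
    expect_true(all(abs(ev$start_index - sim$ledger$start_index) <= 1))
    expect_true(all(abs(ev$end_index - sim$ledger$end_index) <= 1))
    expect_lt(max(abs(ev$blockage_pct - sim$ledger$true_blockage_pct)), 1e-9)
    expect_lt(max(abs(ev$dwell_ms - sim$ledger$true_dwell_ms)),
              1 / 50000 * 1000 + 1e-12)
  }
})

test_that("a deflection exactly at the lvl1 deviation does not trigger", {
  x <- rep(-10, 1000)
  x[500:520] <- -9.5  # deviation exactly 0.5
  tr <- current_trace(x, 50000)
  cfg <- detection_config(lvl0 = -10, lvl1 = 0.5, tolerance = 0.1)
  expect_equal(nrow(detect_events(tr, cfg)), 0L)
  # one epsilon deeper and it triggers
  x[500:520] <- -9.5 + 1e-9
  expect_equal(nrow(detect_events(current_trace(x, 50000), cfg)), 1L)
})

test_that("detection is invariant to a global sign flip", {
  spec <- noisy_spec(7)
  sim <- simulate_trace(spec)
  cfg <- noisy_config()
  ev <- detect_events(sim$trace, cfg)
  flipped <- current_trace(-sim$trace$samples, 50000)
  cfg_f <- detection_config(lvl0 = 13.6, lvl1 = 0.3, tolerance = 0.15,
                            min_event_samples = 2)
  ev_f <- detect_events(flipped, cfg_f)
  expect_equal(ev_f$start_index, ev$start_index)
  expect_equal(ev_f$end_index, ev$end_index)
  expect_equal(ev_f$blockage_pct, ev$blockage_pct)
})

test_that("tolerance closure captures shallow event tails beyond lvl1", {
  # deep core with shallow shoulders above tolerance but below lvl1
  x <- rep(-10, 2000)
  x[1000:1099] <- -9.7   # shoulder: deviation 0.3
  x[1040:1059] <- -8.5   # core: deviation 1.5
  x[1100:1199] <- -9.7   # trailing shoulder
  tr <- current_trace(x, 50000)
  ev <- detect_events(tr, detection_config(lvl0 = -10, lvl1 = 1,
                                           tolerance = 0.1))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_index, 999)   # 0-based: first out-of-tolerance sample
  expect_equal(ev$end_index, 1199)    # half-open at first in-tolerance sample
})

test_that("boundary-touching events are discarded but counted", {
  x <- rep(-10, 1000)
  x[1:50] <- -8         # touches the left boundary
  x[500:540] <- -8      # interior event
  tr <- current_trace(x, 50000)
  ev <- detect_events(tr, detection_config(lvl0 = -10, lvl1 = 1,
                                           tolerance = 0.1))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_index, 499)
  expect_equal(attr(ev, "n_boundary_discarded"), 1L)
})

test_that("merge gap joins nearby events and merging is exhaustive", {
  x <- rep(-10, 3000)
  x[1000:1049] <- -8
  x[1055:1104] <- -8    # 5-sample gap
  x[2000:2049] <- -8    # far away
  tr <- current_trace(x, 50000)
  cfg0 <- detection_config(lvl0 = -10, lvl1 = 1, tolerance = 0.1,
                           merge_gap_samples = 0)
  expect_equal(nrow(detect_events(tr, cfg0)), 3L)
  cfg5 <- detection_config(lvl0 = -10, lvl1 = 1, tolerance = 0.1,
                           merge_gap_samples = 5)
  ev <- detect_events(tr, cfg5)
  expect_equal(nrow(ev), 2L)
  # merging already exhaustive: no surviving pair is within the merge gap
  gaps <- ev$start_index[-1] - ev$end_index[-nrow(ev)]
  expect_true(all(gaps > 5))
})

test_that("auto baseline detection matches a user-supplied lvl0", {
  spec <- noisy_spec(9)
  sim <- simulate_trace(spec)
  cfg_auto <- detection_config(lvl0 = "auto", lvl1 = 0.3, tolerance = 0.15,
                               min_event_samples = 2)
  ev_auto <- detect_events(sim$trace, cfg_auto)
  ev_fix <- detect_events(sim$trace, noisy_config())
  expect_equal(nrow(ev_auto), nrow(ev_fix))
  expect_false(is.na(attr(ev_auto, "noise_sd")))
  expect_lt(abs(attr(ev_auto, "config")$lvl0 - (-13.6)), 0.01)
})

test_that("per-event features follow their definitions", {
  x <- rep(-10, 200)
  x[51:100] <- -8
  tr <- current_trace(x, 50000)
  f <- compute_features(tr, 50, 100, lvl0 = -10, padding = 10)
  expect_equal(f$dwell_ms, 1.0)
  expect_equal(f$blockage_pct, 20)
  expect_equal(f$peak_blockage_pct, 20)
  expect_equal(f$depth_nA, 2)
  expect_equal(f$t_extremum_frac, (50 - 1) / 2 / 50)  # plateau midpoint
  expect_equal(f$padded_start, 40)
  expect_equal(f$padded_end, 110)

  # deep-first sawtooth: extremum in the first half
  y <- rep(-10, 200)
  y[51:100] <- -10 + make_shape("deep_first", 50, 2)
  f2 <- compute_features(current_trace(y, 50000), 50, 100, lvl0 = -10)
  expect_lt(f2$t_extremum_frac, 0.5)

  expect_error(compute_features(tr, 50, 50, lvl0 = -10), "start < end")
  expect_error(compute_features(tr, 50, 100, lvl0 = 0), "nonzero")
})

test_that("noisy blockage estimates concentrate around the truth", {
  spec <- simulation_spec(duration_s = 4, seed = 23, noise_sd_nA = 0.05,
                          filter_cutoff_hz = NULL, event_rate_per_s = 10,
                          dwell_tau_ms = 4.7, baseline_nA = -13.6,
                          blockage_components = list(c(1, 8.3, 0)),
                          shape_mix = c(square = 1, deep_first = 0,
                                        ramp_then_deep = 0),
                          refractory_gap_samples = 250)
  sim <- simulate_trace(spec)
  ev <- detect_events(sim$trace, noisy_config())
  m <- match_events(sim$ledger, ev)
  expect_equal(m$n_fp, 0L)
  # per-event error bound: 3 * noise / (sqrt(n) * |lvl0|) * 100
  for (i in seq_len(nrow(ev))) {
    n_i <- ev$end_index[i] - ev$start_index[i]
    truth <- sim$ledger$true_blockage_pct[
      which(sim$ledger$start_index < ev$end_index[i] &
            sim$ledger$end_index > ev$start_index[i])[1]]
    bound <- 3 * 0.05 / (sqrt(n_i) * 13.6) * 100 + 0.05
    expect_lt(abs(ev$blockage_pct[i] - truth), bound)
  }
})

test_that("stochastic detection meets recall and false-positive bounds", {
  total_samples <- 0; total_events <- 0; total_matched <- 0; total_fp <- 0
  for (s in 1:10) {
    sim <- simulate_trace(noisy_spec(s))
    ev <- detect_events(sim$trace, noisy_config())
    m <- match_events(sim$ledger, ev)
    total_samples <- total_samples + length(sim$trace$samples)
    total_events <- total_events + nrow(sim$ledger)
    total_matched <- total_matched + m$n_matched
    total_fp <- total_fp + m$n_fp
  }
  expect_gt(total_events, 100)
  expect_gte(total_matched / total_events, 0.99)
  expect_lte(total_fp / total_samples * 1e6, 1)
})
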