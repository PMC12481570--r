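test_that("exponential fit equals the closed-form sample mean", {
  expect_equal(fit_dwell_exponential(rep(4.7, 10))$tau_ms, 4.7)
  set.seed(2)
  x <- rexp(400, 1 / 7)
  f <- fit_dwell_exponential(x)
  expect_identical(f$tau_ms, mean(x))         # oracle identity
  expect_identical(f$se_tau_ms, mean(x) / 20)
  expect_equal(coef(f)[["tau_ms"]], mean(x))
})

test_that("exponential MLE recovers a long-dwell population", {
  set.seed(42)
  x <- rexp(2000, 1 / 88.3)
  f <- fit_dwell_exponential(x)
  expect_lt(abs(f$tau_ms - 88.3), 3 * 88.3 / sqrt(2000))
})

test_that("dwell-fit input validation", {
  expect_error(fit_dwell_exponential(c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_dwell_exponential(c(1, 2, 3, 4, 0)), "positive")
  expect_error(fit_dwell_exponential(c(1, 2, 3, 4, -1)), "positive")
})

test_that("the histogram fitting mode roughly agrees with the MLE", {
  set.seed(3)
  x <- rexp(5000, 1 / 4.7)
  mle <- fit_dwell_exponential(x)$tau_ms
  hist_tau <- fit_dwell_exponential(x, method = "histogram")$tau_ms
  expect_lt(abs(hist_tau - mle) / mle, 0.25)
})

test_that("a single Gaussian population selects one component", {
  set.seed(10)
  x <- rnorm(1000, 13.2, 1.0)
  fit <- fit_blockage_populations(x, max_components = 2, seed = 1)
  expect_equal(fit$n_components, 1L)
  expect_lt(abs(fit$components$mean_pct - 13.2), 0.1)
  expect_lt(fit$bic[["1"]], fit$bic[["2"]])
})

test_that("two separated populations are recovered with their weights", {
  set.seed(11)
  x <- c(rnorm(500, 13.2, 0.5), rnorm(500, 18.4, 0.5))
  fit <- fit_blockage_populations(x, max_components = 2, seed = 1)
  expect_equal(fit$n_components, 2L)
  expect_lt(abs(fit$components$mean_pct[1] - 13.2), 0.15)
  expect_lt(abs(fit$components$mean_pct[2] - 18.4), 0.15)
  expect_lt(max(abs(fit$components$weight - 0.5)), 0.05)
  expect_true(all(diff(fit$components$mean_pct) > 0))  # ordered by mean
  expect_equal(sum(fit$components$weight), 1)
})

test_that("EM log-likelihood is monotone and the fit is reproducible", {
  set.seed(12)
  x <- c(rnorm(300, 13.2, 0.8), rnorm(200, 18.4, 0.8))
  f1 <- fit_blockage_populations(x, 2, seed = 99)
  f2 <- fit_blockage_populations(x, 2, seed = 99)
  expect_identical(f1$components, f2$components)  # bit-for-bit
  expect_identical(f1$loglik, f2$loglik)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
})

test_that("the mixture fit agrees with an independent EM implementation", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(13)
  x <- c(rnorm(400, 13.2, 0.6), rnorm(400, 18.4, 0.6))
  ours <- fit_blockage_populations(x, 2, seed = 1)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$components$mean_pct), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
  expect_gte(ours$loglik, ref$loglik - 1e-3)  # same optimum (or better)
})

test_that("degenerate and undersized inputs are handled", {
  expect_warning(fit <- fit_blockage_populations(rep(13.2, 50), 1),
                 "degenerate")
  expect_equal(fit$n_components, 1L)
  expect_equal(fit$components$mean_pct, 13.2)
  expect_gt(fit$components$sd_pct, 0)
  expect_error(fit_blockage_populations(rnorm(30), 2), "at least 40")
  expect_error(fit_blockage_populations(rnorm(10), 1), "at least 20")
})

test_that("fits are invariant to duplicating the dataset", {
  set.seed(14)
  x <- c(rnorm(250, 13.2, 0.5), rnorm(250, 18.4, 0.5))
  f1 <- fit_blockage_populations(x, 2, seed = 5)
  f2 <- fit_blockage_populations(c(x, x), 2, seed = 5)
  expect_equal(f1$components$mean_pct, f2$components$mean_pct, tolerance = 1e-6)
  expect_equal(f1$components$weight, f2$components$weight, tolerance = 1e-6)
  # SEs shrink with n
  expect_true(all(f2$components$se_mean < f1$components$se_mean))
})

test_that("parameter recovery holds across seeded replicates", {
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(500, 13.2, 0.5), rnorm(500, 18.4, 0.5))
    fit <- fit_blockage_populations(x, 2, seed = s)
    mean(abs(fit$components$mean_pct - c(13.2, 18.4)))
  }, numeric(1))
  expect_lte(mean(errs), 0.2)
  expect_true(all(errs < 0.15 + 0.1))  # no replicate far off
})

test_that("condition summaries join both fits and recover a simulated condition", {
  spec <- simulation_spec(duration_s = 20, seed = 31, noise_sd_nA = 0.05,
                          filter_cutoff_hz = NULL, event_rate_per_s = 15,
                          dwell_tau_ms = 4.7, baseline_nA = -13.6,
                          blockage_components = list(c(1, 8.3, 0.4)),
                          shape_mix = c(square = 1, deep_first = 0,
                                        ramp_then_deep = 0),
                          refractory_gap_samples = 250)
  sim <- simulate_trace(spec)
  ev <- detect_events(sim$trace, noisy_config())
  cs <- summarize_condition(ev, max_components = 2, seed = 1)
  n <- cs$n_events
  expect_gt(n, 100)
  expect_equal(cs$blockage$n_components, 1L)
  expect_lt(abs(cs$blockage$components$mean_pct - 8.3), 3 * 0.4 / sqrt(n) + 0.1)
  expect_lt(abs(cs$dwell$tau_ms - 4.7), 3 * 4.7 / sqrt(n) + 0.1)
  expect_match(cs$dwell_text, "±")

  expect_error(summarize_condition(ev[0, ]), "empty")
  expect_error(summarize_condition(ev[1, ]), "at least")
})
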