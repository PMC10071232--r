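# Generators: EMG shape, traces, and the study-level tables.

test_that("EMG apex, normalization, and parameter guards", {
  # Gaussian apex identity at tau = 0
  expect_equal(emg_signal(5, center = 5, area = 2, sigma = 0.1, tau = 0),
               2 / (0.1 * sqrt(2 * pi)))
  # normalization within 0.1% over a grid spanning +/- 10 sigma + 10 tau,
  # across shapes from near-Gaussian to strongly tailed
  for (p in list(c(0.05, 0), c(0.05, 0.01), c(0.04, 0.08), c(0.1, 0.3))) {
    sigma <- p[1]; tau <- p[2]
    tt <- seq(5 - 10 * sigma, 5 + 10 * (sigma + tau), by = sigma / 50)
    y <- emg_signal(tt, 5, area = 123, sigma = sigma, tau = tau)
    expect_equal(sum(y) * (sigma / 50), 123, tolerance = 1e-3)
  }
  expect_error(emg_signal(1, 1, 1, sigma = 0), "sigma")
  expect_error(emg_signal(1, 1, 1, sigma = 0.1, tau = -1), "tau")
})

test_that("EMG matches a numerical convolution oracle and tails correctly", {
  sigma <- 0.05; tau <- 0.05
  tt <- seq(4.7, 5.6, by = 0.01)
  y <- emg_signal(tt, 5, area = 10, sigma = sigma, tau = tau)
  y_oracle <- emg_convolution_oracle(tt, 5, 10, sigma, tau)
  expect_equal(y, y_oracle, tolerance = 1e-5)
  # apex later than the Gaussian center for tau = sigma
  expect_gt(tt[which.max(y)], 5)
  # far tail is finite (stable evaluation), not NaN
  expect_true(all(is.finite(emg_signal(seq(0, 100, 5), 5, 1, 0.05, 0.05))))
  expect_true(all(is.finite(emg_signal(seq(0, 100, 5), 5, 1, 0.05, 1e-6))))
})

test_that("simulate_chromatogram is deterministic and exact at zero noise", {
  expect_true(all(simulate_chromatogram(list(), duration = 2)$signal == 0))

  pk <- peak_model("X", retention = 6, area = 100, sigma = 0.05, tau = 0.05)
  tr <- simulate_chromatogram(pk, duration = 8)
  # apex equals the EMG mode within one grid step
  mode <- stats::optimize(function(t) emg_signal(t, 6, 100, 0.05, 0.05),
                          c(5.8, 6.3), maximum = TRUE)$maximum
  expect_equal(tr$time[which.max(tr$signal)], mode, tolerance = 1 / 600)
  # exact sum of peak signals at noise 0
  expect_equal(tr$signal, emg_signal(tr$time, 6, 100, 0.05, 0.05))

  a <- simulate_chromatogram(pk, noise_sd = 5, seed = 42, duration = 8)
  b <- simulate_chromatogram(pk, noise_sd = 5, seed = 42, duration = 8)
  expect_identical(a$signal, b$signal)
  expect_false(identical(
    a$signal, simulate_chromatogram(pk, noise_sd = 5, seed = 43,
                                    duration = 8)$signal))
  # caller RNG stream is not disturbed
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_chromatogram(pk, noise_sd = 1, seed = 1,
                                               duration = 8))
  expect_identical(rnorm(1), before)

  expect_error(simulate_chromatogram(pk, duration = 5), "X")
})

test_that("factorial study: determinism, design guard, truth recovery", {
  study <- simulate_doe_study()
  expect_identical(as.data.frame(study), as.data.frame(simulate_doe_study()))
  bad <- build_design(uplc_factor_levels())[c(1:7, 7), ]
  class(bad) <- c("ffd_design", "data.frame")
  expect_error(simulate_doe_study(design = bad), "2\\^3")

  # retention truth is linear in the coded factors, so the A-effect on
  # k'(OSTP) estimated from measured apexes equals the truth contrast
  # 2 * bA / t_m up to grid/measurement error
  truth <- uplc_truth()
  fit <- estimate_effects(study, "kprime_ostp")
  expect_equal(unname(fit$effects["A"]), 2 * (-0.40) / truth$t_m,
               tolerance = 0.02)
  expect_equal(unname(fit$effects["C"]), 2 * 0.15 / truth$t_m,
               tolerance = 0.02)
  # sign semantics: more methanol -> less retention; more buffer -> less
  # tailing
  expect_lt(fit$effects["A"], 0)
  expect_lt(estimate_effects(study, "tailing_ostp")$effects["B"], 0)
})

test_that("calibration generator: exact pass-through and slope recovery", {
  lv <- c(10, 50, 100, 250, 400, 500)
  tab0 <- simulate_calibration(slope = 80, intercept = -200, resid_sd = 0,
                               levels = lv)
  f <- fit_line(tab0$concentration, tab0$response)
  expect_equal(f$slope, 80)
  expect_equal(f$intercept, -200)
  expect_equal(f$r_squared, 1)

  expect_error(simulate_calibration(80, levels = 5), "distinct")
  expect_error(simulate_calibration(80, levels = c(-1, 5)), "non-negative")

  # Monte-Carlo: mean fitted slope within 2 SE of truth over 200 seeds
  slopes <- vapply(1:200, function(s) {
    tab <- simulate_calibration(slope = 80, intercept = -200, resid_sd = 50,
                                levels = lv, replicates = 3, seed = s)
    fit_line(tab$concentration, tab$response)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 80), 2 * stats::sd(slopes) / sqrt(200))
})

test_that("standard-addition generator matches the analysis bookkeeping", {
  s <- simulate_standard_addition(sample_truth = 2.463, slope = 8000,
                                  aliquots = c(0, 2, 3, 4, 5, 6))
  expect_equal(s$added, c(0, 0.5, 0.75, 1.0, 1.25, 1.5))
  expect_equal(analyze_series(s)$content, 2.463)

  s1 <- simulate_standard_addition(1, 100, c(0, 2, 4), resid_sd = 5, seed = 1)
  s2 <- simulate_standard_addition(1, 100, c(0, 2, 4), resid_sd = 5, seed = 2)
  expect_identical(s1$added, s2$added)
  expect_false(identical(s1$response, s2$response))
  expect_error(simulate_standard_addition(1, 100, c(2, 4)), "include 0")
  expect_error(simulate_standard_addition(1, 100, c(0, -2)), "non-negative")
})

test_that("stability generator: drift arithmetic and determinism", {
  flat <- simulate_stability(80, 0, c(0, 7, 8))
  expect_equal(to_ratio_series(flat$day, flat$slope)$ratio_pct,
               c(100, 100, 100))
  drift <- simulate_stability(80, 0.12, c(0, 4, 8, 12))
  est <- storage_period(to_ratio_series(drift$day, drift$slope))
  expect_equal(est$days, 2 / 0.12)
  expect_identical(simulate_stability(80, 0.1, 0:8, noise_sd = 1, seed = 3),
                   simulate_stability(80, 0.1, 0:8, noise_sd = 1, seed = 3))
  expect_error(simulate_stability(-1, 0, c(0, 1)), "positive")
})
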