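# Peak measurement and the four system-suitability statistics.

gauss_trace <- function(centers, sigma = 0.05, area = 100, duration = 12,
                        sampling_hz = 20) {
  pks <- lapply(seq_along(centers), function(i)
    peak_model(paste0("p", i), centers[i], area = area, sigma = sigma))
  simulate_chromatogram(pks, duration = duration, sampling_hz = sampling_hz)
}

test_that("detect_and_measure recovers Gaussian geometry", {
  tr <- gauss_trace(5, sigma = 0.1, duration = 8)
  pk <- detect_and_measure(tr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$t_R, 5, tolerance = 1e-4)
  expect_equal(pk$W50, 2.355 * 0.1, tolerance = 1 / 1200 / (2.355 * 0.1))
  expect_equal(pk$area, 100, tolerance = 1e-3)
  # symmetric peak: f5 is half of W5
  expect_equal(pk$f5, pk$W5 / 2, tolerance = 0.01)

  two <- detect_and_measure(gauss_trace(c(7.5, 5)))
  expect_equal(nrow(two), 2L)
  expect_true(!is.unsorted(two$t_R))

  # flat trace: no peaks, not an error
  flat <- list(time = seq(0, 1, 0.01), signal = rep(1, 101))
  expect_equal(nrow(detect_and_measure(flat)), 0L)
  expect_error(detect_and_measure(list(time = c(0, 0.1, 0.3),
                                       signal = c(0, 1, 0))), "uniform")
})

test_that("tailed EMG peak has a narrow leading edge", {
  tr <- simulate_chromatogram(peak_model("X", 6, 100, sigma = 0.05,
                                         tau = 0.05), duration = 9)
  pk <- detect_and_measure(tr)
  expect_lt(pk$f5, pk$W5 / 2)
  expect_gt(tailing_factor(pk$W5, pk$f5), 1)
})

test_that("capacity factor arithmetic and guards", {
  expect_equal(capacity_factor(1.5, 1.5), 0)
  expect_equal(capacity_factor(3.0, 1.5), 1.0)
  # dead time back-solved from a practical k' of 0.526 at t_R = 6.323
  t_m <- 6.323 / 1.526
  expect_equal(capacity_factor(6.323, t_m), 0.526, tolerance = 1e-3)
  expect_error(capacity_factor(2, 0), "t_m")
  expect_warning(capacity_factor(1, 2), "negative")
})

test_that("resolution from geometry and from measured traces", {
  p1 <- list(t_R = 5, W_base = 0.4)
  p2 <- list(t_R = 5.4, W_base = 0.4)
  expect_equal(resolution(p1, p2), 1.0)
  expect_equal(resolution(p1, list(t_R = 5, W_base = 0.4)), 0)
  expect_error(resolution(p2, p1), "after")
  expect_error(resolution(list(t_R = 5, W_base = 0), p2), "width")

  # Gaussian pair: W_base = 4 sigma, so Rs = 2 * 0.5 / (8 * 0.05) = 2.5
  pk <- detect_and_measure(gauss_trace(c(8, 8.5), sigma = 0.05))
  expect_equal(resolution(pk[1, ], pk[2, ]), 2.5, tolerance = 0.02)
})

test_that("tailing factor and plate number formulas", {
  expect_equal(tailing_factor(0.2, 0.1), 1.0)
  expect_equal(tailing_factor(0.30, 0.10), 1.5)
  expect_error(tailing_factor(0.3, 0), "f5")

  expect_equal(plate_number(10, 0.5), 2216)
  expect_equal(plate_number(10, 1.0), 2216 / 4) # doubling W50 quarters N
  expect_error(plate_number(10, 0), "W50")

  # end-to-end on a noiseless Gaussian: T ~ 1, N ~ 5.54 (t/sigma)^2 / 2.355^2
  pk <- detect_and_measure(gauss_trace(8, sigma = 0.05))
  expect_equal(tailing_factor(pk$W5, pk$f5), 1.00, tolerance = 0.02)
  expect_equal(plate_number(pk$t_R, pk$W50), 5.54 * (8 / 0.05)^2 / 2.355^2,
               tolerance = 0.01)
})

test_that("suitability metrics obey shift/scale invariances", {
  base <- gauss_trace(6, sigma = 0.05, duration = 10)
  pk0 <- detect_and_measure(base)
  # amplitude scaling leaves T, N, k' unchanged
  scaled <- list(time = base$time, signal = base$signal * 7.3)
  pk1 <- detect_and_measure(scaled)
  expect_equal(tailing_factor(pk1$W5, pk1$f5), tailing_factor(pk0$W5, pk0$f5))
  expect_equal(plate_number(pk1$t_R, pk1$W50), plate_number(pk0$t_R, pk0$W50))
  expect_equal(capacity_factor(pk1$t_R, 4.1), capacity_factor(pk0$t_R, 4.1))
  # time shift leaves T unchanged
  shifted <- list(time = base$time + 2, signal = base$signal)
  pk2 <- detect_and_measure(shifted)
  expect_equal(tailing_factor(pk2$W5, pk2$f5), tailing_factor(pk0$W5, pk0$f5),
               tolerance = 1e-6)
})

test_that("suitability_report wires the statistics together", {
  tr <- simulate_chromatogram(uplc_truth()$peaks, coded = c(0, 0, 0),
                              duration = 12)
  pk <- detect_and_measure(tr)
  rep4 <- suitability_report(pk, t_m = 4.10)
  expect_equal(nrow(rep4), 4L)
  expect_true(is.na(rep4$Rs_to_previous[1]))
  expect_equal(sum(!is.na(rep4$Rs_to_previous)), 3L)
  expect_true(all(rep4$k_prime > 0))
  expect_true(all(rep4$plates_N > 1000))

  one <- suitability_report(detect_and_measure(gauss_trace(6)), t_m = 4.1)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$Rs_to_previous))
})

test_that("plate count is stable under small detector noise", {
  n_vals <- vapply(1:8, function(s) {
    tr <- simulate_chromatogram(peak_model("X", 6, 100, sigma = 0.05),
                                noise_sd = 2, seed = s, duration = 9,
                                sampling_hz = 20)
    pk <- detect_and_measure(tr, min_height_frac = 0.2)
    plate_number(pk$t_R[1], pk$W50[1])
  }, numeric(1))
  expect_lt(100 * stats::sd(n_vals) / mean(n_vals), 5)
})
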