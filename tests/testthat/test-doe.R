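# Factorial design construction, effect estimation, Lenth screening, and
# the coded/uncoded prediction equations.

paper_levels <- uplc_factor_levels()

test_that("build_design enumerates the 2^3 runs in standard order", {
  d <- build_design(paper_levels)
  expect_equal(nrow(d), 8L)
  expect_equal(unname(unlist(d[8, c("methanol_pct", "aa_conc", "flow_rate")])),
               c(77.0, 20.0, 0.070))
  expect_equal(unname(unlist(d[1, c("methanol_pct", "aa_conc", "flow_rate")])),
               c(73.0, 5.0, 0.030))
  # coded columns sum to zero and are mutually orthogonal (incl. interactions)
  X <- cbind(d$A, d$B, d$C, d$A * d$B, d$A * d$C, d$B * d$C, d$A * d$B * d$C)
  expect_equal(colSums(X), rep(0, 7))
  expect_equal(crossprod(X), diag(8, 7), ignore_attr = TRUE)
  expect_error(build_design(list(a = c(1, 1), b = c(0, 1), c = c(0, 1))),
               "low < high")
})

test_that("effects recover a planted coded model and match least squares", {
  d <- build_design(paper_levels)
  y <- 10 + 2 * d$A - 3 * d$B + 1 * d$A * d$B
  fit <- estimate_effects(d, y)
  expect_equal(fit$effects,
               c(A = 4, B = -6, C = 0, AB = 2, AC = 0, BC = 0, ABC = 0))
  expect_equal(unname(fit$coef_coded["(Intercept)"]), 10)

  const <- estimate_effects(d, rep(3.5, 8))
  expect_equal(unname(const$effects), rep(0, 7))
  expect_equal(unname(const$coef_coded["(Intercept)"]), 3.5)

  # oracle: saturated lm on the 8x8 signed model matrix, random responses
  set.seed(11)
  for (rep in 1:20) {
    y <- rnorm(8)
    fit <- estimate_effects(d, y)
    lmfit <- lm(y ~ A * B * C, data = d)
    expect_equal(unname(fit$coef_coded),
                 unname(coef(lmfit)[c("(Intercept)", "A", "B", "C", "A:B",
                                      "A:C", "B:C", "A:B:C")]))
    # saturated model reproduces every run exactly
    expect_equal(predict(fit, d, warn_extrapolation = FALSE), y)
  }
  expect_error(estimate_effects(d, rep(1, 7)), "8")
})

test_that("Lenth pseudo-standard error follows the trimmed-median recipe", {
  # hand evaluation: |e| sorted (0.5, 0.5, 0.5, 1, 2, 4, 6), median 1,
  # s0 = 1.5; trimming drops |e| >= 2.5 * s0 = 3.75 (the 4 and 6), leaving
  # median 0.5, so pse = 0.75
  effects <- c(A = 4, B = -6, C = 2, AB = 1, AC = 0.5, BC = -0.5, ABC = 0.5)
  res <- lenth_significance(effects, alpha = 0.05)
  expect_equal(res$pse, 0.75)
  expect_equal(res$standardized, effects / 0.75)
  expect_equal(res$margin_of_error, qt(0.975, df = 7 / 3) * 0.75)
  expect_true(all(res$significant[c("A", "B")]))

  # scale equivariance: pse scales, standardized effects do not
  res10 <- lenth_significance(effects * 10)
  expect_equal(res10$pse, 7.5)
  expect_equal(res10$standardized, res$standardized)

  dom <- lenth_significance(c(A = 100, B = 1e-3, C = 1e-3, AB = 1e-3,
                              AC = 1e-3, BC = 1e-3, ABC = 1e-3))
  expect_true(dom$significant["A"])
  expect_false(any(dom$significant[-1]))

  expect_error(lenth_significance(rep(0, 7)), "zero")
  # a mostly-sparse effect vector degenerates the median too
  expect_error(lenth_significance(c(4, -6, 2, 0, 0, 0, 0)), "zero")
})

test_that("uncoded coefficients are an exact re-expression of the coded fit", {
  # coded y = 5 + 2 xA over A in [73, 77] expands to y = uA - 70
  cc <- c(`(Intercept)` = 5, A = 2, B = 0, C = 0, AB = 0, AC = 0, BC = 0,
          ABC = 0)
  beta <- to_uncoded(cc, paper_levels)
  expect_equal(unname(beta["(Intercept)"]), -70)
  expect_equal(unname(beta["A"]), 1)
  expect_equal(unname(beta[c("B", "C", "AB", "AC", "BC", "ABC")]), rep(0, 6),
               tolerance = 1e-12)

  d <- build_design(paper_levels)
  set.seed(5)
  y <- rnorm(8, 10)
  fit <- estimate_effects(d, y)
  # coded and uncoded forms agree at the corners and at the optimum setting
  Xc <- cbind(1, d$A, d$B, d$C, d$A * d$B, d$A * d$C, d$B * d$C,
              d$A * d$B * d$C)
  expect_equal(drop(Xc %*% fit$coef_coded), predict(fit, d), tolerance = 1e-12)
  opt <- data.frame(methanol_pct = 75.7, aa_conc = 8.1818, flow_rate = 0.048)
  xo <- c((75.7 - 75) / 2, (8.1818 - 12.5) / 7.5, (0.048 - 0.05) / 0.02)
  coded_pred <- sum(fit$coef_coded * c(1, xo, xo[1] * xo[2], xo[1] * xo[3],
                                       xo[2] * xo[3], prod(xo)))
  expect_equal(predict(fit, opt), coded_pred)
})

test_that("prediction equals a brute-force linear solve at random points", {
  d <- build_design(paper_levels)
  set.seed(21)
  y <- rnorm(8, 50, 5)
  fit <- estimate_effects(d, y)
  Xu <- cbind(1, d$methanol_pct, d$aa_conc, d$flow_rate,
              d$methanol_pct * d$aa_conc, d$methanol_pct * d$flow_rate,
              d$aa_conc * d$flow_rate,
              d$methanol_pct * d$aa_conc * d$flow_rate)
  beta <- solve(Xu, y)
  pts <- data.frame(methanol_pct = runif(100, 73, 77),
                    aa_conc = runif(100, 5, 20),
                    flow_rate = runif(100, 0.03, 0.07))
  oracle <- drop(cbind(1, pts[, 1], pts[, 2], pts[, 3],
                       pts[, 1] * pts[, 2], pts[, 1] * pts[, 3],
                       pts[, 2] * pts[, 3],
                       pts[, 1] * pts[, 2] * pts[, 3]) %*% beta)
  expect_equal(predict(fit, pts), oracle, tolerance = 1e-9)
  # intercept-only fit predicts the grand mean at the midpoint
  flat <- estimate_effects(d, rep(7, 8))
  expect_equal(predict(flat, data.frame(methanol_pct = 75, aa_conc = 12.5,
                                        flow_rate = 0.05)), 7)
  expect_warning(predict(fit, data.frame(methanol_pct = 80, aa_conc = 12.5,
                                         flow_rate = 0.05)), "design region")
})

test_that("level means reproduce hand-computed cell averages", {
  d <- build_design(paper_levels)
  y <- 10 + 2 * d$A - 3 * d$B # additive: no interaction
  mm <- level_means(d, y, "A")
  expect_equal(mm$mean_response, c(mean(y[d$A == -1]), mean(y[d$A == 1])))
  # main-effect slope sign matches the effect sign
  expect_gt(diff(mm$mean_response), 0)
  cells <- level_means(d, y, "AB")
  expect_equal(nrow(cells), 4L)
  # parallel interaction-plot lines for an additive model
  lowB <- cells$mean_response[cells$level_B == -1]
  highB <- cells$mean_response[cells$level_B == 1]
  expect_equal(diff(lowB), diff(highB))
  # hand check of one cell: A = -1, B = -1 runs
  expect_equal(cells$mean_response[cells$level_A == -1 & cells$level_B == -1],
               mean(y[d$A == -1 & d$B == -1]))
  expect_error(level_means(d, y, "AD"), "unknown")
})
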