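# Independent oracles used across the suite.

# EMG by brute-force numerical convolution of a Gaussian with a normalized
# exponential decay (trapezoidal quadrature on a fine grid)
emg_convolution_oracle <- function(t, center, area, sigma, tau,
                                   n_quad = 6000L) {
  vapply(t, function(ti) {
    s <- seq(0, 30 * tau, length.out = n_quad)
    f <- stats::dnorm(ti - s, mean = center, sd = sigma) *
      exp(-s / tau) / tau
    area * sum((f[-1] + f[-n_quad]) * diff(s)[1] / 2)
  }, numeric(1))
}

# straight line by explicit normal equations
normal_equations_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# random linear-plus-interaction response surface over natural units,
# returned as a prediction function of a settings data.frame
random_surface <- function(bounds) {
  nm <- names(bounds)
  ctr <- vapply(bounds, mean, numeric(1))
  half <- vapply(bounds, function(b) diff(b) / 2, numeric(1))
  coefs <- stats::rnorm(7)
  function(settings) {
    x <- sweep(sweep(as.matrix(settings[nm]), 2, ctr), 2, half, `/`)
    drop(cbind(x, x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
               x[, 1] * x[, 2] * x[, 3]) %*% coefs)
  }
}
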