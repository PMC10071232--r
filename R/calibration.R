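# Calibration statistics, sensitivity limits, and accuracy summaries.

#' Ordinary least-squares calibration line with full statistics
#'
#' Unweighted straight-line fit reporting the statistic set of a validation
#' report: slope, intercept, R^2, and the standard deviations of the
#' residuals (`Syx = sqrt(SSE/(n-2))`), the slope (`Sb = Syx/sqrt(Sxx)`),
#' and the intercept (`Sa = Syx sqrt(sum(x^2)/(n Sxx))`).
#'
#' @param x,y Numeric vectors of equal length (n >= 2, at least two distinct
#'   x). With n = 2 the line is returned with the dispersion statistics
#'   flagged `NA`.
#' @return Object of class `line_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `sd_intercept`, `sd_slope`, `sd_residuals`, `n`.
#' @examples
#' fit_line(c(0, 7, 8), c(100.000, 100.166, 101.413))
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(unique(x)) < 2L) stop("all x values identical", call. = FALSE)
  fit <- stats::lm(y ~ x)
  n <- length(x)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  if (n >= 3L) {
    syx <- sqrt(sse / (n - 2))
    sxx <- sum((x - mean(x))^2)
    sb <- syx / sqrt(sxx)
    sa <- syx * sqrt(sum(x^2) / (n * sxx))
  } else {
    syx <- sb <- sa <- NA_real_
  }
  structure(list(slope = b, intercept = a, r_squared = r2,
                 sd_intercept = sa, sd_slope = sb, sd_residuals = syx,
                 n = n),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line_fit> y = %.6g + %.6g x  (n = %d, R^2 = %.6f)\n",
              x$intercept, x$slope, x$n, x$r_squared))
  cat(sprintf("  Sa = %.6g, Sb = %.6g, Sy/x = %.6g\n",
              x$sd_intercept, x$sd_slope, x$sd_residuals))
  invisible(x)
}

#' Detection and quantitation limits from regression statistics
#'
#' ICH Q2-style limits from the calibration line:
#' `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S`, where `sigma` is the
#' standard deviation of the y-intercept and `S` the slope. The returned
#' limits carry the concentration units of the calibration axis.
#'
#' @param sigma Standard deviation of the y-intercept (response units), >= 0.
#' @param slope Calibration slope (response per concentration), > 0.
#' @return List of class `sensitivity_limits`: `lod`, `loq`,
#'   `method = "sigma_slope"`, `sigma_used`, `slope_used`.
#' @examples
#' lod_loq_sigma(sigma = 55.290, slope = 80.859) # lod 2.256, loq 6.838
#' @export
lod_loq_sigma <- function(sigma, slope) {
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  structure(list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope,
                 method = "sigma_slope", sigma_used = sigma,
                 slope_used = slope),
            class = "sensitivity_limits")
}

#' Detection and quantitation limits from signal-to-noise
#'
#' Pharmacopoeial signal-to-noise convention: `S/N = 2 H / h`, where `H` is
#' the peak height and `h` the peak-to-peak noise in a stated blank window
#' of the trace. The concentration limits scale the injected concentration
#' by `3 / (S/N)` (LOD) and `10 / (S/N)` (LOQ), assuming response linearity.
#' A noiseless blank gives infinite S/N and zero-flagged limits.
#'
#' @param trace A `chromatogram_trace`.
#' @param peak One-row `peak_geometry` entry for the analyte peak.
#' @param blank_window `c(t_start, t_end)` in minutes, containing no peak.
#' @param injected_conc Concentration injected to produce `peak` (any unit;
#'   the limits inherit it).
#' @return List of class `sensitivity_limits`: `lod`, `loq`, `sn`,
#'   `noise_pp`, `method = "signal_noise"`.
#' @export
lod_loq_sn <- function(trace, peak, blank_window, injected_conc = 1) {
  sel <- trace$time >= blank_window[1] & trace$time <= blank_window[2]
  if (!any(sel)) stop("empty blank window", call. = FALSE)
  noise_pp <- diff(range(trace$signal[sel]))
  if (noise_pp == 0) {
    return(structure(list(lod = 0, loq = 0, sn = Inf, noise_pp = 0,
                          method = "signal_noise"),
                     class = "sensitivity_limits"))
  }
  sn <- 2 * peak$height / noise_pp
  structure(list(lod = injected_conc * 3 / sn, loq = injected_conc * 10 / sn,
                 sn = sn, noise_pp = noise_pp, method = "signal_noise"),
            class = "sensitivity_limits")
}

#' @export
print.sensitivity_limits <- function(x, ...) {
  cat(sprintf("<sensitivity_limits> (%s) LOD = %.4g, LOQ = %.4g\n",
              x$method, x$lod, x$loq))
  invisible(x)
}

#' Recovery, precision, and relative-error summary
#'
#' Per-sample recovery is `100 found / nominal`; the summary reports its
#' mean, standard deviation (n - 1 denominator), percentage relative
#' standard deviation, and the percentage relative error
#' `Er = 100 mean(|found - nominal| / nominal)` (mean absolute relative
#' error).
#'
#' @param found Measured concentrations.
#' @param nominal True (spiked) concentrations, positive, same length.
#' @return List of class `recovery_summary`: `mean_recovery_pct`, `sd`,
#'   `rsd_pct`, `er_pct`, `n`, `recovery_pct` (per sample).
#' @export
recovery_stats <- function(found, nominal) {
  if (length(found) != length(nominal)) stop("length mismatch", call. = FALSE)
  if (any(nominal <= 0)) stop("`nominal` must be positive", call. = FALSE)
  rec <- 100 * found / nominal
  m <- mean(rec)
  s <- if (length(rec) > 1L) stats::sd(rec) else NA_real_
  structure(list(mean_recovery_pct = m, sd = s,
                 rsd_pct = if (is.na(s)) NA_real_ else 100 * s / m,
                 er_pct = 100 * mean(abs(found - nominal) / nominal),
                 n = length(rec), recovery_pct = rec),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> mean %.3f%% +/- %.3f (RSD %.3f%%, Er %.3f%%, n = %d)\n",
              x$mean_recovery_pct, x$sd, x$rsd_pct, x$er_pct, x$n))
  invisible(x)
}
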