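# Exponentially-modified-Gaussian peak model and trace simulation.

#' Exponentially modified Gaussian peak amplitude
#'
#' Evaluates the EMG line shape used throughout the simulator: a Gaussian of
#' width `sigma` convolved with a one-sided exponential decay of time constant
#' `tau`. The curve integrates to `area`; as `tau -> 0` it degenerates
#' continuously to a pure Gaussian. Tailed chromatographic peaks (tailing
#' factor above 1) are obtained with `tau > 0`.
#'
#' @param t Numeric vector of times (min) at which to evaluate the signal.
#' @param center Gaussian component center (min). For `tau > 0` the observed
#'   apex lies later than `center`.
#' @param area Peak area (response units x min).
#' @param sigma Gaussian standard deviation (min), strictly positive.
#' @param tau Exponential tail time constant (min), non-negative.
#' @return Numeric vector of detector response, same length as `t`.
#' @examples
#' t <- seq(4, 8, by = 0.001)
#' y <- emg_signal(t, center = 6, area = 100, sigma = 0.05, tau = 0.1)
#' sum(y) * 0.001 # ~ 100
#' @export
emg_signal <- function(t, center, area = 1, sigma, tau = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  if (tau < 1e-12 * sigma)
    return(area * stats::dnorm(t, mean = center, sd = sigma))
  z <- (t - center) / sigma
  u <- (sigma / tau - z) / sqrt(2)
  out <- numeric(length(t))
  pos <- u >= 0
  # u >= 0: scaled-complementary-error-function form is overflow-free
  if (any(pos))
    out[pos] <- area / (2 * tau) * exp(-z[pos]^2 / 2) * erfcx_(u[pos])
  # u < 0 (far trailing tail): exponent sigma^2/(2 tau^2) - (t-center)/tau is
  # provably negative there, so the direct erfc form is safe
  if (any(!pos)) {
    arg <- sigma^2 / (2 * tau^2) - (t[!pos] - center) / tau
    out[!pos] <- area / (2 * tau) * exp(arg) * 2 * stats::pnorm(-sqrt(2) * u[!pos])
  }
  out
}

# exp(x^2) * erfc(x); pracma's implementation loses accuracy past ~26, switch
# to the asymptotic expansion there (error < 1e-15 at x = 25)
erfcx_ <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xl <- x[!small]
    s <- rep(1, length(xl))
    term <- rep(1, length(xl))
    for (k in 1:8) {
      term <- term * -(2 * k - 1) / (2 * xl^2)
      s <- s + term
    }
    out[!small] <- s / (xl * sqrt(pi))
  }
  out
}

#' Describe a ground-truth chromatographic peak
#'
#' A peak model records how a single analyte's peak responds to the three
#' method factors (methanol %, ammonium acetate concentration, flow rate) in
#' coded units. `retention` and `tau` may be a single number (no factor
#' dependence) or a length-4 vector `c(intercept, A, B, C)` of coded linear
#' coefficients, so retention shifts and tailing changes across a factorial
#' design can be expressed.
#'
#' @param analyte Analyte label.
#' @param retention Retention-time model (min): scalar or `c(b0, bA, bB, bC)`
#'   over coded factors in \[-1, 1\].
#' @param area Peak area (response units x min).
#' @param sigma Gaussian width (min).
#' @param tau Exponential tail constant (min): scalar or coded coefficients.
#' @return An object of class `peak_model`.
#' @seealso [simulate_chromatogram()], [uplc_truth()]
#' @export
peak_model <- function(analyte, retention, area = 5e4, sigma = 0.05, tau = 0) {
  stopifnot(length(analyte) == 1L, sigma > 0)
  if (!length(retention) %in% c(1L, 4L))
    stop("`retention` must be a scalar or c(intercept, A, B, C)", call. = FALSE)
  if (!length(tau) %in% c(1L, 4L))
    stop("`tau` must be a scalar or c(intercept, A, B, C)", call. = FALSE)
  structure(list(analyte = as.character(analyte),
                 retention = as.numeric(retention),
                 area = as.numeric(area), sigma = as.numeric(sigma),
                 tau = as.numeric(tau)),
            class = "peak_model")
}

# evaluate a coded linear coefficient vector at coded point x = c(A, B, C)
eval_coded <- function(coef, coded) {
  if (length(coef) == 1L) return(coef)
  coef[1L] + sum(coef[-1L] * coded)
}

# peak list -> data.frame of (analyte, center, area, sigma, tau) at one
# coded design point
evaluate_peaks <- function(peaks, coded = c(0, 0, 0)) {
  if (inherits(peaks, "peak_model")) peaks <- list(peaks)
  if (length(peaks) == 0L)
    return(data.frame(analyte = character(0), center = numeric(0),
                      area = numeric(0), sigma = numeric(0),
                      tau = numeric(0)))
  rows <- lapply(peaks, function(p) {
    tau <- eval_coded(p$tau, coded)
    if (tau < 0) tau <- 0
    data.frame(analyte = p$analyte,
               center = eval_coded(p$retention, coded),
               area = p$area, sigma = p$sigma, tau = tau,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a baseline-corrected chromatogram trace
#'
#' Sums the EMG signals of a set of peaks on a uniform time grid and adds
#' white Gaussian detector noise. Deterministic for a fixed seed; with
#' `noise_sd = 0` the trace is the exact sum of the peak signals.
#'
#' @param peaks A `peak_model`, a list of them, or a data.frame with columns
#'   `analyte`, `center`, `area`, `sigma`, `tau` (factor-independent form).
#' @param coded Coded factor point `c(A, B, C)` at which factor-dependent
#'   peaks are evaluated.
#' @param noise_sd White-noise standard deviation (response units).
#' @param seed RNG seed (integer) used only for the noise; ignored when
#'   `noise_sd = 0`.
#' @param duration Trace length (min). Must cover every retention time plus
#'   five widths (`sigma + tau`).
#' @param sampling_hz Detector sampling rate (points per second). Must give
#'   at least 20 points per `sigma`.
#' @return An object of class `chromatogram_trace`: list with `time` (min),
#'   `signal`, `noise_sd`, `seed`, `peaks` (the evaluated peak table).
#' @examples
#' tr <- simulate_chromatogram(peak_model("X", 6.0, sigma = 0.05), duration = 8)
#' range(tr$time); max(tr$signal)
#' @export
simulate_chromatogram <- function(peaks, coded = c(0, 0, 0), noise_sd = 0,
                                  seed = 1L, duration = 12, sampling_hz = 10) {
  tab <- if (is.data.frame(peaks)) peaks else evaluate_peaks(peaks, coded)
  dt <- 1 / (60 * sampling_hz)
  time <- seq(0, duration, by = dt)
  signal <- numeric(length(time))
  if (nrow(tab) > 0) {
    reach <- tab$center + 5 * (tab$sigma + tab$tau)
    if (any(reach > duration))
      stop("peak(s) not covered by `duration`: ",
           paste(tab$analyte[reach > duration], collapse = ", "), call. = FALSE)
    if (any(tab$sigma / 20 < dt))
      stop("sampling too coarse: need >= 20 points per sigma", call. = FALSE)
    for (i in seq_len(nrow(tab)))
      signal <- signal + emg_signal(time, tab$center[i], tab$area[i],
                                    tab$sigma[i], tab$tau[i])
  }
  if (noise_sd > 0)
    signal <- signal +
      with_seed(seed, stats::rnorm(length(time), sd = noise_sd))
  structure(list(time = time, signal = signal, noise_sd = noise_sd,
                 seed = if (noise_sd > 0) seed else NA_integer_, peaks = tab),
            class = "chromatogram_trace")
}

#' @export
as.data.frame.chromatogram_trace <- function(x, ...) {
  data.frame(time_min = x$time, signal = x$signal)
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf("<chromatogram_trace> %d points over %.2f min, %d peak(s), noise_sd = %g\n",
              length(x$time), max(x$time), nrow(x$peaks), x$noise_sd))
  invisible(x)
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
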