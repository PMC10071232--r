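# Study-level generators: factorial runs, calibration tables,
# standard-addition series, and day-indexed slope tables from known ground
# truth, so every downstream estimator is testable without an instrument.

#' Validate a set of factor settings
#'
#' @param methanol_pct Methanol volume fraction, % (v/v), in (0, 100).
#' @param aa_conc Ammonium acetate concentration (mM), non-negative.
#' @param flow_rate Flow rate (mL/min), positive.
#' @return Named list of class `factor_settings`.
#' @export
factor_settings <- function(methanol_pct, aa_conc, flow_rate) {
  if (methanol_pct <= 0 || methanol_pct >= 100)
    stop("`methanol_pct` must lie in (0, 100)", call. = FALSE)
  if (aa_conc < 0) stop("`aa_conc` must be non-negative", call. = FALSE)
  if (flow_rate <= 0) stop("`flow_rate` must be positive", call. = FALSE)
  structure(list(methanol_pct = methanol_pct, aa_conc = aa_conc,
                 flow_rate = flow_rate),
            class = "factor_settings")
}

#' Ground-truth separation model for the four-analyte study
#'
#' The default truth used by [simulate_doe_study()]: four EMG peaks whose
#' retention times shift linearly with the coded factors (all peaks move
#' earlier with more methanol), the first peak's tail constant shrinks with
#' buffer concentration (tailing improves at high ammonium acetate), and the
#' gap between the last two peaks narrows with buffer and flow (resolution
#' falls). The dead time is a declared simulator parameter.
#'
#' @param t_m Dead time (min), default 4.10.
#' @return List of class `uplc_truth`: `peaks` (list of [peak_model()]),
#'   `t_m`.
#' @export
uplc_truth <- function(t_m = 4.10) {
  stopifnot(t_m > 0)
  peaks <- list(
    peak_model("OSTP", retention = c(6.99, -0.40, 0.08, 0.15),
               area = 5.0e4, sigma = 0.040,
               tau = c(0.0850, 0, -0.0220, 0)),
    peak_model("DEX", retention = c(7.59, -0.40, 0.08, 0.15),
               area = 5.2e4, sigma = 0.045, tau = 0.010),
    peak_model("DAC", retention = c(8.19, -0.40, 0.08, 0.15),
               area = 4.8e4, sigma = 0.050, tau = 0.012),
    peak_model("REM", retention = c(8.61, -0.415, 0.00, 0.115),
               area = 5.5e4, sigma = 0.050, tau = 0.008))
  structure(list(peaks = peaks, t_m = t_m), class = "uplc_truth")
}

#' Simulate the eight-run factorial study
#'
#' Simulates one chromatogram per design run (peaks evaluated at the run's
#' coded factor levels), measures every trace with [detect_and_measure()],
#' and extracts the three optimization responses: the first peak's capacity
#' factor (`kprime_ostp`) and tailing factor (`tailing_ostp`), and the
#' resolution of the last peak pair (`rs_rem`). With the default truth and
#' no noise, all 24 responses land inside the ranges observed in the
#' reference study: k' in 0.48-0.91, T in 1.30-2.30, Rs in 1.39-2.83.
#'
#' @param truth A [uplc_truth()] model.
#' @param design An `ffd_design` over the three factors (all 8 runs).
#' @param noise_sd Trace noise SD (response units).
#' @param seed RNG seed (one stream per run, derived from it).
#' @param duration,sampling_hz Passed to [simulate_chromatogram()].
#' @return The design data.frame with response columns `kprime_ostp`,
#'   `tailing_ostp`, `rs_rem` appended (class `ffd_design` preserved).
#' @export
simulate_doe_study <- function(truth = uplc_truth(),
                               design = build_design(uplc_factor_levels()),
                               noise_sd = 0, seed = 1L,
                               duration = 12, sampling_hz = 10) {
  stopifnot(inherits(truth, "uplc_truth"))
  if (!inherits(design, "ffd_design") || nrow(design) != 8L ||
      anyDuplicated(paste(design$A, design$B, design$C)))
    stop("`design` must be a full 2^3 design (8 distinct sign runs)", call. = FALSE)
  resp <- t(vapply(seq_len(8L), function(i) {
    coded <- c(design$A[i], design$B[i], design$C[i])
    tr <- simulate_chromatogram(truth$peaks, coded = coded,
                                noise_sd = noise_sd, seed = seed + i,
                                duration = duration, sampling_hz = sampling_hz)
    pk <- detect_and_measure(tr, min_height_frac = 0.05)
    if (nrow(pk) != length(truth$peaks))
      stop("run ", i, ": expected ", length(truth$peaks), " peaks, found ",
           nrow(pk), call. = FALSE)
    rep_tab <- suitability_report(pk, truth$t_m)
    c(kprime_ostp = rep_tab$k_prime[1],
      tailing_ostp = rep_tab$tailing_T[1],
      rs_rem = rep_tab$Rs_to_previous[nrow(rep_tab)])
  }, numeric(3)))
  out <- cbind(design, as.data.frame(resp))
  attr(out, "levels") <- attr(design, "levels")
  attr(out, "t_m") <- truth$t_m
  class(out) <- c("ffd_design", "data.frame")
  out
}

#' Simulate a calibration table
#'
#' `response = intercept + slope x concentration + N(0, resid_sd)`,
#' deterministic per seed.
#'
#' @param slope,intercept True calibration line.
#' @param resid_sd Residual (homoscedastic) noise SD.
#' @param levels Concentration levels (>= 2 distinct, non-negative).
#' @param replicates Replicates per level.
#' @param seed RNG seed.
#' @return Data.frame with `level`, `concentration`, `replicate`, `response`.
#' @export
simulate_calibration <- function(slope, intercept = 0, resid_sd = 0,
                                 levels, replicates = 3, seed = 1L) {
  if (any(levels < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (length(unique(levels)) < 2L)
    stop("need at least 2 distinct concentration levels", call. = FALSE)
  out <- expand.grid(replicate = seq_len(replicates),
                     level = seq_along(levels), KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$level, out$replicate), c("level", "replicate")]
  out$concentration <- levels[out$level]
  mu <- intercept + slope * out$concentration
  out$response <- if (resid_sd > 0)
    mu + with_seed(seed, stats::rnorm(nrow(out), sd = resid_sd)) else mu
  rownames(out) <- NULL
  out[c("level", "concentration", "replicate", "response")]
}

#' Simulate a standard-addition series
#'
#' Generates the spiked-aliquot response table for either procedure. The
#' added axis is computed with the same bookkeeping used in the analysis
#' ([added_amount_instrumental()] / [added_concentration_classic()]), and
#' `response_i = slope x (sample_truth + added_i) + N(0, resid_sd)`.
#'
#' @param sample_truth True sample content: an amount (ng, instrumental) or
#'   concentration (w/v, classic).
#' @param slope True response slope (AUC per added-axis unit).
#' @param aliquots Aliquot series including 0: uL (instrumental) or mL
#'   (classic).
#' @param mode `"instrumental"` or `"classic"`.
#' @param std_conc Standard concentration (ng/mL for instrumental, w/v for
#'   classic; default 250).
#' @param flask_volume Flask volume (mL), classic mode only.
#' @param resid_sd Response noise SD.
#' @param seed RNG seed.
#' @param predicted_content Nominal content carried into the series
#'   (defaults to `sample_truth`).
#' @return An [addition_series()].
#' @export
simulate_standard_addition <- function(sample_truth, slope, aliquots,
                                       mode = c("instrumental", "classic"),
                                       std_conc = 250, flask_volume = 10,
                                       resid_sd = 0, seed = 1L,
                                       predicted_content = sample_truth) {
  mode <- match.arg(mode)
  if (any(aliquots < 0)) stop("aliquots must be non-negative", call. = FALSE)
  if (!any(aliquots == 0)) stop("aliquot series must include 0", call. = FALSE)
  added <- if (mode == "instrumental")
    added_amount_instrumental(std_conc, aliquots)
  else added_concentration_classic(std_conc, flask_volume, aliquots)
  mu <- slope * (sample_truth + added)
  response <- if (resid_sd > 0)
    mu + with_seed(seed, stats::rnorm(length(mu), sd = resid_sd)) else mu
  addition_series(added, response, mode = mode,
                  predicted_content = predicted_content)
}

#' Simulate day-indexed calibration slopes under linear drift
#'
#' `slope(day) = day0_slope (1 + drift_pct_per_day x day / 100) + N(0,
#' noise_sd)`.
#'
#' @param day0_slope Day-0 calibration slope, positive.
#' @param drift_pct_per_day Fractional slope change per day, in percent.
#' @param days Day grid including 0.
#' @param noise_sd Slope noise SD.
#' @param seed RNG seed.
#' @return Data.frame with `day` and `slope`.
#' @export
simulate_stability <- function(day0_slope, drift_pct_per_day, days,
                               noise_sd = 0, seed = 1L) {
  if (day0_slope <= 0) stop("`day0_slope` must be positive", call. = FALSE)
  if (!any(days == 0)) stop("`days` must include 0", call. = FALSE)
  mu <- day0_slope * (1 + drift_pct_per_day * days / 100)
  slope <- if (noise_sd > 0)
    mu + with_seed(seed, stats::rnorm(length(days), sd = noise_sd)) else mu
  data.frame(day = days, slope = slope)
}
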