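# Dosage-form arithmetic and end-to-end pipeline orchestration.

#' Define a dilution chain
#'
#' Records the volumetric preparation of an injected sample: an initial
#' amount dissolved in a flask, a sequence of aliquot-into-flask dilution
#' steps, and the injected volume.
#'
#' @param initial_amount_mg Drug amount dissolved at the head of the chain
#'   (mg).
#' @param initial_volume_ml First flask volume (mL).
#' @param steps List of `c(aliquot_mL, flask_mL)` dilution steps (aliquot
#'   must not exceed the flask volume); may be empty.
#' @param injected_ul Volume injected or drawn by the instrument (uL).
#' @return Object of class `dilution_chain`.
#' @examples
#' # hard-capsule content: 98.50 mg to 100 mL, 250 uL to 10 mL, 0.1 uL drawn
#' dilution_chain(98.50, 100, list(c(0.250, 10)), injected_ul = 0.1)
#' @export
dilution_chain <- function(initial_amount_mg, initial_volume_ml, steps = list(),
                           injected_ul) {
  stopifnot(initial_amount_mg > 0, initial_volume_ml > 0, injected_ul > 0)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (length(st) != 2L || st[1] <= 0 || st[2] <= 0)
      stop("step ", i, ": need c(aliquot_mL, flask_mL), both positive", call. = FALSE)
    if (st[1] > st[2])
      stop("step ", i, ": aliquot exceeds flask volume", call. = FALSE)
  }
  structure(list(initial_amount_mg = initial_amount_mg,
                 initial_volume_ml = initial_volume_ml,
                 steps = steps, injected_ul = injected_ul),
            class = "dilution_chain")
}

#' Nominal injected amount from a dilution chain
#'
#' Folds the chain: the concentration after each step is the previous
#' concentration times `aliquot / flask_volume`; the injected amount is the
#' final concentration times the injected volume, reported in nanograms.
#'
#' @param chain A [dilution_chain()].
#' @return Nominal injected amount (ng).
#' @examples
#' nominal_amount(dilution_chain(98.50, 100, list(c(0.250, 10)), 0.1)) # 2.4625 ng
#' @export
nominal_amount <- function(chain) {
  stopifnot(inherits(chain, "dilution_chain"))
  conc <- chain$initial_amount_mg / chain$initial_volume_ml # mg/mL
  for (st in chain$steps) conc <- conc * st[1] / st[2]
  conc * (chain$injected_ul / 1000) * 1e6 # mg -> ng
}

#' Found content as a percentage of nominal
#'
#' @param found Measured content (any unit).
#' @param nominal Nominal content, same unit, positive.
#' @return `100 found / nominal`.
#' @export
content_percent <- function(found, nominal) {
  if (any(nominal <= 0)) stop("`nominal` must be positive", call. = FALSE)
  100 * found / nominal
}

#' Which BP dosage-unit uniformity test applies
#'
#' Classifier for the British Pharmacopoeia rule: the weight-variation test
#' applies to dosage units containing 25 mg or more of drug substance that
#' makes up 25% or more of the unit by weight; otherwise the
#' content-uniformity test applies. (The acceptance-value statistic itself
#' is out of scope here.)
#'
#' @param drug_mg Drug substance per dosage unit (mg).
#' @param pct_by_weight Drug substance as % of the dosage-unit weight.
#' @return `"weight_variation"` or `"content_uniformity"`.
#' @export
bp_uniformity_test <- function(drug_mg, pct_by_weight) {
  stopifnot(drug_mg > 0, pct_by_weight > 0)
  if (drug_mg >= 25 && pct_by_weight >= 25) "weight_variation"
  else "content_uniformity"
}

#' Run the full simulated method-development pipeline
#'
#' End-to-end orchestration over synthetic data: simulate the factorial
#' study and estimate effects for each response, optimize the factor
#' settings by composite desirability, simulate and fit a calibration with
#' sensitivity limits, quantify a sample by instrumental standard addition,
#' estimate the solution storage period, and score the method's greenness.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param noise_sd Trace noise SD for the factorial study.
#' @param cal_resid_sd Calibration residual SD.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus per-stage CSV tables.
#' @return Nested list of class `pipeline_report` with components `doe`,
#'   `optimum`, `calibration`, `standard_addition`, `stability`,
#'   `greenness`, `seed`.
#' @export
run_pipeline <- function(seed = 1L, noise_sd = 0, cal_resid_sd = 2,
                         out_dir = NULL) {
  truth <- uplc_truth()
  study <- simulate_doe_study(truth, noise_sd = noise_sd, seed = seed)
  fits <- list(
    kprime_ostp = estimate_effects(study, "kprime_ostp"),
    tailing_ostp = estimate_effects(study, "tailing_ostp"),
    rs_rem = estimate_effects(study, "rs_rem"))
  optimum <- optimize_settings(fits, uplc_goals())

  cal_tab <- simulate_calibration(slope = 80.859, intercept = 0,
                                  resid_sd = cal_resid_sd,
                                  levels = c(10, 50, 100, 250, 400, 500),
                                  replicates = 3, seed = seed + 100L)
  cal_fit <- fit_line(cal_tab$concentration, cal_tab$response)
  limits <- lod_loq_sigma(cal_fit$sd_intercept, cal_fit$slope)

  chain <- dilution_chain(98.50, 100, list(c(0.250, 10)), injected_ul = 0.1)
  nominal <- nominal_amount(chain)
  series <- simulate_standard_addition(
    sample_truth = 0.92 * nominal, slope = 8000,
    aliquots = c(0, 2, 3, 4, 5, 6), mode = "instrumental",
    resid_sd = 10 * cal_resid_sd, seed = seed + 200L,
    predicted_content = nominal)
  stdadd <- analyze_series(series)

  slopes <- simulate_stability(day0_slope = cal_fit$slope,
                               drift_pct_per_day = 0.12,
                               days = c(0, 7, 8),
                               noise_sd = 0.02 * cal_resid_sd,
                               seed = seed + 300L)
  stab <- storage_period(to_ratio_series(slopes$day, slopes$slope))

  eco <- eco_scale(uplc_method_inventory())

  report <- structure(list(
    doe = list(study = study,
               effects = lapply(fits, function(f) f$effects)),
    optimum = optimum,
    calibration = list(fit = cal_fit, limits = limits, table = cal_tab),
    standard_addition = stdadd,
    stability = stab,
    greenness = eco,
    seed = seed), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(study), file.path(out_dir, "doe_runs.csv"),
                     row.names = FALSE)
    utils::write.csv(cal_tab, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes, file.path(out_dir, "stability_slopes.csv"),
                     row.names = FALSE)
    json <- list(
      optimum = c(as.list(optimum$settings), composite_D = optimum$composite_D),
      effects = lapply(fits, function(f) as.list(f$effects)),
      calibration = list(slope = cal_fit$slope, intercept = cal_fit$intercept,
                         r_squared = cal_fit$r_squared,
                         lod = limits$lod, loq = limits$loq),
      standard_addition = list(content = stdadd$content,
                               content_pct = stdadd$content_pct),
      stability_days = stab$days,
      eco_score = eco$score,
      seed = seed)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  optimum: %s (D = %.3f)\n",
              paste(sprintf("%s = %.4g", names(x$optimum$settings),
                            unlist(x$optimum$settings)), collapse = ", "),
              x$optimum$composite_D))
  cat(sprintf("  calibration: slope %.3f, R^2 %.6f, LOD %.3f, LOQ %.3f\n",
              x$calibration$fit$slope, x$calibration$fit$r_squared,
              x$calibration$limits$lod, x$calibration$limits$loq))
  cat(sprintf("  standard addition: content %.3f ng (%.2f%% of nominal)\n",
              x$standard_addition$content, x$standard_addition$content_pct))
  cat(sprintf("  stability: %.2f days; eco score %g\n",
              x$stability$days, x$greenness$score))
  invisible(x)
}
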