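# Classic and instrumental standard-addition quantitation.

#' Added concentration in the classic standard-addition procedure
#'
#' Spike bookkeeping for manual flask preparation: the final added
#' concentration is `std_conc / flask_volume x aliquot` (same w/v units as
#' `std_conc`).
#'
#' @param std_conc Standard solution concentration (w/v).
#' @param flask_volume Volumetric-flask volume (mL), positive.
#' @param aliquot Aliquot(s) of standard transferred (mL), non-negative and
#'   at most `flask_volume`.
#' @return Added concentration(s), vectorised over `aliquot`.
#' @examples
#' added_concentration_classic(250, 10, c(0, 0.01, 0.1, 0.25, 0.5))
#' @export
added_concentration_classic <- function(std_conc, flask_volume, aliquot) {
  if (flask_volume <= 0) stop("`flask_volume` must be positive", call. = FALSE)
  if (any(aliquot < 0)) stop("aliquots must be non-negative", call. = FALSE)
  if (any(aliquot > flask_volume))
    stop("aliquot exceeds flask volume", call. = FALSE)
  std_conc / flask_volume * aliquot
}

#' Added amount in the instrumental standard-addition procedure
#'
#' The autosampler mixes microlitre aliquots of the standard directly with
#' the sample, so the spike is an amount: `std_conc / 1000 x aliquot_uL`
#' nanograms for `std_conc` in ng/mL.
#'
#' @param std_conc Standard concentration (ng/mL).
#' @param aliquot Aliquot(s) drawn by the instrument (uL), non-negative.
#' @return Added amount(s) in ng, vectorised over `aliquot`.
#' @examples
#' added_amount_instrumental(250, c(0, 2, 3, 4, 5, 6)) # 0 .. 1.5 ng
#' @export
added_amount_instrumental <- function(std_conc, aliquot) {
  if (any(aliquot < 0)) stop("aliquots must be non-negative", call. = FALSE)
  std_conc / 1000 * aliquot
}

#' Sample content from a standard-addition line
#'
#' Extrapolation of the addition line to zero response:
#' `content = -(0 - intercept) / slope = intercept / slope`, in the units of
#' the added axis. A non-positive slope signals a failed series.
#'
#' @param fit A [fit_line()] result for response versus added.
#' @return Content in added-axis units.
#' @examples
#' f <- list(slope = 7985.943, intercept = 17832.714)
#' class(f) <- "line_fit"
#' content_from_fit(f) # 2.233 ng
#' @export
content_from_fit <- function(fit) {
  if (!is.finite(fit$slope) || fit$slope <= 0)
    stop("addition-series slope must be positive", call. = FALSE)
  fit$intercept / fit$slope
}

#' Assemble a standard-addition series
#'
#' @param added Added concentrations (classic, w/v) or amounts
#'   (instrumental, ng); must include 0.
#' @param response Detector responses (AUC), same length.
#' @param mode `"instrumental"` or `"classic"`.
#' @param predicted_content Nominal content from the dilution chain, in
#'   added-axis units (used for the content percentage); optional.
#' @param analyte Analyte label.
#' @return Object of class `addition_series`.
#' @export
addition_series <- function(added, response, mode = c("instrumental", "classic"),
                            predicted_content = NULL, analyte = "analyte") {
  mode <- match.arg(mode)
  if (length(added) != length(response)) stop("length mismatch", call. = FALSE)
  if (any(added < 0)) stop("added values must be non-negative", call. = FALSE)
  if (!any(added == 0)) stop("series must include added = 0", call. = FALSE)
  structure(list(added = added, response = response, mode = mode,
                 predicted_content = predicted_content, analyte = analyte),
            class = "addition_series")
}

#' Analyse a standard-addition series
#'
#' Fits response against added level, extrapolates the content, and reports
#' the content as a percentage of the nominal (dilution-chain) content plus
#' per-level recoveries. The per-level recovery convention is
#' `100 ((response_i - response_0) / slope) / added_i` for each non-zero
#' addition, with `response_0` the fitted response at zero added.
#'
#' @param series An [addition_series()].
#' @return List of class `addition_result`: `fit` (a `line_fit`), `content`,
#'   `content_pct` (`NA` without a `predicted_content`), `recovery`
#'   (data.frame `added`/`recovery_pct`), `mode`, `analyte`.
#' @export
analyze_series <- function(series) {
  stopifnot(inherits(series, "addition_series"))
  if (length(series$added) < 3L)
    stop("need at least 3 addition levels", call. = FALSE)
  fit <- fit_line(series$added, series$response)
  content <- content_from_fit(fit)
  content_pct <- if (is.null(series$predicted_content)) NA_real_
                 else 100 * content / series$predicted_content
  nz <- series$added > 0
  r0 <- series$response[series$added == 0][1]
  recovery <- data.frame(
    added = series$added[nz],
    recovery_pct = 100 * ((series$response[nz] - r0) / fit$slope) /
      series$added[nz])
  structure(list(fit = fit, content = content, content_pct = content_pct,
                 recovery = recovery, mode = series$mode,
                 analyte = series$analyte),
            class = "addition_result")
}

#' @export
print.addition_result <- function(x, ...) {
  cat(sprintf("<addition_result> %s (%s): content %.4g", x$analyte, x$mode,
              x$content))
  if (!is.na(x$content_pct)) cat(sprintf(" (%.2f%% of nominal)", x$content_pct))
  cat(sprintf(", slope %.6g, intercept %.6g, R^2 %.5f\n",
              x$fit$slope, x$fit$intercept, x$fit$r_squared))
  invisible(x)
}
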