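# Slope-ratio stability of standard solutions: day-indexed calibration
# slopes are converted to percentages of the day-0 slope, regressed against
# day, and the regression is solved for the day the acceptance bound is hit.

#' Convert day-indexed calibration slopes to a ratio series
#'
#' `Y_i = 100 S_i / S_0`, anchored at 100 on day 0.
#'
#' @param days Storage days, non-negative, strictly increasing, including 0.
#' @param slopes Calibration slope on each day; the day-0 slope must be
#'   positive. A negative slope on any later day is flagged with a warning
#'   (it indicates a failed calibration, not mere degradation).
#' @param analyte,range_id Optional labels.
#' @return Object of class `stability_series`: `days`, `slopes`,
#'   `ratio_pct`, labels.
#' @export
to_ratio_series <- function(days, slopes, analyte = NULL, range_id = NULL) {
  if (length(days) != length(slopes)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE) || any(days < 0))
    stop("`days` must be non-negative and strictly increasing", call. = FALSE)
  if (days[1] != 0) stop("day 0 is required", call. = FALSE)
  if (slopes[1] <= 0) stop("day-0 slope must be positive", call. = FALSE)
  if (any(slopes < 0))
    warning("negative slope in series: check the day-",
            paste(days[slopes < 0], collapse = ","), " calibration", call. = FALSE)
  structure(list(days = days, slopes = slopes,
                 ratio_pct = 100 * slopes / slopes[1],
                 analyte = analyte, range_id = range_id),
            class = "stability_series")
}

#' Admissible storage period from a slope-ratio series
#'
#' Regresses the slope percentages on storage day (ordinary least squares)
#' and solves for the day the fitted line reaches the acceptance bound:
#' `(threshold - intercept) / slope` for upward drift. For downward drift
#' the symmetric lower bound `200 - threshold` (e.g. 98% for a 102%
#' threshold) is used. A zero fitted slope means no detectable drift
#' (`Inf`, flagged); a negative solution is flagged as not estimable under
#' linear drift (`NA`).
#'
#' @param series A [to_ratio_series()] result (needs >= 3 days).
#' @param threshold_pct Acceptance bound on the slope percentage
#'   (default 102).
#' @return List of class `stability_estimate`: `days` (the storage period),
#'   `fit` (`line_fit` of Y on X), `threshold_pct`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `estimable`.
#' @examples
#' s <- to_ratio_series(c(0, 7, 8), c(80.859, 80.993, 82.002))
#' storage_period(s)$days
#' @export
storage_period <- function(series, threshold_pct = 102) {
  stopifnot(inherits(series, "stability_series"))
  if (length(series$days) < 3L) stop("need at least 3 days", call. = FALSE)
  fit <- fit_line(series$days, series$ratio_pct)
  # a fitted slope at rounding-noise level means no detectable drift
  if (abs(fit$slope) < 1e-8) {
    return(structure(list(days = Inf, fit = fit, threshold_pct = threshold_pct,
                          direction = "none", estimable = FALSE),
                     class = "stability_estimate"))
  }
  if (fit$slope > 0) {
    days <- (threshold_pct - fit$intercept) / fit$slope
    direction <- "up"
  } else {
    days <- ((200 - threshold_pct) - fit$intercept) / fit$slope
    direction <- "down"
  }
  estimable <- is.finite(days) && days > 0
  structure(list(days = if (estimable) days else NA_real_, fit = fit,
                 threshold_pct = threshold_pct, direction = direction,
                 estimable = estimable),
            class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  if (!x$estimable)
    cat(sprintf("<stability_estimate> not estimable under linear drift (%s)\n",
                x$direction))
  else
    cat(sprintf("<stability_estimate> %.3f days to the %g%% bound (drift %s, %.4g %%/day)\n",
                x$days, x$threshold_pct, x$direction, x$fit$slope))
  invisible(x)
}

#' Pool per-range storage periods
#'
#' Arithmetic mean of the storage periods obtained for the linearity ranges
#' of one analyte.
#'
#' @param periods Numeric vector of per-range storage periods (days), or a
#'   list of `stability_estimate` objects.
#' @return Mean storage period (days).
#' @examples
#' pooled_stability(c(17.249, 18.717)) # 17.983
#' @export
pooled_stability <- function(periods) {
  if (is.list(periods))
    periods <- vapply(periods, function(p) p$days, numeric(1))
  if (length(periods) == 0L) stop("no periods to pool", call. = FALSE)
  mean(periods)
}
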