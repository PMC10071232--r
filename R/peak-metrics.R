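# Peak detection, geometry measurement, and system-suitability statistics.

#' Detect peaks and measure their geometry
#'
#' Finds strict local maxima above a height threshold on a uniformly sampled,
#' baseline-corrected trace, then measures each peak's retention time (apex
#' refined by a parabola through the three samples around the maximum),
#' height, area (trapezoidal, between the flanking valleys), and widths at
#' 50% and 5% of the apex height. Fractional-height crossings are located
#' by linear interpolation between the bracketing samples, searching outward
#' from the apex but never past the valley separating the peak from its
#' neighbour; a crossing that is not reached within the peak's support is
#' returned as `NA`. Shoulder maxima whose separating valley stays above
#' half the lower apex are merged into the taller peak.
#'
#' @param trace A `chromatogram_trace` (or list/data.frame with `time` and
#'   `signal`); the grid must be uniform and the baseline zero.
#' @param min_height_frac Detection threshold as a fraction of the global
#'   signal maximum, in (0, 1).
#' @return A data.frame of class `peak_geometry` ordered by retention time,
#'   with columns `peak`, `t_R`, `height`, `area`, `W50`, `W5`, `f5`,
#'   `W_base` (tangent width, `1.699 * W50`). Empty (zero rows) when nothing
#'   exceeds the threshold.
#' @export
detect_and_measure <- function(trace, min_height_frac = 0.05) {
  time <- trace$time
  signal <- trace$signal
  if (length(time) < 3L) stop("trace needs at least 3 points", call. = FALSE)
  if (min_height_frac <= 0 || min_height_frac >= 1)
    stop("`min_height_frac` must be in (0, 1)", call. = FALSE)
  dt <- diff(time)
  if (diff(range(dt)) > 1e-8 * mean(dt))
    stop("time grid must be uniform", call. = FALSE)
  dt <- mean(dt)
  n <- length(signal)
  thr <- min_height_frac * max(signal)

  # strict local maxima above threshold
  idx <- which(signal[2:(n - 1)] > signal[1:(n - 2)] &
               signal[2:(n - 1)] >= signal[3:n] &
               signal[2:(n - 1)] >= thr) + 1L
  if (length(idx) == 0L)
    return(empty_geometry())

  # merge shoulders: accept tallest first; a candidate is a separate peak only
  # if the signal between it and every accepted apex dips below half the
  # smaller of the two apex heights
  keep <- integer(0)
  for (i in idx[order(-signal[idx])]) {
    sep <- TRUE
    for (j in keep) {
      rng <- if (i < j) i:j else j:i
      if (min(signal[rng]) > 0.5 * min(signal[i], signal[j])) { sep <- FALSE; break }
    }
    if (sep) keep <- c(keep, i)
  }
  keep <- sort(keep)

  # support boundaries: minimum between consecutive apexes, trace ends outside
  bounds <- vapply(seq_along(keep)[-length(keep)], function(k) {
    rng <- keep[k]:keep[k + 1L]
    rng[which.min(signal[rng])]
  }, integer(1))
  lo <- c(1L, bounds)
  hi <- c(bounds, n)

  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    # parabolic apex refinement
    if (i > 1L && i < n) {
      y1 <- signal[i - 1L]; y2 <- signal[i]; y3 <- signal[i + 1L]
      den <- y1 - 2 * y2 + y3
      delta <- if (den < 0) 0.5 * (y1 - y3) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      t_R <- time[i] + delta * dt
      height <- y2 - 0.25 * (y1 - y3) * delta
    } else {
      t_R <- time[i]; height <- signal[i]
    }
    l50 <- cross_left(time, signal, i, lo[k], 0.5 * height)
    r50 <- cross_right(time, signal, i, hi[k], 0.5 * height)
    l5  <- cross_left(time, signal, i, lo[k], 0.05 * height)
    r5  <- cross_right(time, signal, i, hi[k], 0.05 * height)
    seg <- lo[k]:hi[k]
    area <- sum((signal[seg][-1] + signal[seg][-length(seg)]) / 2) * dt
    W50 <- r50 - l50
    data.frame(peak = k, t_R = t_R, height = height, area = area,
               W50 = W50, W5 = r5 - l5, f5 = t_R - l5, W_base = 1.699 * W50)
  })
  out <- do.call(rbind, rows)
  out$peak <- seq_len(nrow(out))
  class(out) <- c("peak_geometry", "data.frame")
  out
}

empty_geometry <- function() {
  out <- data.frame(peak = integer(0), t_R = numeric(0), height = numeric(0),
                    area = numeric(0), W50 = numeric(0), W5 = numeric(0),
                    f5 = numeric(0), W_base = numeric(0))
  class(out) <- c("peak_geometry", "data.frame")
  out
}

# first crossing of `level` scanning left from apex i, floor at index `lo`;
# linear interpolation between the bracketing samples (outermost crossing wins
# on plateaus because the scan continues until the signal is at/below level)
cross_left <- function(time, signal, i, lo, level) {
  j <- i
  while (j > lo && signal[j] > level) j <- j - 1L
  if (signal[j] > level) return(NA_real_)
  if (j == i) return(time[j])
  t0 <- time[j]; t1 <- time[j + 1L]; y0 <- signal[j]; y1 <- signal[j + 1L]
  if (y1 == y0) t1 else t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

cross_right <- function(time, signal, i, hi, level) {
  j <- i
  while (j < hi && signal[j] > level) j <- j + 1L
  if (signal[j] > level) return(NA_real_)
  if (j == i) return(time[j])
  t0 <- time[j - 1L]; t1 <- time[j]; y0 <- signal[j - 1L]; y1 <- signal[j]
  if (y1 == y0) t0 else t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Capacity (retention) factor
#'
#' `k' = (t_R - t_m) / t_m`, the analyte's retention relative to the
#' unretained solvent-front marker. The pharmacopoeial acceptance window is
#' 0.5 to 10.
#'
#' @param t_R Analyte retention time (min).
#' @param t_m Dead time: solvent-front retention time (min), positive.
#' @return Dimensionless capacity factor (vectorised over `t_R`).
#' @export
capacity_factor <- function(t_R, t_m) {
  if (!is.numeric(t_m) || length(t_m) != 1L || !is.finite(t_m) || t_m <= 0)
    stop("`t_m` must be a single positive number", call. = FALSE)
  if (any(t_R < t_m))
    warning("t_R < t_m: negative capacity factor returned", call. = FALSE)
  (t_R - t_m) / t_m
}

#' Resolution between two consecutive peaks
#'
#' `Rs = 2 (t_R2 - t_R1) / (W_base1 + W_base2)` using tangent baseline
#' widths; values of 1.5 or more indicate baseline separation.
#'
#' @param peak_n,peak_n1 One-row `peak_geometry` entries (or lists with
#'   `t_R` and `W_base`), with `peak_n1` eluting after `peak_n`.
#' @return Dimensionless resolution.
#' @export
resolution <- function(peak_n, peak_n1) {
  t1 <- peak_n$t_R; t2 <- peak_n1$t_R
  w1 <- peak_n$W_base; w2 <- peak_n1$W_base
  if (t2 < t1) stop("`peak_n1` must elute after `peak_n`", call. = FALSE)
  if (any(c(w1, w2) <= 0) || any(!is.finite(c(w1, w2))))
    stop("peak widths must be positive", call. = FALSE)
  2 * (t2 - t1) / (w1 + w2)
}

#' Tailing (symmetry) factor
#'
#' `T = W5 / (2 f5)` from the full width and the leading-edge half-width at
#' 5% of peak height; 1 for a symmetric peak, above 1 for a tailed one.
#' The usual acceptance range is 0.8 to 2.
#'
#' @param W5 Full peak width at 5% height (min).
#' @param f5 Distance from the leading-edge 5% crossing to the apex (min).
#' @return Dimensionless tailing factor.
#' @export
tailing_factor <- function(W5, f5) {
  if (any(f5 <= 0)) stop("`f5` must be positive", call. = FALSE)
  if (any(W5 <= 0)) stop("`W5` must be positive", call. = FALSE)
  W5 / (2 * f5)
}

#' Number of theoretical plates
#'
#' Column efficiency under the half-height convention,
#' `N = 5.54 (t_R / W50)^2`.
#'
#' @param t_R Retention time (min).
#' @param W50 Full width at half height (min).
#' @return Plate count (dimensionless).
#' @export
plate_number <- function(t_R, W50) {
  if (any(W50 <= 0)) stop("`W50` must be positive", call. = FALSE)
  5.54 * (t_R / W50)^2
}

#' System-suitability report for an ordered peak set
#'
#' Computes, per peak, the capacity factor, tailing factor, plate number,
#' and the resolution against the preceding peak (none for the first).
#'
#' @param peaks A `peak_geometry` data.frame ordered by `t_R`
#'   (from [detect_and_measure()]).
#' @param t_m Dead time (min).
#' @return Data.frame with columns `peak`, `t_R`, `k_prime`,
#'   `Rs_to_previous`, `tailing_T`, `plates_N`, and attribute `t_m`.
#' @export
suitability_report <- function(peaks, t_m) {
  if (nrow(peaks) == 0L) stop("no peaks to report on", call. = FALSE)
  if (is.unsorted(peaks$t_R)) stop("peaks must be ordered by t_R", call. = FALSE)
  rs <- c(NA_real_,
          if (nrow(peaks) > 1L)
            vapply(2:nrow(peaks), function(i)
              resolution(peaks[i - 1L, ], peaks[i, ]), numeric(1)))
  out <- data.frame(peak = peaks$peak, t_R = peaks$t_R,
                    k_prime = capacity_factor(peaks$t_R, t_m),
                    Rs_to_previous = rs,
                    tailing_T = tailing_factor(peaks$W5, peaks$f5),
                    plates_N = plate_number(peaks$t_R, peaks$W50))
  attr(out, "t_m") <- t_m
  out
}
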