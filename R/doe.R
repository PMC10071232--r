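# Two-level full factorial design: construction, effect estimation, Lenth
# significance, coded/uncoded coefficient conversion, and prediction.

FACTORS <- c("A", "B", "C")
TERMS <- c("A", "B", "C", "AB", "AC", "BC", "ABC")

#' Build a 2^3 full factorial design
#'
#' Enumerates all eight sign combinations of three two-level factors in
#' standard (Yates) order: A fastest, then B, then C.
#'
#' @param levels Named list giving `c(low, high)` for each of the three
#'   factors, e.g. `list(methanol_pct = c(73, 77), aa_conc = c(5, 20),
#'   flow_rate = c(0.030, 0.070))`. Names supply the natural-unit column
#'   names; order maps to coded factors A, B, C.
#' @return A data.frame of class `ffd_design` with columns `run_id`, coded
#'   `A`, `B`, `C` (-1/+1), and the three natural-unit factor columns.
#'   The level map is kept in `attr(, "levels")`.
#' @examples
#' build_design(uplc_factor_levels())
#' @export
build_design <- function(levels = uplc_factor_levels()) {
  if (length(levels) != 3L || is.null(names(levels)))
    stop("`levels` must be a named list of three c(low, high) pairs", call. = FALSE)
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) != 2L || !all(is.finite(lv)) || lv[1] >= lv[2])
      stop("levels for ", nm, " must satisfy low < high", call. = FALSE)
  }
  coded <- expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1),
                       KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(run_id = seq_len(8L), coded)
  for (k in 1:3) {
    lv <- levels[[k]]
    out[[names(levels)[k]]] <- ifelse(coded[[k]] > 0, lv[2], lv[1])
  }
  attr(out, "levels") <- levels
  class(out) <- c("ffd_design", "data.frame")
  out
}

#' Factor levels of the reference UPLC separation
#'
#' The two-level settings studied for the quaternary antiviral separation:
#' methanol 73.0/77.0 % (v/v), ammonium acetate 5.0/20.0 mM, flow rate
#' 0.030/0.070 mL/min.
#'
#' @return Named list of `c(low, high)` pairs suitable for [build_design()].
#' @export
uplc_factor_levels <- function() {
  list(methanol_pct = c(73.0, 77.0),
       aa_conc = c(5.0, 20.0),
       flow_rate = c(0.030, 0.070))
}

# 8 x 8 signed model matrix (intercept + 7 terms) from coded columns
model_matrix_coded <- function(A, B, C) {
  cbind(`(Intercept)` = 1, A = A, B = B, C = C,
        AB = A * B, AC = A * C, BC = B * C, ABC = A * B * C)
}

#' Estimate factorial effects and model coefficients
#'
#' For a saturated 2^3 design, the effect of a term is the mean response at
#' its +1 contrast minus the mean at -1 (interaction contrasts are products
#' of factor columns). Coded coefficients are half the effects plus the grand
#' mean; uncoded (natural-unit) coefficients are obtained by exact linear
#' solve on the natural-unit polynomial basis, so both forms predict
#' identically everywhere.
#'
#' @param design An `ffd_design` (all 8 runs exactly once).
#' @param response Numeric vector of 8 responses in run order, or the name of
#'   a column of `design`.
#' @return Object of class `ffd_fit`: list with `effects` (7 terms),
#'   `coef_coded`, `coef_uncoded`, `levels`, `response_name`, `design`.
#' @export
estimate_effects <- function(design, response) {
  if (!inherits(design, "ffd_design")) stop("`design` must come from build_design()", call. = FALSE)
  response_name <- "response"
  if (is.character(response) && length(response) == 1L) {
    response_name <- response
    if (is.null(design[[response]])) stop("no column `", response, "` in design", call. = FALSE)
    response <- design[[response]]
  }
  if (length(response) != 8L || !all(is.finite(response)))
    stop("`response` must be 8 finite values", call. = FALSE)
  key <- paste(design$A, design$B, design$C)
  if (nrow(design) != 8L || anyDuplicated(key))
    stop("design must contain each of the 8 sign combinations exactly once", call. = FALSE)
  X <- model_matrix_coded(design$A, design$B, design$C)
  # orthogonal columns: contrast means are t(X) y / 4, intercept = mean
  est <- drop(crossprod(X, response)) / 8
  coef_coded <- est
  effects <- 2 * est[TERMS]
  levels <- attr(design, "levels")
  coef_uncoded <- to_uncoded(coef_coded, levels)
  structure(list(effects = effects, coef_coded = coef_coded,
                 coef_uncoded = coef_uncoded, levels = levels,
                 response_name = response_name,
                 design = design, response = response),
            class = "ffd_fit")
}

#' @export
print.ffd_fit <- function(x, ...) {
  cat(sprintf("2^3 full factorial fit for `%s`\n", x$response_name))
  print(round(rbind(effect = x$effects, coef_coded = x$coef_coded[TERMS]), 5))
  invisible(x)
}

#' Lenth's pseudo-standard-error significance test
#'
#' Significance screening for a saturated, unreplicated two-level design:
#' `s0 = 1.5 median|effect|`, the pseudo standard error (PSE) is
#' `1.5 median{|effect| : |effect| < 2.5 s0}`, standardized effects are
#' `effect / PSE`, and the margin of error is `t(1 - alpha/2, df = m/3) x
#' PSE` with `m` the number of effects. A term is significant when its
#' absolute effect exceeds the margin of error.
#'
#' @param effects Named numeric vector of effects (e.g. `fit$effects`), or an
#'   `ffd_fit`.
#' @param alpha Significance level (default 0.05).
#' @return List with `pse`, `standardized`, `margin_of_error`, `significant`
#'   (named logical), and `alpha`.
#' @export
lenth_significance <- function(effects, alpha = 0.05) {
  if (inherits(effects, "ffd_fit")) effects <- effects$effects
  m <- length(effects)
  if (m < 3L) stop("need at least 3 effects", call. = FALSE)
  ae <- abs(effects)
  s0 <- 1.5 * stats::median(ae)
  if (s0 == 0)
    stop("median absolute effect is zero: PSE undefined", call. = FALSE)
  trimmed <- ae[ae < 2.5 * s0]
  pse <- 1.5 * stats::median(trimmed)
  if (!is.finite(pse) || pse == 0)
    stop("PSE degenerate after trimming", call. = FALSE)
  me <- stats::qt(1 - alpha / 2, df = m / 3) * pse
  list(pse = pse, standardized = effects / pse, margin_of_error = me,
       significant = ae > me, alpha = alpha)
}

#' Convert coded coefficients to natural (uncoded) units
#'
#' Substitutes `x_j = (u_j - center_j) / halfrange_j` into the coded
#' polynomial. Implemented as an exact linear solve: the uncoded coefficients
#' are those of the natural-unit polynomial basis (1, uA, uB, uC, uAuB, ...)
#' that reproduce the coded model's predictions at the 8 design corners, so
#' the two forms agree at every point.
#'
#' @param coef_coded Named length-8 vector: `(Intercept)`, `A`, `B`, `C`,
#'   `AB`, `AC`, `BC`, `ABC`.
#' @param levels Level map as in [build_design()].
#' @return Named length-8 vector of natural-unit polynomial coefficients.
#' @export
to_uncoded <- function(coef_coded, levels) {
  coded <- expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1))
  Xc <- model_matrix_coded(coded$A, coded$B, coded$C)
  yhat <- drop(Xc %*% coef_coded)
  nat <- mapply(function(lv, x) ifelse(x > 0, lv[2], lv[1]), levels, coded)
  Xu <- model_matrix_coded(nat[, 1], nat[, 2], nat[, 3])
  beta <- solve(Xu, yhat)
  names(beta) <- colnames(Xu)
  beta
}

#' Predict a response from a factorial fit
#'
#' Evaluates the natural-unit prediction polynomial of an `ffd_fit` at the
#' supplied factor settings. These polynomials are the prediction equations
#' used for robustness and system-suitability forecasting.
#'
#' @param object An `ffd_fit`.
#' @param newdata Data.frame (or named list) with the three natural-unit
#'   factor columns used in the design.
#' @param warn_extrapolation Warn when a setting lies outside the design
#'   region (default TRUE).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.ffd_fit <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  nm <- names(object$levels)
  newdata <- as.data.frame(as.list(newdata))
  if (!all(nm %in% names(newdata)))
    stop("`newdata` must contain columns ", paste(nm, collapse = ", "), call. = FALSE)
  u <- as.matrix(newdata[nm])
  if (warn_extrapolation) {
    for (k in 1:3) {
      lv <- object$levels[[k]]
      if (any(u[, k] < lv[1] - 1e-9 | u[, k] > lv[2] + 1e-9)) {
        warning("prediction outside the design region for ", nm[k], call. = FALSE)
        break
      }
    }
  }
  Xu <- model_matrix_coded(u[, 1], u[, 2], u[, 3])
  unname(drop(Xu %*% object$coef_uncoded))
}

#' Main-effect and interaction plot data
#'
#' Mean responses behind a main-effect plot (two level means for one factor)
#' or an interaction plot (the four cell means of a factor pair).
#'
#' @param design An `ffd_design`.
#' @param response 8 responses in run order, or a design column name.
#' @param term One of `"A"`, `"B"`, `"C"` or a pair such as `"AB"` (first
#'   letter on the x axis, second the stratifying factor).
#' @return Data.frame of level means; for pairs, one row per cell.
#' @export
level_means <- function(design, response, term) {
  if (!inherits(design, "ffd_design")) stop("`design` must come from build_design()", call. = FALSE)
  if (is.character(response) && length(response) == 1L) response <- design[[response]]
  ltrs <- strsplit(term, "")[[1]]
  if (!term %in% c(FACTORS, "AB", "AC", "BC", "BA", "CA", "CB"))
    stop("unknown term `", term, "`", call. = FALSE)
  if (length(ltrs) == 1L) {
    agg <- stats::aggregate(response, list(level = design[[term]]), mean)
    names(agg)[2] <- "mean_response"
    agg
  } else {
    agg <- stats::aggregate(
      response, list(level = design[[ltrs[1]]], by = design[[ltrs[2]]]), mean)
    names(agg) <- c(paste0("level_", ltrs[1]), paste0("level_", ltrs[2]),
                    "mean_response")
    agg
  }
}
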