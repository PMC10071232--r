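# Derringer-Suich desirability functions and the response optimizer.

#' Define a response goal for desirability optimization
#'
#' @param response Response name (must match a name in the fits list passed
#'   to [optimize_settings()]).
#' @param kind `"maximize"`, `"minimize"`, or `"target"`.
#' @param low,target,high Goal geometry: maximize needs `low < target`
#'   (desirability ramps from 0 at `low` to 1 at `target`); minimize needs
#'   `target < high`; target needs `low < target < high` (two-sided ramp
#'   peaking at `target`).
#' @param importance Weight in \[0.1, 10\] (default 1); it is the ramp
#'   exponent and the geometric-mean weight.
#' @return Object of class `response_goal`.
#' @export
response_goal <- function(response, kind = c("maximize", "minimize", "target"),
                          low = NA, target = NA, high = NA, importance = 1) {
  kind <- match.arg(kind)
  if (importance < 0.1 || importance > 10)
    stop("`importance` must lie in [0.1, 10]", call. = FALSE)
  ok <- switch(kind,
    maximize = is.finite(low) && is.finite(target) && low < target,
    minimize = is.finite(target) && is.finite(high) && target < high,
    target = is.finite(low) && is.finite(target) && is.finite(high) &&
      low < target && target < high)
  if (!ok) stop("invalid goal geometry for kind = ", kind, call. = FALSE)
  structure(list(response = response, kind = kind, low = low, target = target,
                 high = high, importance = importance),
            class = "response_goal")
}

#' Individual desirability of a predicted response
#'
#' Derringer-style power ramps: for a maximize goal, `d = 0` below `low`,
#' `((y - low)/(target - low))^importance` between, and 1 at or above
#' `target`; minimize is mirrored; a target goal rises to 1 at `target` and
#' falls back to 0 at the outer bounds.
#'
#' @param y Predicted response value(s).
#' @param goal A [response_goal()].
#' @return Desirability in \[0, 1\], vectorised over `y`.
#' @export
individual_desirability <- function(y, goal) {
  stopifnot(inherits(goal, "response_goal"))
  w <- goal$importance
  d <- switch(goal$kind,
    maximize = pmin(1, pmax(0, (y - goal$low) / (goal$target - goal$low)))^w,
    minimize = pmin(1, pmax(0, (goal$high - y) / (goal$high - goal$target)))^w,
    target = {
      up <- pmin(1, pmax(0, (y - goal$low) / (goal$target - goal$low)))
      dn <- pmin(1, pmax(0, (goal$high - y) / (goal$high - goal$target)))
      pmin(up, dn)^w
    })
  d
}

#' Composite (overall) desirability
#'
#' Importance-weighted geometric mean
#' `D = (prod d_i^{w_i})^{1 / sum w_i}`; zero whenever any component is zero.
#'
#' @param d Numeric vector (or matrix, columns = responses) of individual
#'   desirabilities in \[0, 1\].
#' @param importance Positive weights, one per response (default all 1).
#' @return Composite desirability in \[0, 1\] (vector if `d` is a matrix).
#' @export
composite_desirability <- function(d, importance = NULL) {
  if (is.matrix(d)) {
    k <- ncol(d)
    if (k == 0L) stop("empty desirability set", call. = FALSE)
    if (is.null(importance)) importance <- rep(1, k)
    ex <- exp(sweep(log(pmax(d, 0)), 2, importance, `*`) %*%
                rep(1 / sum(importance), k))
    out <- drop(ex)
    out[apply(d == 0, 1, any)] <- 0
    return(out)
  }
  if (length(d) == 0L) stop("empty desirability set", call. = FALSE)
  if (is.null(importance)) importance <- rep(1, length(d))
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

#' Reference goals for the quaternary separation
#'
#' The acceptance limits used as optimizer goals: capacity factor maximized
#' past 0.5, tailing targeted inside \[0.8, 2\], resolution maximized past
#' 1.5, all with importance 1.
#'
#' @param kprime_target,rs_target Ramp tops for the two maximize goals
#'   (defaults 1 and 3: comfortably beyond the acceptance limits).
#' @return List of three [response_goal()] objects named `kprime_ostp`,
#'   `tailing_ostp`, `rs_rem`.
#' @export
uplc_goals <- function(kprime_target = 1, rs_target = 3) {
  list(
    kprime_ostp = response_goal("kprime_ostp", "maximize",
                                low = 0.5, target = kprime_target),
    tailing_ostp = response_goal("tailing_ostp", "target",
                                 low = 0.8, target = 1.4, high = 2),
    rs_rem = response_goal("rs_rem", "maximize", low = 1.5, target = rs_target))
}

#' Optimize factor settings by composite desirability
#'
#' The response optimizer: evaluates the composite desirability of the
#' factorial prediction equations over a coarse factor grid, breaks ties
#' deterministically (lowest flow rate, then lowest first factor), and
#' refines the best grid point with a Nelder-Mead simplex clamped to the
#' bounds. Deterministic for fixed options.
#'
#' @param fits Named list of `ffd_fit` objects (names matching the goals'
#'   `response` fields), or of functions `f(data.frame of settings) -> y`.
#' @param goals List of [response_goal()] objects.
#' @param bounds Named list of `c(low, high)` per factor; defaults to the
#'   design region of the first `ffd_fit`.
#' @param n_grid Grid points per factor (default 41).
#' @param refine Run simplex refinement from the best grid point (default TRUE).
#' @return List of class `desirability_optimum`: `settings` (one-row
#'   data.frame), `individual_d`, `composite_D`, `evaluations`, `feasible`.
#' @export
optimize_settings <- function(fits, goals, bounds = NULL, n_grid = 41,
                              refine = TRUE) {
  stopifnot(length(goals) > 0, length(fits) > 0)
  goal_names <- vapply(goals, function(g) g$response, character(1))
  names(goals) <- goal_names
  if (!all(goal_names %in% names(fits)))
    stop("every goal needs a matching entry in `fits`", call. = FALSE)
  if (is.null(bounds)) {
    first_fit <- fits[[which(vapply(fits, inherits, logical(1), "ffd_fit"))[1]]]
    if (is.null(first_fit)) stop("supply `bounds` when no fit is an ffd_fit", call. = FALSE)
    bounds <- first_fit$levels
  }
  fac <- names(bounds)
  predict_one <- function(fit, settings) {
    if (inherits(fit, "ffd_fit"))
      predict(fit, settings, warn_extrapolation = FALSE)
    else fit(settings)
  }
  imp <- vapply(goals, function(g) g$importance, numeric(1))
  d_matrix <- function(settings) {
    vapply(goal_names, function(nm)
      individual_desirability(predict_one(fits[[nm]], settings), goals[[nm]]),
      numeric(nrow(settings)))
  }
  grid <- do.call(expand.grid, c(lapply(bounds, function(b)
    seq(b[1], b[2], length.out = n_grid)), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- fac
  dm <- d_matrix(grid)
  if (!is.matrix(dm)) dm <- matrix(dm, nrow = 1)
  D <- composite_desirability(dm, imp)
  evals <- nrow(grid)
  feasible <- any(D > 0)
  # deterministic tie-break: among near-best points prefer the lowest flow
  # rate, then the lowest first factor (solvent frugality)
  best_D <- max(D)
  cand <- which(D >= best_D - 1e-12)
  ord_cols <- intersect(c("flow_rate", fac[1]), fac)
  cand <- cand[do.call(order, grid[cand, ord_cols, drop = FALSE])]
  best <- cand[1]
  x0 <- as.numeric(grid[best, ])
  x_best <- x0
  D_best <- D[best]
  if (refine && feasible) {
    lo <- vapply(bounds, `[`, numeric(1), 1)
    hi <- vapply(bounds, `[`, numeric(1), 2)
    fn <- function(x) {
      x <- pmin(hi, pmax(lo, x))
      s <- as.data.frame(as.list(stats::setNames(x, fac)))
      -composite_desirability(matrix(d_matrix(s), nrow = 1), imp)
    }
    opt <- stats::optim(x0, fn, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    evals <- evals + opt$counts[["function"]]
    xr <- pmin(hi, pmax(lo, opt$par))
    if (-opt$value > D_best) { x_best <- xr; D_best <- -opt$value }
  }
  settings <- as.data.frame(as.list(stats::setNames(x_best, fac)))
  dvec <- drop(d_matrix(settings))
  names(dvec) <- goal_names
  structure(list(settings = settings, individual_d = dvec,
                 composite_D = D_best, evaluations = evals,
                 feasible = feasible),
            class = "desirability_optimum")
}

#' @export
print.desirability_optimum <- function(x, ...) {
  if (!x$feasible) {
    cat("<desirability_optimum> infeasible goals: D = 0 everywhere\n")
    return(invisible(x))
  }
  cat("<desirability_optimum>\n")
  print(x$settings, row.names = FALSE)
  cat(sprintf("composite D = %.4f (d: %s; %d evaluations)\n", x$composite_D,
              paste(sprintf("%s=%.3f", names(x$individual_d), x$individual_d),
                    collapse = ", "), x$evaluations))
  invisible(x)
}
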