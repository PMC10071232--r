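# Equivalence statistics: one-way ANOVA F, F critical values, and the
# two-sample t / variance-ratio F pair.

#' One-way analysis of variance for method equivalence
#'
#' Classical between/within mean-squares F statistic with its upper-tail
#' critical value; used to compare the same quantity measured by two or more
#' procedures (equivalence claimed when F stays below the critical value).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `f_critical`, `significant`, `alpha`.
#' @examples
#' one_way_anova(list(c(100.000, 100.166, 101.413),
#'                    c(100.000, 100.662, 100.402)))$f_statistic # 0.125
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), n)
  grand <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  fc <- f_critical(alpha, df1, df2)
  structure(list(f_statistic = f, df_between = df1, df_within = df2,
                 f_critical = fc, significant = f > fc, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, critical %.3f (alpha %g): %s\n",
              x$df_between, x$df_within, x$f_statistic, x$f_critical, x$alpha,
              if (x$significant) "significant difference" else "no significant difference"))
  invisible(x)
}

#' Upper-tail F critical value
#'
#' @param alpha Upper-tail probability.
#' @param df1,df2 Numerator and denominator degrees of freedom, >= 1.
#' @return The `1 - alpha` quantile of the F distribution.
#' @examples
#' f_critical(0.05, 1, 4) # 7.709
#' f_critical(0.05, 2, 3) # 9.552
#' @export
f_critical <- function(alpha, df1, df2) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

#' Student's t and variance-ratio F for two samples
#'
#' Pooled-variance two-sample t test (Welch available via `welch = TRUE`)
#' together with the variance-ratio F test (larger variance over smaller),
#' both decided two-sided at `alpha`.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's unequal-variance t instead of pooled (default
#'   FALSE).
#' @return List with `t_statistic`, `t_df`, `t_critical`, `t_significant`,
#'   `f_statistic`, `f_df`, `f_critical`, `f_significant`, `alpha`.
#' @export
two_sample_t_and_f <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both samples", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = !welch)
  f <- max(va, vb) / min(va, vb)
  f_df <- if (va >= vb) c(length(a) - 1L, length(b) - 1L)
          else c(length(b) - 1L, length(a) - 1L)
  f_crit <- stats::qf(1 - alpha / 2, f_df[1], f_df[2])
  t_crit <- stats::qt(1 - alpha / 2, tt$parameter)
  list(t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
       t_critical = t_crit, t_significant = abs(unname(tt$statistic)) > t_crit,
       f_statistic = f, f_df = f_df, f_critical = f_crit,
       f_significant = f > f_crit, alpha = alpha)
}
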