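# Method comparison: linearity/accuracy by ordinary least squares,
# Spearman rank agreement, and Bland-Altman limits of agreement.

#' Ordinary least-squares fit of test against reference
#'
#' Fits `y ~ x`, reporting slope, intercept, r², the t-based 95% CI of the
#' slope, the slope p-value, and whether the slope CI contains 1 (the
#' accuracy check: a method reproducing the reference has slope
#' indistinguishable from 1).
#'
#' @param x Reference-method values.
#' @param y Test-method values (same units).
#' @param labels Optional sample labels.
#' @return A list with `slope`, `intercept`, `r2`, `slope_ci95`,
#'   `p_slope`, `slope_ci_contains_one`, and the underlying `fit`.
#' @export
linear_fit <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs required for regression")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  slope_ci <- c(ci[1, 1], ci[1, 2])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       slope_ci95 = slope_ci,
       p_slope = sm$coefficients["x", "Pr(>|t|)"],
       slope_ci_contains_one = slope_ci[1] <= 1 && 1 <= slope_ci[2],
       fit = fit)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; 1 for any strictly monotone
#' increasing relation.
#'
#' @param x,y Paired values, length >= 3.
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series; rank correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `test − reference` (`y − x`); the bias is their
#' mean, and the limits of agreement are `bias ± 1.96 × SD(differences)`
#' (sample SD). The per-pair (average, difference) table supports the
#' standard agreement plot.
#'
#' @param x Reference-method values.
#' @param y Test-method values.
#' @param labels Optional sample labels.
#' @return An object of class `agreement_result` with `bias`, `sd_diff`,
#'   `loa` (lower, upper), `n`, `direction`, and `table`
#'   (`label`, `average`, `difference`).
#' @export
bland_altman <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("at least 2 pairs required")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = s,
    loa = c(bias - 1.96 * s, bias + 1.96 * s), n = length(d),
    direction = "test - reference",
    table = data.frame(
      label = if (is.null(labels)) seq_along(d) else labels,
      average = (x + y) / 2, difference = d)),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias %.6g (%s), SD %.6g, LoA [%.6g, %.6g], n = %d\n",
    x$bias, x$direction, x$sd_diff, x$loa[1], x$loa[2], x$n))
  invisible(x)
}
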