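#' Pearson correlation between two series
#'
#' Standard product-moment correlation, used to quantify trend agreement
#' between two model-predicted time series.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("series must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation is undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlation-strength label
#'
#' Conventional banding of the absolute Pearson coefficient:
#' `|r| >= 0.8` extremely strong (`"ESC"`), `[0.6, 0.8)` strong,
#' `[0.4, 0.6)` moderate, `[0.2, 0.4)` weak, below 0.2 very weak.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of labels.
#' @export
correlation_label <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  cut(pmin(abs(r), 1),
      breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("very weak", "weak", "moderate", "strong", "ESC")) |>
    as.character()
}

#' One-way ANOVA between groups
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance F
#' test) across two or more groups, reporting the F statistic, its p value,
#' the upper-`alpha` critical value at the same degrees of freedom, and a
#' verdict: `"NSD"` (no significant difference) when `F < F_crit`,
#' `"ESD"` otherwise.
#'
#' @param groups List of two or more numeric vectors (each length >= 2).
#' @param alpha Significance level; default 0.05.
#' @return Object of class `anova_result`: list with `F`, `p`, `df1`,
#'   `df2`, `F_crit`, `alpha`, `verdict`.
#' @examples
#' one_way_anova(list(rnorm(20), rnorm(20, 1)))
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  lens <- lengths(groups)
  if (any(lens < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  check_scalar(alpha, "alpha", lower = 0)
  if (alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  v <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(v))) stop("groups must be finite", call. = FALSE)
  g <- factor(rep(seq_along(groups), lens))
  ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
  df1 <- unname(ow$parameter["num df"])
  df2 <- unname(ow$parameter["denom df"])
  Fstat <- unname(ow$statistic)
  F_crit <- stats::qf(1 - alpha, df1, df2)
  structure(
    list(F = Fstat, p = unname(ow$p.value), df1 = df1, df2 = df2,
         F_crit = F_crit, alpha = alpha,
         verdict = if (Fstat < F_crit) "NSD" else "ESD"),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%g, %g) = %.4g, p = %.4g, F-crit(alpha = %g) = %.4g -> %s\n",
    x$df1, x$df2, x$F, x$p, x$alpha, x$F_crit, x$verdict))
  invisible(x)
}

#' Agreement report between two predicted series
#'
#' Combines the two model-agreement statistics used throughout the package:
#' the Pearson correlation (with its strength label) measuring whether two
#' series share a trend, and a one-way ANOVA treating the series as two
#' groups, measuring whether their levels differ. Note the ANOVA treats
#' autocorrelated time samples as independent observations -- a convention
#' of this comparison protocol rather than a rigorous time-series test; see
#' the methods vignette.
#'
#' @param x,y Numeric series of equal length >= 3.
#' @param alpha ANOVA significance level; default 0.05.
#' @return Object of class `agreement_report`: list with `pearson_r`,
#'   `correlation_label` and `anova` (an `anova_result`).
#' @examples
#' a <- sin(seq(0, pi, length.out = 50))
#' agreement_report(a, a + rnorm(50, sd = 0.01))
#' @export
agreement_report <- function(x, y, alpha = 0.05) {
  r <- pearson_r(x, y)
  structure(
    list(pearson_r = r, correlation_label = correlation_label(r),
         anova = one_way_anova(list(x, y), alpha = alpha)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s)\n",
              x$pearson_r, x$correlation_label))
  print(x$anova)
  invisible(x)
}
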