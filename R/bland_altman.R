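# Bland-Altman agreement analysis: per-sample differences between a
# comparator and the reference, their mean (bias), 1.96-SD limits of
# agreement, and a one-sample t test of the bias.

#' Per-sample Bland-Altman differences
#'
#' @param x Reference values (must be positive in percent mode when the
#'   reference is the denominator).
#' @param y Comparator values, same length.
#' @param mode `"absolute"` (`y - x`, same units) or `"percent"`.
#' @param denominator Denominator convention for percent mode:
#'   `"reference"` gives `100 (y - x) / x` with the reference value as the
#'   x-axis coordinate; `"mean_of_methods"` gives
#'   `100 (y - x) / ((x + y)/2)` with the mean of methods as coordinate.
#' @return A data.frame with `x_coord` and `diff`; samples excluded in
#'   percent mode because of a non-positive denominator are dropped and
#'   counted in the `n_excluded` attribute.
#' @export
ba_differences <- function(x, y, mode = c("absolute", "percent"),
                           denominator = c("reference", "mean_of_methods")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n_excluded <- 0L
  if (mode == "absolute") {
    d <- y - x
    coord <- (x + y) / 2
    if (denominator == "reference") coord <- x
  } else {
    den <- if (denominator == "reference") x else (x + y) / 2
    keep <- den > 0
    n_excluded <- sum(!keep)
    if (n_excluded > 0) {
      message(sprintf(
        "%d sample(s) with non-positive denominator excluded from percent differences",
        n_excluded))
    }
    d <- 100 * (y[keep] - x[keep]) / den[keep]
    coord <- den[keep]
  }
  out <- data.frame(x_coord = coord, diff = d)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Summarize differences into a Bland-Altman result
#'
#' Bias is the mean difference, the limits of agreement are
#' `bias +/- loa_mult * SD` (sample SD, n - 1), the bias CI and p-value
#' come from the one-sample t statistic `bias / (SD / sqrt(n))`.
#'
#' @param differences Numeric vector of per-sample differences (or the
#'   data.frame from [ba_differences()]).
#' @param mode,denominator Labels recorded in the result.
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @param conf_level Confidence level of the bias CI.
#' @return An object of class `ba_result`: `bias`, `sd_diff`, `loa`,
#'   `bias_ci`, `p_bias`, `n`, `exact_agreement` (TRUE when the
#'   differences have zero variance, in which case `p_bias` is NA).
#' @export
ba_summary <- function(differences, mode = "absolute",
                       denominator = "reference", loa_mult = 1.96,
                       conf_level = 0.95) {
  if (is.data.frame(differences)) differences <- differences$diff
  n <- length(differences)
  if (n < 3) stop("need at least 3 differences")
  bias <- mean(differences)
  sd_diff <- stats::sd(differences)
  loa <- c(bias - loa_mult * sd_diff, bias + loa_mult * sd_diff)
  exact <- sd_diff == 0
  if (exact) {
    bias_ci <- c(bias, bias)
    p_bias <- NA_real_
  } else {
    se <- sd_diff / sqrt(n)
    tcrit <- stats::qt((1 + conf_level) / 2, df = n - 1)
    bias_ci <- c(bias - tcrit * se, bias + tcrit * se)
    tstat <- bias / se
    p_bias <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  structure(list(mode = mode, denominator = denominator, bias = bias,
                 sd_diff = sd_diff, loa = loa, bias_ci = bias_ci,
                 p_bias = p_bias, n = n, loa_mult = loa_mult,
                 conf_level = conf_level, exact_agreement = exact),
            class = "ba_result")
}

#' Bland-Altman analysis of a paired series
#'
#' Convenience wrapper: [ba_differences()] followed by [ba_summary()].
#'
#' @inheritParams ba_differences
#' @inheritParams ba_summary
#' @return A `ba_result` with the per-sample difference table attached as
#'   `$differences`.
#' @export
bland_altman <- function(x, y, mode = c("absolute", "percent"),
                         denominator = c("reference", "mean_of_methods"),
                         loa_mult = 1.96, conf_level = 0.95) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  d <- ba_differences(x, y, mode, denominator)
  res <- ba_summary(d$diff, mode, denominator, loa_mult, conf_level)
  res$n_excluded <- attr(d, "n_excluded")
  res$differences <- d
  res
}

#' @export
print.ba_result <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("Bland-Altman (%s, denominator = %s, n = %d)\n",
              x$mode, x$denominator, x$n))
  cat(sprintf("  bias: %.3f%s  (%.0f%% CI %.3f to %.3f)\n",
              x$bias, unit, 100 * x$conf_level, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  limits of agreement: %.3f to %.3f%s\n",
              x$loa[1], x$loa[2], unit))
  if (x$exact_agreement) {
    cat("  differences are constant (exact agreement up to the offset)\n")
  } else {
    cat(sprintf("  p (bias != 0): %.4g\n", x$p_bias))
  }
  invisible(x)
}
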