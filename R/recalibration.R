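# Cross-population recalibration: remove the assay-vs-reference
# calibration difference estimated in healthy controls, then quantify the
# residual bias that is specific to the second population (here pregnancy).
# Any residual deviation after this correction reflects the sample matrix,
# not the assay's ordinary calibration offset.

#' Map assay values onto the reference scale with a linear fit
#'
#' Applies `(value - intercept) / slope`, the exact inverse of the linear
#' response `value = slope * x + intercept`.  Only the point estimates of
#' the fit are used; fit uncertainty is carried by the downstream
#' Bland-Altman summary.
#'
#' @param values Assay readings, pmol/L.
#' @param fit A [pb_fit()] or any list with `slope` and `intercept`.
#' @return Recalibrated values, pmol/L.  Negative outputs are retained but
#'   counted in the `n_negative` attribute (with a warning).
#' @export
#' @examples
#' recalibrate(13.25, list(slope = 0.65, intercept = 4.67))  # 13.2
recalibrate <- function(values, fit) {
  if (is.null(fit$slope) || is.null(fit$intercept)) {
    stop("fit must supply 'slope' and 'intercept'")
  }
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop("recalibration requires a finite, strictly positive slope")
  }
  out <- (values - fit$intercept) / fit$slope
  n_neg <- sum(out < 0)
  if (n_neg > 0) {
    warning(sprintf("%d recalibrated value(s) are negative", n_neg))
  }
  attr(out, "n_negative") <- n_neg
  out
}

#' Pregnancy-specific assay deviation after control-based recalibration
#'
#' The study's core procedure, per assay:
#' 1. fit Passing-Bablok of assay vs reference on the control group only;
#' 2. recalibrate the assay's pregnant-group readings with that control
#'    fit, `(value - intercept) / slope`;
#' 3. Bland-Altman (percent mode, reference denominator) of the
#'    recalibrated pregnant values against the pregnant reference values.
#'
#' The resulting bias is the headline matrix deviation: it is ~0 when the
#' assay behaves identically in both populations, and positive when the
#' assay reads relatively higher in pregnancy.
#'
#' @param table Tidy measurement table (see [simulate_measurements()]).
#' @param assay Comparator assay name.
#' @param reference Reference method name.
#' @param conf_level Confidence level for the Passing-Bablok fit and the
#'   bias CI.
#' @return An object of class `deviation_report`: `assay`, `control_fit`
#'   (a `pb_fit`), `recalibrated` (data.frame `sample_id`, `reference`,
#'   `recalibrated`), `ba` (a percent-mode `ba_result` on the pregnant
#'   group) and `excluded` (samples dropped in pairing or percent mode).
#' @export
cross_population_deviation <- function(table, assay,
                                       reference = "LC-MS/MS",
                                       conf_level = 0.95) {
  validate_measurement_table(table)
  for (g in c("control", "pregnant")) {
    if (!g %in% table$group) {
      stop(sprintf("group '%s' is required but missing from the table", g))
    }
  }
  if (!assay %in% table$method) {
    stop(sprintf("assay '%s' not present in the table", assay))
  }
  if (!reference %in% table$method) {
    stop(sprintf("reference method '%s' not present in the table", reference))
  }

  ctrl <- paired_series(table, reference, assay, "control")
  control_fit <- suppressWarnings(pb_fit(ctrl$x, ctrl$y, conf_level))

  preg <- paired_series(table, reference, assay, "pregnant")
  recal <- suppressWarnings(recalibrate(preg$y, control_fit))
  d <- ba_differences(preg$x, as.numeric(recal), mode = "percent",
                      denominator = "reference")
  ba <- ba_summary(d$diff, mode = "percent", denominator = "reference",
                   conf_level = conf_level)

  structure(list(
    assay = assay,
    control_fit = control_fit,
    recalibrated = data.frame(sample_id = preg$sample_id,
                              reference = preg$x,
                              recalibrated = as.numeric(recal),
                              stringsAsFactors = FALSE),
    ba = ba,
    excluded = ctrl$n_dropped + preg$n_dropped + attr(d, "n_excluded")),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("Cross-population deviation: %s vs reference\n", x$assay))
  cat(sprintf("  control fit: slope %.3f, intercept %.3f (n = %d)\n",
              x$control_fit$slope, x$control_fit$intercept, x$control_fit$n))
  cat(sprintf("  pregnant-group deviation after recalibration: %+.2f%% ",
              x$ba$bias))
  cat(sprintf("(LoA %.2f to %.2f%%, p = %.4g, n = %d)\n",
              x$ba$loa[1], x$ba$loa[2], x$ba$p_bias, x$ba$n))
  invisible(x)
}
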