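# Group-comparison statistics: summaries (mean/CI or median/IQR), the
# independent t test, a Mann-Whitney U with exact small-sample enumeration,
# a Shapiro-Wilk normality gate that routes variables to the appropriate
# test, and per-assay percent-difference tests against the reference.

#' Summarize a sample as mean/95% CI or median/IQR
#'
#' @param values Numeric vector, n >= 2.
#' @param kind `"mean_ci"` for mean with t-based CI, `"median_iqr"` for
#'   median with 25th-75th percentiles (type-7 linear interpolation).
#' @param conf_level Confidence level for the mean CI.
#' @return A list: `kind`, `estimate`, `lower`, `upper`, `n`.
#' @export
#' @examples
#' summarize_values(c(1, 2, 3), "mean_ci")     # 2 (-0.48 to 4.48)
#' summarize_values(1:100, "median_iqr")       # 50.5 (25.75 to 75.25)
summarize_values <- function(values, kind = c("mean_ci", "median_iqr"),
                             conf_level = 0.95) {
  kind <- match.arg(kind)
  n <- length(values)
  if (n < 2) stop("degenerate input: need at least 2 values")
  if (kind == "mean_ci") {
    m <- mean(values)
    se <- stats::sd(values) / sqrt(n)
    tcrit <- stats::qt((1 + conf_level) / 2, df = n - 1)
    list(kind = kind, estimate = m, lower = m - tcrit * se,
         upper = m + tcrit * se, n = n)
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(kind = kind, estimate = q[2], lower = q[1], upper = q[3], n = n)
  }
}

#' Independent two-sample t test
#'
#' Thin wrapper over [stats::t.test()] returning the package's comparison
#' record.  Defaults to the Student (equal-variance) variant; Welch is
#' available by flag.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return A list of class `group_comparison`: `test`, `estimate_1`,
#'   `estimate_2` (means with CIs), `statistic`, `p`, and
#'   `exact_agreement` when both groups are constant (p is then NA unless
#'   the means coincide).
#' @export
t_test_independent <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("both groups need n >= 2")
  res <- tryCatch(
    stats::t.test(a, b, var.equal = (variant == "student")),
    error = function(e) NULL)
  exact <- is.null(res)
  p <- if (exact) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
  } else {
    unname(res$p.value)
  }
  structure(list(
    test = paste0("t_independent_", variant),
    estimate_1 = summarize_values(a, "mean_ci"),
    estimate_2 = summarize_values(b, "mean_ci"),
    statistic = if (exact) NA_real_ else unname(res$statistic),
    p = p,
    exact_agreement = exact), class = "group_comparison")
}

# U statistic of group a against group b, from midranks of the pooled data.
u_statistic <- function(ranks_a, n_a) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

# Exact two-sided p by enumerating every assignment of the pooled midranks
# to group a (feasible for the small totals it is used at).
mw_exact_p <- function(pooled_ranks, n_a, u_obs) {
  combos <- utils::combn(length(pooled_ranks), n_a)
  u_all <- apply(combos, 2, function(ix) u_statistic(pooled_ranks[ix], n_a))
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test
#'
#' Computes the U statistic from midranks.  For total sample sizes up to
#' `exact_max` the two-sided p-value is obtained by exact enumeration of
#' all rank assignments (valid under ties); otherwise the normal
#' approximation with continuity correction and tie-corrected variance is
#' used.
#'
#' @param a,b Numeric vectors, each n >= 1.
#' @param exact_max Largest pooled n for which exact enumeration is used
#'   (default 12).
#' @return A list of class `group_comparison`: `test` (`"mann_whitney_u"`),
#'   `estimate_1`, `estimate_2` (medians with IQRs), `statistic` (U of the
#'   first group), `p`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # 1/3 by enumeration
mann_whitney_u <- function(a, b, exact_max = 12) {
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both groups need n >= 1")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- u_statistic(r[seq_len(n_a)], n_a)
  n <- n_a + n_b
  if (n <= exact_max) {
    p <- mw_exact_p(r, n_a, u)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence of a shift
    } else {
      # continuity correction: shrink |U - mu| by 0.5
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  est <- function(v) {
    if (length(v) >= 2) summarize_values(v, "median_iqr")
    else list(kind = "median_iqr", estimate = v, lower = v, upper = v, n = 1L)
  }
  structure(list(test = "mann_whitney_u", estimate_1 = est(a),
                 estimate_2 = est(b), statistic = u, p = p,
                 method = method), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(e) sprintf("%.3g (%.3g to %.3g)", e$estimate, e$lower,
                             e$upper)
  cat(sprintf("%s: %s vs %s, p = %.4g\n", x$test, fmt(x$estimate_1),
              fmt(x$estimate_2), x$p))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Decides whether a sample looks normal at level `alpha`; degenerate
#' samples (n < 3 or zero variance) are routed to `"non_normal"` so the
#' caller falls back to the rank test.
#'
#' @param values Numeric vector.
#' @param alpha Decision level (default 0.05).
#' @return A list: `decision` (`"normal"` or `"non_normal"`) and `p` (NA
#'   when the test is undefined).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3 || stats::sd(values) == 0) {
    return(list(decision = "non_normal", p = NA_real_))
  }
  p <- tryCatch(stats::shapiro.test(values)$p.value,
                error = function(e) NA_real_)
  decision <- if (!is.na(p) && p > alpha) "normal" else "non_normal"
  list(decision = decision, p = p)
}

#' Per-assay percent difference from the reference within one group
#'
#' For each comparator assay, pairs its readings with the reference by
#' sample, reports the mean per-sample percent difference
#' `100 (assay - reference) / reference`, and tests the paired difference
#' with a paired t test.
#'
#' @param table Tidy measurement table.
#' @param group Group to analyse (`"pregnant"` or `"control"`).
#' @param reference Reference method name.
#' @return A data.frame: `assay`, `group`, `n`, `mean_pct_diff`, `p`,
#'   `n_dropped` (unpaired samples).
#' @export
method_vs_reference_tests <- function(table, group,
                                      reference = "LC-MS/MS") {
  validate_measurement_table(table)
  if (!group %in% table$group) {
    stop(sprintf("group '%s' not present in the table", group))
  }
  assays <- setdiff(unique(table$method), reference)
  out <- lapply(assays, function(a) {
    s <- paired_series(table, reference, a, group)
    pct <- 100 * (s$y - s$x) / s$x
    p <- if (isTRUE(all.equal(s$x, s$y))) {
      1  # identical methods: no paired difference to test
    } else {
      stats::t.test(s$y, s$x, paired = TRUE)$p.value
    }
    data.frame(assay = a, group = group, n = length(s$x),
               mean_pct_diff = mean(pct), p = p, n_dropped = s$n_dropped,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$assay), ]
  rownames(res) <- NULL
  res
}

#' Pregnant-vs-control comparisons of fT4, TBG and albumin
#'
#' Reproduces the study-level group statistics: each variable is routed to
#' the Student t test when both groups pass the Shapiro-Wilk gate and to
#' the Mann-Whitney U test otherwise.  fT4 is taken from the reference
#' method's rows; TBG and albumin are per-sample covariates.
#'
#' @param table Tidy measurement table with `tbg_nmol_l` and
#'   `albumin_g_l` columns.
#' @param reference Reference method name (supplies the fT4 values).
#' @param alpha Level of the normality gate.
#' @param t_variant Passed to [t_test_independent()].
#' @return A data.frame: `variable`, `test`, `estimate_pregnant`,
#'   `lower_pregnant`, `upper_pregnant`, `estimate_control`,
#'   `lower_control`, `upper_control`, `p`.
#' @export
group_comparisons <- function(table, reference = "LC-MS/MS", alpha = 0.05,
                              t_variant = "student") {
  validate_measurement_table(table)
  ref <- table[table$method == reference, ]
  vars <- list(
    ft4_pmol_l = ref$ft4_pmol_l,
    tbg_nmol_l = ref$tbg_nmol_l,
    albumin_g_l = ref$albumin_g_l)
  groups <- ref$group
  out <- lapply(names(vars), function(v) {
    vals <- vars[[v]]
    if (all(is.na(vals))) return(NULL)
    a <- vals[groups == "pregnant"]
    b <- vals[groups == "control"]
    gate_ok <- normality_gate(a, alpha)$decision == "normal" &&
      normality_gate(b, alpha)$decision == "normal"
    cmp <- if (gate_ok) t_test_independent(a, b, t_variant)
           else mann_whitney_u(a, b)
    data.frame(variable = v, test = cmp$test,
               estimate_pregnant = cmp$estimate_1$estimate,
               lower_pregnant = cmp$estimate_1$lower,
               upper_pregnant = cmp$estimate_1$upper,
               estimate_control = cmp$estimate_2$estimate,
               lower_control = cmp$estimate_2$lower,
               upper_control = cmp$estimate_2$upper,
               p = cmp$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
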