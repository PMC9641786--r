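# Passing-Bablok nonparametric method-comparison regression.
#
# The slope is a shifted median of all pairwise slopes, which makes the fit
# scale-invariant and robust to measurement error in both methods; the
# confidence interval comes from the rank distribution of Kendall's tau.

#' All pairwise slopes of a paired series
#'
#' Computes the N(N-1)/2 slopes `(y_j - y_i) / (x_j - x_i)` over pairs
#' `i < j`.  Pairs with equal x but different y (vertical), identical
#' points, and slopes exactly equal to -1 are excluded and counted; the
#' -1 exclusion preserves the procedure's invariance under swapping the
#' two methods.
#'
#' @param x Reference-method values.
#' @param y Comparator values, same length.
#' @return A list with `slopes` (sorted ascending), and exclusion counts
#'   `n_vertical`, `n_identical`, `n_minus_one`.
#' @export
pairwise_slopes <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[idx[, 2]] - x[idx[, 1]]
  dy <- y[idx[, 2]] - y[idx[, 1]]
  identical_pt <- dx == 0 & dy == 0
  vertical <- dx == 0 & dy != 0
  s <- dy[!identical_pt & !vertical] / dx[!identical_pt & !vertical]
  minus_one <- s == -1
  list(slopes = sort(s[!minus_one]),
       n_vertical = sum(vertical),
       n_identical = sum(identical_pt),
       n_minus_one = sum(minus_one))
}

# Round-half-up, the convention used for the CI rank M1.
round_half_up <- function(z) floor(z + 0.5)

clamp_index <- function(i, n_s) {
  if (i < 1L || i > n_s) {
    warning("confidence-interval rank fell outside the slope multiset; ",
            "clamped to the extreme order statistic")
  }
  min(max(i, 1L), n_s)
}

#' Passing-Bablok regression fit
#'
#' Estimates the comparator-vs-reference line `y = a + b x`.  The slope is
#' the offset median of the sorted pairwise-slope multiset `S` of size
#' `n_s`, shifted by `K`, the number of slopes below -1:
#' `b = S[(n_s + 1)/2 + K]` for odd `n_s`, the mean of `S[n_s/2 + K]` and
#' `S[n_s/2 + 1 + K]` for even.  Its confidence bounds are the order
#' statistics `S[M1 + K]`, `S[M2 + K]` with
#' `C = z * sqrt(N (N - 1) (2N + 5) / 18)`, `M1 = round((n_s - C)/2)`
#' (half-up), `M2 = n_s - M1 + 1`.  The intercept is `median(y - b x)`,
#' with CI bounds computed at the opposite slope bounds.  Pearson r on the
#' raw pairs accompanies the fit.
#'
#' @param x Reference-method values.
#' @param y Comparator values.
#' @param conf_level Confidence level for the rank-based CIs (default 0.95).
#' @return An object of class `pb_fit`: `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `n`, `pearson_r`, `conf_level`, and the exclusion
#'   counts from [pairwise_slopes()].
#' @export
#' @examples
#' x <- c(10, 12, 15, 17, 19, 21, 24, 26, 28, 30)
#' fit <- pb_fit(x, 0.53 * x + 3.78)
#' fit$slope      # 0.53
#' fit$intercept  # 3.78
pb_fit <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (n < 10) {
    warning("fewer than 10 pairs: rank-based confidence intervals are ",
            "unreliable at this size")
  }
  ps <- pairwise_slopes(x, y)
  s <- ps$slopes
  n_s <- length(s)
  if (n_s < 3) stop("degenerate input: fewer than 3 valid pairwise slopes")
  k_off <- sum(s < -1)

  if (n_s %% 2 == 1) {
    b <- s[clamp_index((n_s + 1L) %/% 2L + k_off, n_s)]
  } else {
    i1 <- clamp_index(n_s %/% 2L + k_off, n_s)
    i2 <- clamp_index(n_s %/% 2L + 1L + k_off, n_s)
    b <- mean(c(s[i1], s[i2]))
  }
  if (b <= 0) {
    warning("non-positive Passing-Bablok slope: the methods do not show ",
            "the positive association the comparison assumes")
  }

  z <- stats::qnorm((1 + conf_level) / 2)
  c_stat <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round_half_up((n_s - c_stat) / 2)
  m2 <- n_s - m1 + 1
  b_lo <- s[clamp_index(as.integer(m1) + k_off, n_s)]
  b_hi <- s[clamp_index(as.integer(m2) + k_off, n_s)]

  a <- stats::median(y - b * x)
  a_lo <- stats::median(y - b_hi * x)
  a_hi <- stats::median(y - b_lo * x)

  structure(list(slope = b, slope_ci = c(b_lo, b_hi),
                 intercept = a, intercept_ci = c(a_lo, a_hi),
                 n = n, pearson_r = stats::cor(x, y),
                 conf_level = conf_level,
                 n_slopes = n_s,
                 exclusions = ps[c("n_vertical", "n_identical",
                                   "n_minus_one")]),
            class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d)\n", x$n))
  cat(sprintf("  slope:     %.4f  (%.0f%% CI %.4f to %.4f)\n",
              x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept: %.4f  (%.0f%% CI %.4f to %.4f)\n",
              x$intercept, 100 * x$conf_level, x$intercept_ci[1],
              x$intercept_ci[2]))
  cat(sprintf("  Pearson r: %.4f\n", x$pearson_r))
  invisible(x)
}

# Pair a comparator method against the reference within one group of a
# tidy measurement table; rows missing either member are dropped.
paired_series <- function(table, reference, method, group) {
  ref <- table[table$method == reference & table$group == group,
               c("sample_id", "ft4_pmol_l")]
  cmp <- table[table$method == method & table$group == group,
               c("sample_id", "ft4_pmol_l")]
  m <- merge(ref, cmp, by = "sample_id", suffixes = c("_ref", "_cmp"))
  m <- m[order(m$sample_id), ]
  n_dropped <- (nrow(ref) - nrow(m)) + (nrow(cmp) - nrow(m))
  list(x = m$ft4_pmol_l_ref, y = m$ft4_pmol_l_cmp,
       sample_id = m$sample_id, n_dropped = n_dropped)
}

#' Passing-Bablok fits for every assay and group in a measurement table
#'
#' @param table Tidy measurement table (see [simulate_measurements()]).
#' @param reference Name of the reference method; must be present.
#' @param conf_level Confidence level passed to [pb_fit()].
#' @return A data.frame with one row per comparator per group: `assay`,
#'   `group`, `n`, `slope`, `slope_lo`, `slope_hi`, `intercept`,
#'   `intercept_lo`, `intercept_hi`, `r`.  A group/assay cell whose fit is
#'   degenerate yields NA estimates with a warning; other cells proceed.
#' @export
pb_fit_all <- function(table, reference = "LC-MS/MS", conf_level = 0.95) {
  validate_measurement_table(table)
  if (!reference %in% table$method) {
    stop(sprintf("reference method '%s' not present in the table", reference))
  }
  assays <- setdiff(unique(table$method), reference)
  groups <- unique(table$group)
  out <- list()
  for (a in assays) {
    for (g in groups) {
      series <- paired_series(table, reference, a, g)
      fit <- tryCatch(
        suppressWarnings(pb_fit(series$x, series$y, conf_level)),
        error = function(e) {
          warning(sprintf("fit failed for assay '%s', group '%s': %s",
                          a, g, conditionMessage(e)))
          NULL
        })
      out[[length(out) + 1L]] <- data.frame(
        assay = a, group = g, n = length(series$x),
        slope = if (is.null(fit)) NA_real_ else fit$slope,
        slope_lo = if (is.null(fit)) NA_real_ else fit$slope_ci[1],
        slope_hi = if (is.null(fit)) NA_real_ else fit$slope_ci[2],
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        intercept_lo = if (is.null(fit)) NA_real_ else fit$intercept_ci[1],
        intercept_hi = if (is.null(fit)) NA_real_ else fit$intercept_ci[2],
        r = if (is.null(fit)) NA_real_ else fit$pearson_r,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$assay, res$group), ]
  rownames(res) <- NULL
  res
}
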