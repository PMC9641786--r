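# Pipeline shell: measurement-table schema, JSON config, orchestration of
# the full analysis (Passing-Bablok table, Bland-Altman summaries,
# cross-population deviations, group comparisons) and CSV/manifest output.

MEASUREMENT_COLUMNS <- c("sample_id", "group", "method", "ft4_pmol_l")

#' Validate a tidy measurement table
#'
#' Checks the long-format schema: required columns, groups restricted to
#' pregnant/control, strictly positive fT4 values, and uniqueness of
#' (sample_id, method).  Violations are reported with the offending rows.
#'
#' @param table A data.frame of paired measurements.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_measurement_table <- function(table) {
  if (!is.data.frame(table)) stop("measurement table must be a data.frame")
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(table))
  if (length(missing_cols) > 0) {
    stop("measurement table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_group <- which(!table$group %in% c("pregnant", "control"))
  if (length(bad_group) > 0) {
    stop("invalid group label(s) in row(s): ",
         paste(utils::head(bad_group, 10), collapse = ", "))
  }
  bad_val <- which(!is.finite(table$ft4_pmol_l) | table$ft4_pmol_l <= 0)
  if (length(bad_val) > 0) {
    stop("non-positive or missing fT4 value(s) in row(s): ",
         paste(utils::head(bad_val, 10), collapse = ", "))
  }
  key <- paste(table$sample_id, table$method, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicated (sample_id, method) pair(s) in row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  invisible(table)
}

#' Default simulation/analysis configuration
#'
#' Bundles the packaged study conditions: the pregnant and control group
#' profiles, the five-assay calibration panel, the reference-method CV
#' model, and the canonical binding-constant calibration.
#'
#' @param n_pregnant,n_control Cohort sizes.
#' @param assay_cv Fractional imprecision applied to every immunoassay.
#' @return A list of class `ft4_config` with elements `profiles`,
#'   `calibrations`, `cv_model`, `constants`, `reference`.
#' @export
default_config <- function(n_pregnant = 30, n_control = 30,
                           assay_cv = 0.04) {
  structure(list(
    profiles = list(pregnant_profile(n_pregnant),
                    control_profile(n_control)),
    calibrations = default_assay_calibrations(cv = assay_cv),
    cv_model = reference_cv_model(),
    constants = calibrate_binding_constants(),
    reference = "LC-MS/MS"), class = "ft4_config")
}

#' Read a simulation/analysis configuration from JSON
#'
#' The JSON object may contain `groups` (a list of group-profile records
#' with the [group_profile()] fields), `assays` (records with the
#' [assay_calibration()] fields), `cv_model` (`concentrations`, `cvs`),
#' `reference` (method name) and either `binding_constants`
#' (`ka_tbg`, `ka_ttr`, `ka_alb`) or `binding_calibration`
#' (a [reference_serum()] record plus `f_free`, `bound_ratios`).  Missing
#' sections fall back to the packaged defaults.
#'
#' @param path Path to a JSON file.
#' @return An `ft4_config` list (see [default_config()]).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  if (!is.null(raw$groups)) {
    cfg$profiles <- lapply(seq_len(nrow(raw$groups)), function(i) {
      g <- raw$groups[i, ]
      group_profile(g$name, g$ft4_mean, g$ft4_sd, g$tbg_mean, g$tbg_sd,
                    g$alb_median, g$alb_sd,
                    ttr_mean = if (!is.null(g$ttr_mean) && !is.na(g$ttr_mean))
                      g$ttr_mean else 4.6,
                    n = g$n)
    })
  }
  if (!is.null(raw$assays)) {
    a <- as.data.frame(raw$assays, stringsAsFactors = FALSE)
    if (is.null(a$cv)) a$cv <- 0.04
    cfg$calibrations <- a[, c("assay", "group", "slope", "intercept", "cv")]
  }
  if (!is.null(raw$cv_model)) {
    cfg$cv_model <- cv_model(raw$cv_model$concentrations, raw$cv_model$cvs)
  }
  if (!is.null(raw$binding_constants)) {
    b <- raw$binding_constants
    cfg$constants <- binding_constants(b$ka_tbg, b$ka_ttr, b$ka_alb)
  } else if (!is.null(raw$binding_calibration)) {
    b <- raw$binding_calibration
    ref <- reference_serum(
      total_t4 = if (is.null(b$total_t4)) 100 else b$total_t4,
      tbg = if (is.null(b$tbg)) 302 else b$tbg,
      ttr = if (is.null(b$ttr)) 4.6 else b$ttr,
      albumin_gl = if (is.null(b$albumin_gl)) 41.8 else b$albumin_gl)
    cfg$constants <- calibrate_binding_constants(
      ref,
      f_free = if (is.null(b$f_free)) 2e-4 else b$f_free,
      bound_ratios = if (is.null(b$bound_ratios)) c(tbg = 75, ttr = 10,
                                                    alb = 12)
                     else unlist(b$bound_ratios))
  }
  if (!is.null(raw$reference)) cfg$reference <- raw$reference
  cfg
}

# Small deterministic fingerprint of the run settings for the manifest.
settings_fingerprint <- function(config, seed) {
  s <- paste(seed,
             paste(vapply(config$profiles, function(p) {
               paste(p$name, p$ft4_mean, p$ft4_sd, p$tbg_mean, p$tbg_sd,
                     p$alb_median, p$alb_sd, p$ttr_mean, p$n, sep = ",")
             }, character(1)), collapse = ";"),
             paste(apply(config$calibrations, 1, paste, collapse = ","),
                   collapse = ";"),
             paste(config$cv_model$concentrations, config$cv_model$cvs,
                   collapse = ","),
             sep = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_output_csv <- function(df, path, fingerprint) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ft4compare run manifest %s", fingerprint), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a tidy measurement CSV
#'
#' Reads (and validates) a measurement table written by
#' [write_measurement_csv()] or assembled externally; lines starting with
#' `#` are treated as comments.
#'
#' @param path CSV path.
#' @return A validated measurement data.frame.
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_measurement_table(df)
  df
}

#' Write a tidy measurement CSV
#'
#' @param table A validated measurement data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurement_csv <- function(table, path) {
  validate_measurement_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Run the full method-comparison pipeline
#'
#' Either simulates a study from the configuration or analyses a provided
#' measurement table, then computes (1) Passing-Bablok fits per assay and
#' group, (2) percent-mode Bland-Altman summaries per assay and group,
#' (3) the control-based recalibration deviation per assay, and (4) the
#' pregnant-vs-control group comparisons.  With `out_dir` set, writes
#' `measurements.csv`, `table1.csv`, `bland_altman.csv`,
#' `deviation_report.csv`, `group_comparisons.csv` and `manifest.json`;
#' reruns with the same seed and configuration are byte-identical.
#'
#' @param config An `ft4_config` (see [default_config()], [read_config()]).
#' @param input Optional measurement table (data.frame or CSV path); when
#'   given, no simulation is performed.
#' @param seed Master seed for the simulation.
#' @param out_dir Optional output directory (created if needed).
#' @param conf_level Confidence level used throughout.
#' @return A list (invisibly when writing): `measurements`, `table1`,
#'   `bland_altman`, `deviation_report`, `group_comparisons`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), input = NULL,
                         seed = 1L, out_dir = NULL, conf_level = 0.95) {
  stopifnot(inherits(config, "ft4_config"))
  reference <- config$reference
  if (is.null(input)) {
    table <- simulate_measurements(config$profiles, config$calibrations,
                                   config$cv_model, config$constants,
                                   seed = seed, reference = reference)
  } else {
    table <- if (is.character(input)) read_measurement_csv(input) else input
    validate_measurement_table(table)
  }

  table1 <- pb_fit_all(table, reference, conf_level)

  assays <- setdiff(unique(table$method), reference)
  groups <- unique(table$group)
  ba_rows <- list()
  for (a in assays) {
    for (g in groups) {
      s <- paired_series(table, reference, a, g)
      ba <- bland_altman(s$x, s$y, mode = "percent",
                         denominator = "reference",
                         conf_level = conf_level)
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        assay = a, group = g, mode = "percent", bias = ba$bias,
        sd = ba$sd_diff, loa_lo = ba$loa[1], loa_hi = ba$loa[2],
        ci_lo = ba$bias_ci[1], ci_hi = ba$bias_ci[2], p = ba$p_bias,
        n = ba$n, stringsAsFactors = FALSE)
    }
  }
  ba_table <- do.call(rbind, ba_rows)
  ba_table <- ba_table[order(ba_table$assay, ba_table$group), ]
  rownames(ba_table) <- NULL

  dev_rows <- lapply(sort(assays), function(a) {
    rep_ <- cross_population_deviation(table, a, reference, conf_level)
    data.frame(assay = a, control_slope = rep_$control_fit$slope,
               control_intercept = rep_$control_fit$intercept,
               n_pregnant = rep_$ba$n, deviation_pct = rep_$ba$bias,
               loa_lo = rep_$ba$loa[1], loa_hi = rep_$ba$loa[2],
               p = rep_$ba$p_bias, stringsAsFactors = FALSE)
  })
  deviation_report <- do.call(rbind, dev_rows)
  rownames(deviation_report) <- NULL

  comparisons <- group_comparisons(table, reference)

  fingerprint <- settings_fingerprint(config, seed)
  manifest <- list(
    package = "ft4compare",
    version = as.character(utils::packageVersion("ft4compare")),
    seed = seed,
    fingerprint = fingerprint,
    reference = reference,
    n_samples = length(unique(table$sample_id)),
    n_assays = length(assays),
    simulated = is.null(input))

  result <- list(measurements = table, table1 = table1,
                 bland_altman = ba_table,
                 deviation_report = deviation_report,
                 group_comparisons = comparisons, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_output_csv(table, file.path(out_dir, "measurements.csv"),
                     fingerprint)
    write_output_csv(table1, file.path(out_dir, "table1.csv"), fingerprint)
    write_output_csv(ba_table, file.path(out_dir, "bland_altman.csv"),
                     fingerprint)
    write_output_csv(deviation_report,
                     file.path(out_dir, "deviation_report.csv"), fingerprint)
    write_output_csv(comparisons,
                     file.path(out_dir, "group_comparisons.csv"), fingerprint)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(result))
  }
  result
}
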