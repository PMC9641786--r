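# Synthetic serum cohorts and simulated measurements.
#
# Cohorts are generated on the free-hormone scale: free fT4, TBG, albumin
# and TTR are drawn per individual, and total T4 is then back-computed from
# the binding equilibrium so every simulated serum is internally consistent
# with the mass-action model.

#' Distributional profile of a study group
#'
#' Describes how one group's sera are generated: normal draws for free fT4,
#' TBG and albumin (around its median), truncated at physiologic floors
#' (fT4 > 1 pmol/L, TBG > 50 nmol/L, albumin > 15 g/L), and TTR normal with
#' a 10% CV.
#'
#' @param name Group label, `"pregnant"` or `"control"`.
#' @param ft4_mean,ft4_sd Free fT4 mean and SD, pmol/L.
#' @param tbg_mean,tbg_sd TBG mean and SD, nmol/L.
#' @param alb_median,alb_sd Albumin centre and SD, g/L.
#' @param ttr_mean TTR mean, umol/L (default 4.6; shared by both groups).
#' @param n Cohort size (>= 3).
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(name, ft4_mean, ft4_sd, tbg_mean, tbg_sd,
                          alb_median, alb_sd, ttr_mean = 4.6, n = 30) {
  name <- match.arg(name, c("pregnant", "control"))
  if (n < 3) stop("cohort size must be at least 3")
  disp <- c(ft4_sd, tbg_sd, alb_sd)
  if (any(disp < 0)) stop("dispersions must be non-negative")
  if (any(c(ft4_mean, tbg_mean, alb_median, ttr_mean) <= 0)) {
    stop("location parameters must be strictly positive")
  }
  structure(list(name = name, ft4_mean = ft4_mean, ft4_sd = ft4_sd,
                 tbg_mean = tbg_mean, tbg_sd = tbg_sd,
                 alb_median = alb_median, alb_sd = alb_sd,
                 ttr_mean = ttr_mean, n = as.integer(n)),
            class = "group_profile")
}

#' Default pregnant-group profile
#'
#' Free fT4 13.2 (SD 2.5) pmol/L, TBG 802 (SD 184) nmol/L, albumin centred
#' at 29.7 (SD 1.78) g/L.  SDs are back-derived from the printed 95% CIs of
#' the means (SD = half-width * sqrt(n) / 1.96) and, for albumin, from the
#' IQR (SD = IQR / 1.349).
#'
#' @param n Cohort size.
#' @return A [group_profile()].
#' @export
pregnant_profile <- function(n = 30) {
  group_profile("pregnant", ft4_mean = 13.2, ft4_sd = 2.5,
                tbg_mean = 802, tbg_sd = 184,
                alb_median = 29.7, alb_sd = 1.78, n = n)
}

#' Default healthy-control profile
#'
#' Free fT4 19.6 (SD 2.5) pmol/L, TBG 302 (SD 32) nmol/L, albumin centred
#' at 41.8 (SD 4.60) g/L; derivation as in [pregnant_profile()].
#'
#' @param n Cohort size.
#' @return A [group_profile()].
#' @export
control_profile <- function(n = 30) {
  group_profile("control", ft4_mean = 19.6, ft4_sd = 2.5,
                tbg_mean = 302, tbg_sd = 32,
                alb_median = 41.8, alb_sd = 4.60, n = n)
}

# Truncated-normal draws by resampling below the floor; a cohort that still
# violates the floor after the retry cap signals impossible parameters.
rnorm_truncated <- function(n, mean, sd, floor, retries = 1000) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(retries)) {
    bad <- x <= floor
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop(sprintf(
    "could not draw values above the physiologic floor %g after %d retries",
    floor, retries))
}

#' Generate an equilibrium-consistent serum cohort
#'
#' Draws free fT4, TBG, albumin and TTR per individual from the group
#' profile, then back-computes each individual's total T4 with
#' [invert_total_from_free()] so free + bound mass balance holds exactly.
#'
#' @param profile A [group_profile()].
#' @param constants [binding_constants()]; defaults to the canonical
#'   calibration of [calibrate_binding_constants()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A data.frame with one row per individual: `sample_id`, `group`,
#'   `free_t4` (pmol/L), `total_t4` (nmol/L), `tbg` (nmol/L), `ttr`
#'   (umol/L), `albumin_gl` (g/L), `albumin_nm` (nmol/L).
#' @export
sample_cohort <- function(profile, constants = calibrate_binding_constants(),
                          seed = NULL) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(constants, "binding_constants"))
  if (!is.null(seed)) set.seed(seed)
  n <- profile$n
  free_t4 <- rnorm_truncated(n, profile$ft4_mean, profile$ft4_sd, floor = 1)
  tbg <- rnorm_truncated(n, profile$tbg_mean, profile$tbg_sd, floor = 50)
  alb <- rnorm_truncated(n, profile$alb_median, profile$alb_sd, floor = 15)
  ttr <- rnorm_truncated(n, profile$ttr_mean, 0.1 * profile$ttr_mean,
                         floor = 0.5)
  total_t4 <- mapply(function(fr, b, t, a) {
    invert_total_from_free(fr, tbg = b, ttr = t, albumin_gl = a,
                           constants = constants)
  }, free_t4, tbg, ttr, alb)
  data.frame(
    sample_id = sprintf("%s_%02d", profile$name, seq_len(n)),
    group = profile$name,
    free_t4 = free_t4,
    total_t4 = total_t4,
    tbg = tbg,
    ttr = ttr,
    albumin_gl = alb,
    albumin_nm = albumin_gl_to_nmol(alb),
    stringsAsFactors = FALSE
  )
}

#' Concentration-dependent imprecision model
#'
#' Piecewise-linear interpolation of CV against concentration, clamped to
#' the end anchors outside their range.
#'
#' @param concentrations Anchor concentrations, pmol/L, strictly increasing.
#' @param cvs Fractional CVs at the anchors, each in (0, 0.2) (zero allowed
#'   for noise-free checks).
#' @return A list of class `cv_model`.
#' @export
cv_model <- function(concentrations, cvs) {
  if (length(concentrations) != length(cvs) || length(cvs) < 1) {
    stop("need matching, non-empty concentration and CV anchors")
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("anchor concentrations must be strictly increasing")
  }
  if (any(cvs < 0 | cvs >= 0.2)) stop("CVs must lie in [0, 0.2)")
  structure(list(concentrations = concentrations, cvs = cvs),
            class = "cv_model")
}

#' Reference-method (LC-MS/MS) imprecision model
#'
#' Total CV of 3.9% at 13.1 pmol/L and 3.1% at 32.0 pmol/L, interpolated
#' linearly in between and clamped outside.
#'
#' @return A [cv_model()].
#' @export
reference_cv_model <- function() {
  cv_model(c(13.1, 32.0), c(0.039, 0.031))
}

cv_at <- function(model, concentration) {
  if (length(model$concentrations) == 1L) {
    return(rep(model$cvs, length(concentration)))
  }
  stats::approx(model$concentrations, model$cvs, xout = concentration,
                rule = 2)$y
}

#' Simulate the reference (LC-MS/MS) measurement of free fT4
#'
#' Applies unbiased multiplicative noise at the concentration-dependent CV:
#' `measured = true * (1 + eps)`, `eps ~ N(0, cv(true)^2)`.  The stated
#' total CV already describes the reported (triplicate-mean) value, so it is
#' applied once.
#'
#' @param true_ft4 True free fT4 values, pmol/L (vectorized).
#' @param model A [cv_model()]; defaults to [reference_cv_model()].
#' @param seed Optional integer seed.
#' @return Measured fT4, pmol/L.
#' @export
measure_reference <- function(true_ft4, model = reference_cv_model(),
                              seed = NULL) {
  stopifnot(inherits(model, "cv_model"))
  if (!is.null(seed)) set.seed(seed)
  cv <- cv_at(model, true_ft4)
  true_ft4 * (1 + stats::rnorm(length(true_ft4), 0, 1) * cv)
}

#' Group-specific linear immunoassay response
#'
#' An immunoassay is modeled as a linear map of true free fT4 with
#' multiplicative imprecision: `reading = (slope * true + intercept) *
#' (1 + eps)`, `eps ~ N(0, cv^2)`.  An optional mechanistic term
#' `lambda * (tbg - tbg_ref)` adds TBG interference; it is off by default
#' (`lambda = 0`) because interference coefficients are not separately
#' identifiable from group-level calibrations.
#'
#' @param assay Assay name.
#' @param group Group the calibration applies to, `"pregnant"` or
#'   `"control"`.
#' @param slope Dimensionless response slope, > 0.
#' @param intercept Response intercept, pmol/L.
#' @param cv Fractional imprecision in \[0, 0.2\] (default 0.04).
#' @param lambda TBG-interference coefficient, pmol/L per nmol/L.
#' @param tbg_ref TBG reference point for the interference term, nmol/L.
#' @return A list of class `assay_calibration`.
#' @export
assay_calibration <- function(assay, group, slope, intercept, cv = 0.04,
                              lambda = 0, tbg_ref = 302) {
  group <- match.arg(group, c("pregnant", "control"))
  if (slope <= 0) stop("calibration slope must be strictly positive")
  if (cv < 0 || cv > 0.2) stop("assay CV must lie in [0, 0.2]")
  structure(list(assay = assay, group = group, slope = slope,
                 intercept = intercept, cv = cv, lambda = lambda,
                 tbg_ref = tbg_ref),
            class = "assay_calibration")
}

#' Default panel of five immunoassay calibrations
#'
#' Group-specific linear responses of the five automated fT4 immunoassays
#' (Alinity, Atellica, Cobas, Lumipulse, UniCel DXI) relative to the
#' LC-MS/MS reference, one row per assay and group, used as generating
#' truth by the simulator.  Assay imprecision defaults to a 4% CV.
#'
#' @param cv Fractional imprecision applied to every assay.
#' @return A data.frame with columns `assay`, `group`, `slope`,
#'   `intercept`, `cv`.
#' @export
default_assay_calibrations <- function(cv = 0.04) {
  d <- data.frame(
    assay = rep(c("Alinity", "Atellica", "Cobas", "Lumipulse", "UniCel DXI"),
                each = 2),
    group = rep(c("control", "pregnant"), times = 5),
    slope = c(0.41, 0.53, 0.69, 0.65, 0.79, 0.84, 0.71, 0.73, 0.55, 0.58),
    intercept = c(4.37, 3.78, 1.65, 4.67, 0.49, 1.63, -0.004, 0.40,
                  -0.13, 0.47),
    stringsAsFactors = FALSE
  )
  d$cv <- cv
  d
}

#' Simulate one immunoassay measurement per sample
#'
#' @param samples A cohort data.frame from [sample_cohort()] (needs
#'   `free_t4`, `tbg`, `group`).
#' @param calibration An [assay_calibration()] whose `group` matches the
#'   cohort's.
#' @param seed Optional integer seed.
#' @return Assay readings, pmol/L.  Readings that would be negative are
#'   clamped at 0.1 pmol/L with a warning.
#' @export
measure_immunoassay <- function(samples, calibration, seed = NULL) {
  stopifnot(inherits(calibration, "assay_calibration"))
  if (!all(samples$group == calibration$group)) {
    stop(sprintf("calibration is for group '%s' but the cohort contains ",
                 calibration$group), "other groups")
  }
  if (!is.null(seed)) set.seed(seed)
  expected <- calibration$slope * samples$free_t4 + calibration$intercept +
    calibration$lambda * (samples$tbg - calibration$tbg_ref)
  reading <- expected *
    (1 + stats::rnorm(nrow(samples), 0, 1) * calibration$cv)
  n_neg <- sum(reading < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative assay reading(s) clamped at 0.1 pmol/L",
                    n_neg))
    reading[reading < 0] <- 0.1
  }
  reading
}

# Deterministic per-task sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(master, n) {
  s <- as.double(master %% 2147483647L)
  vapply(seq_len(n), function(i) {
    as.integer((s * 48271 + i * 104729) %% 2147483629)
  }, integer(1))
}

#' Simulate a full paired-measurement study
#'
#' Generates one cohort per group profile, measures every sample with the
#' reference method and with each configured immunoassay, and returns the
#' tidy long table the analysis functions consume.
#'
#' @param profiles List of [group_profile()]s (default: pregnant + control).
#' @param calibrations Data.frame like [default_assay_calibrations()]; one
#'   row per assay x group.
#' @param ref_cv_model [cv_model()] for the reference method.
#' @param constants [binding_constants()] for the equilibrium back-solve.
#' @param seed Master seed; per-cohort and per-assay sub-seeds are derived
#'   deterministically from it.
#' @param reference Name given to the reference method in the table.
#' @return A data.frame with columns `sample_id`, `group`, `method`,
#'   `ft4_pmol_l`, `tbg_nmol_l`, `albumin_g_l`, `true_ft4_pmol_l`.
#' @export
simulate_measurements <- function(profiles = list(pregnant_profile(),
                                                  control_profile()),
                                  calibrations = default_assay_calibrations(),
                                  ref_cv_model = reference_cv_model(),
                                  constants = calibrate_binding_constants(),
                                  seed = 1L,
                                  reference = "LC-MS/MS") {
  assays <- unique(calibrations$assay)
  n_tasks <- length(profiles) * (1 + 1 + length(assays))
  seeds <- derive_seeds(seed, n_tasks)
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    seeds[k]
  }
  rows <- list()
  for (profile in profiles) {
    cohort <- sample_cohort(profile, constants, seed = next_seed())
    ref_val <- measure_reference(cohort$free_t4, ref_cv_model,
                                 seed = next_seed())
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = cohort$sample_id, group = cohort$group,
      method = reference, ft4_pmol_l = ref_val,
      tbg_nmol_l = cohort$tbg, albumin_g_l = cohort$albumin_gl,
      true_ft4_pmol_l = cohort$free_t4, stringsAsFactors = FALSE)
    for (a in assays) {
      row <- calibrations[calibrations$assay == a &
                            calibrations$group == profile$name, ]
      if (nrow(row) != 1L) {
        stop(sprintf("need exactly one calibration for assay '%s', group '%s'",
                     a, profile$name))
      }
      cal <- assay_calibration(a, profile$name, row$slope, row$intercept,
                               cv = row$cv)
      val <- measure_immunoassay(cohort, cal, seed = next_seed())
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cohort$sample_id, group = cohort$group,
        method = a, ft4_pmol_l = val,
        tbg_nmol_l = cohort$tbg, albumin_g_l = cohort$albumin_gl,
        true_ft4_pmol_l = cohort$free_t4, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
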