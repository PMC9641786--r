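# Cohort generation and simulated measurements.

test_that("cohorts have the requested size and are equilibrium-consistent", {
  cohort <- sample_cohort(pregnant_profile(n = 12), seed = 11)
  expect_equal(nrow(cohort), 12)
  expect_true(all(cohort$free_t4 > 1))
  expect_true(all(cohort$tbg > 50))
  expect_true(all(cohort$albumin_gl > 15))
  expect_equal(cohort$albumin_nm, cohort$albumin_gl / 66500 * 1e9)

  # total was derived from free via the equilibrium: forward solve returns
  # the free value, and total (pmol/L) exceeds free
  ka <- default_constants
  for (i in seq_len(nrow(cohort))) {
    eq <- solve_free_t4(cohort$total_t4[i], cohort$tbg[i], cohort$ttr[i],
                        cohort$albumin_gl[i], ka)
    expect_equal(eq$free_pmol, cohort$free_t4[i], tolerance = 1e-9)
    expect_lte(eq$residual, 1e-9)
  }
  expect_true(all(cohort$total_t4 * 1000 > cohort$free_t4))
})

test_that("zero dispersion collapses the cohort to identical samples", {
  prof <- group_profile("control", ft4_mean = 19.6, ft4_sd = 0,
                        tbg_mean = 302, tbg_sd = 0, alb_median = 41.8,
                        alb_sd = 0, n = 5)
  # keep TTR stochastic-free by overriding its mean-proportional CV draw:
  # with sd = 0 elsewhere the only variation left is TTR, so compare the
  # deterministic columns only
  cohort <- sample_cohort(prof, seed = 3)
  expect_true(all(cohort$free_t4 == 19.6))
  expect_true(all(cohort$tbg == 302))
  expect_true(all(cohort$albumin_gl == 41.8))
})

test_that("impossible truncation floors raise a generation error", {
  # mean below the 1 pmol/L floor with ~zero spread: cannot succeed
  prof <- group_profile("control", ft4_mean = 0.5, ft4_sd = 1e-9,
                        tbg_mean = 302, tbg_sd = 32, alb_median = 41.8,
                        alb_sd = 4.6, n = 5)
  expect_error(sample_cohort(prof, seed = 1), "floor")
})

test_that("cohort generation is bit-reproducible given a seed", {
  a <- sample_cohort(pregnant_profile(), seed = 99)
  b <- sample_cohort(pregnant_profile(), seed = 99)
  expect_identical(a, b)
  c <- sample_cohort(pregnant_profile(), seed = 100)
  expect_false(identical(a, c))
})

test_that("pregnant cohorts have higher TBG than controls in paired draws", {
  higher <- vapply(1:60, function(s) {
    p <- sample_cohort(pregnant_profile(), seed = 2 * s)
    c <- sample_cohort(control_profile(), seed = 2 * s + 1)
    mean(p$tbg) > mean(c$tbg)
  }, logical(1))
  expect_true(mean(higher) >= 0.99)
})

test_that("reference measurement applies the interpolated CV, unbiased", {
  # anchors: 3.9% at 13.1 pmol/L, 3.1% at 32.0 pmol/L
  m <- reference_cv_model()
  set.seed(5)
  reps <- measure_reference(rep(13.1, 20000), m)
  expect_equal(sd(reps) / 13.1, 0.039, tolerance = 0.03)
  expect_equal(mean(reps), 13.1, tolerance = 0.01)

  reps32 <- measure_reference(rep(32, 20000), m, seed = 6)
  expect_equal(sd(reps32) / 32, 0.031, tolerance = 0.031 * 0.04)

  # all-zero CV returns the truth exactly
  exact <- measure_reference(c(10, 20), cv_model(c(1, 50), c(0, 0)), seed = 1)
  expect_identical(exact, c(10, 20))

  # clamped outside the anchors
  expect_equal(ft4compare:::cv_at(m, 5), 0.039)
  expect_equal(ft4compare:::cv_at(m, 100), 0.031)
})

test_that("immunoassay measurement applies the group linear map", {
  cohort <- data.frame(sample_id = "s1", group = "control", free_t4 = 19.6,
                       tbg = 302)
  cal <- assay_calibration("Alinity", "control", slope = 0.41,
                           intercept = 4.37, cv = 0)
  expect_equal(measure_immunoassay(cohort, cal), 0.41 * 19.6 + 4.37)

  # identity calibration
  ident <- assay_calibration("id", "control", slope = 1, intercept = 0,
                             cv = 0)
  expect_equal(measure_immunoassay(cohort, ident), 19.6)

  # mean over noisy replicates converges to the linear map (12.41 pmol/L)
  noisy <- assay_calibration("Alinity", "control", 0.41, 4.37, cv = 0.04)
  big <- cohort[rep(1, 20000), ]
  reps <- measure_immunoassay(big, noisy, seed = 8)
  expect_equal(mean(reps), 12.406, tolerance = 0.01)
  expect_equal(sd(reps) / mean(reps), 0.04, tolerance = 0.02)

  # group mismatch refused; negative readings clamped with a warning
  expect_error(measure_immunoassay(transform(cohort, group = "pregnant"),
                                   cal), "group")
  neg <- assay_calibration("neg", "control", slope = 0.01, intercept = -5,
                           cv = 0)
  expect_warning(v <- measure_immunoassay(cohort, neg), "clamped")
  expect_equal(v, 0.1)
})

test_that("simulated study table is tidy, complete and reproducible", {
  tab <- simulate_measurements(seed = 21)
  expect_named(tab, c("sample_id", "group", "method", "ft4_pmol_l",
                      "tbg_nmol_l", "albumin_g_l", "true_ft4_pmol_l"))
  validate_measurement_table(tab)
  # 2 groups x 30 samples x (reference + 5 assays)
  expect_equal(nrow(tab), 2 * 30 * 6)
  expect_setequal(unique(tab$method),
                  c("LC-MS/MS", "Alinity", "Atellica", "Cobas", "Lumipulse",
                    "UniCel DXI"))
  expect_identical(tab, simulate_measurements(seed = 21))
  expect_false(identical(tab, simulate_measurements(seed = 22)))
})
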