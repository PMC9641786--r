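# Summaries, t test, Mann-Whitney U, normality gate, per-assay tests.

test_that("summaries match their closed forms", {
  s <- summarize_values(c(1, 2, 3), "mean_ci")
  expect_equal(s$estimate, 2)
  expect_equal(s$upper - s$estimate, qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(c(s$lower, s$upper), c(-0.4841377, 4.4841377),
               tolerance = 1e-6)

  sm <- summarize_values(1:100, "median_iqr")
  expect_equal(sm$estimate, 50.5)
  expect_equal(c(sm$lower, sm$upper), c(25.75, 75.25))

  # constant vector: zero-width CI
  sc <- summarize_values(rep(7, 4), "mean_ci")
  expect_equal(c(sc$lower, sc$estimate, sc$upper), c(7, 7, 7))

  expect_error(summarize_values(1), "degenerate")
})

test_that("independent t test matches the hand computation", {
  cmp <- t_test_independent(c(10, 11, 12), c(13, 14, 15))
  expect_equal(cmp$statistic, -3 / sqrt(2/3), tolerance = 1e-6)  # -3.674
  expect_equal(cmp$p, 2 * pt(-3 / sqrt(2/3), df = 4), tolerance = 1e-9)
  expect_equal(round(cmp$p, 4), 0.0213)

  same <- t_test_independent(c(10, 11, 12), c(10, 11, 12))
  expect_equal(same$p, 1)

  # zero pooled variance, different means -> exact-agreement flag
  flag <- t_test_independent(rep(1, 3), rep(2, 3))
  expect_true(flag$exact_agreement)
  expect_true(is.na(flag$p))

  # welch equals stats::t.test default
  set.seed(2)
  a <- rnorm(12); b <- rnorm(15, 0.5, 2)
  expect_equal(t_test_independent(a, b, "welch")$p, t.test(a, b)$p.value)
})

test_that("Mann-Whitney exact enumeration matches brute force and wilcox", {
  cmp <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1/3)
  expect_equal(cmp$method, "exact")

  # identical multisets: U = n^2 / 2
  tie <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$statistic, 4.5)

  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:20, 5, replace = TRUE)  # replacement forces ties
    b <- sample(1:20, 6, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, mw_brute_p(a, b))
  }

  # without ties the enumeration agrees with the exact Wilcoxon
  # distribution used by stats::wilcox.test
  for (i in 1:10) {
    a <- sample(seq(1, 200, by = 1), 6)
    b <- sample(seq(0.5, 199.5, by = 1), 6)
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks the exact p at moderate n", {
  set.seed(88)
  for (i in 1:10) {
    a <- rnorm(12)
    b <- rnorm(12, 0.4)
    approx_p <- mann_whitney_u(a, b, exact_max = 12)$p  # 24 > 12: normal
    exact_p <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("normality gate routes as expected", {
  set.seed(10)
  passes <- replicate(200, normality_gate(rnorm(100))$decision == "normal")
  expect_equal(mean(passes), 0.95, tolerance = 0.05)

  skewed <- replicate(100,
    normality_gate(exp(rnorm(30, 0, 1)))$decision == "non_normal")
  expect_gt(mean(skewed), 0.8)

  expect_equal(normality_gate(rep(1, 3))$decision, "non_normal")
  expect_equal(normality_gate(c(1, 2))$decision, "non_normal")
})

test_that("group label swap preserves p and swaps estimates", {
  set.seed(11)
  a <- rnorm(20, 10); b <- rnorm(20, 11)
  t1 <- t_test_independent(a, b); t2 <- t_test_independent(b, a)
  expect_equal(t1$p, t2$p)
  expect_equal(t1$estimate_1, t2$estimate_2)
  m1 <- mann_whitney_u(a, b); m2 <- mann_whitney_u(b, a)
  expect_equal(m1$p, m2$p)
  expect_equal(m1$statistic + m2$statistic, 400)  # U1 + U2 = n_a n_b
})

test_that("simulated group contrasts are overwhelmingly significant", {
  sig <- vapply(1:30, function(s) {
    p <- sample_cohort(pregnant_profile(), seed = 1000 + s)$free_t4
    c <- sample_cohort(control_profile(), seed = 2000 + s)$free_t4
    t_test_independent(p, c)$p < 1e-4
  }, logical(1))
  expect_gte(mean(sig), 0.99)
})

test_that("per-assay percent differences and paired tests behave", {
  tab <- simulate_measurements(seed = 61)
  res <- method_vs_reference_tests(tab, "control")
  expect_setequal(res$assay, c("Alinity", "Atellica", "Cobas", "Lumipulse",
                               "UniCel DXI"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # all assays read low in controls; UniCel lowest, Cobas least low
  expect_true(all(res$mean_pct_diff < 0))
  expect_equal(res$assay[which.min(res$mean_pct_diff)], "UniCel DXI")
  expect_equal(res$assay[which.max(res$mean_pct_diff)], "Cobas")

  # sign equals sign of (slope - 1) * mean + intercept for the generator
  cal <- default_assay_calibrations()
  for (i in seq_len(nrow(res))) {
    row <- cal[cal$assay == res$assay[i] & cal$group == "control", ]
    expect_equal(sign(res$mean_pct_diff[i]),
                 sign((row$slope - 1) * 19.6 + row$intercept))
  }

  # an assay identical to the reference gives 0% and p = 1
  ref <- tab[tab$method == "LC-MS/MS", ]
  clone <- transform(ref, method = "Clone")
  res2 <- method_vs_reference_tests(rbind(tab, clone), "control")
  crow <- res2[res2$assay == "Clone", ]
  expect_equal(crow$mean_pct_diff, 0)
  expect_equal(crow$p, 1)
})

test_that("group_comparisons routes via the gate and finds the contrasts", {
  tab <- simulate_measurements(seed = 62)
  gc <- group_comparisons(tab)
  expect_setequal(gc$variable, c("ft4_pmol_l", "tbg_nmol_l", "albumin_g_l"))
  expect_true(all(gc$p >= 0 & gc$p <= 1))
  expect_true(all(gc$p < 1e-4))
  ft4 <- gc[gc$variable == "ft4_pmol_l", ]
  expect_lt(ft4$estimate_pregnant, ft4$estimate_control)
  tbg <- gc[gc$variable == "tbg_nmol_l", ]
  expect_gt(tbg$estimate_pregnant, tbg$estimate_control)
  alb <- gc[gc$variable == "albumin_g_l", ]
  expect_lt(alb$estimate_pregnant, alb$estimate_control)
})
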