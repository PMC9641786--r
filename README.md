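# ft4compare

Method-comparison tools for free thyroxine (fT4) measurement, built
around one clinical question: **how much of an automated immunoassay's
disagreement with the equilibrium-dialysis LC-MS/MS reference method is
specific to a patient population's serum matrix?** The motivating case is
pregnancy, where thyroxine-binding globulin (TBG) roughly triples and
albumin falls, and where immunoassays read fT4 falsely high relative to
the reference even after their ordinary calibration difference has been
removed.

The package is aimed at clinical chemists and biostatisticians running or
re-analysing method-comparison studies (one reference method, one or more
comparator assays, two populations), and at anyone who needs a
physiologically structured simulator of free-hormone measurements.

## What it computes

**Passing–Bablok regression.** For paired series $(x_i, y_i)$ the slope
is the shifted median of all pairwise slopes
$S_{ij} = (y_j - y_i)/(x_j - x_i)$: with $K$ slopes below $-1$ and $n_s$
valid slopes, $\hat\beta$ is the $(n_s/2 + K)$-th order statistic, with
rank-based confidence bounds at $M_{1,2}$ from
$C = z_{(1+\gamma)/2}\sqrt{N(N-1)(2N+5)/18}$, and
$\hat\alpha = \mathrm{median}(y_i - \hat\beta x_i)$. Scale-invariant,
robust to error on both axes — the standard regression for method
comparison.

**Bland–Altman analysis.** Per-sample differences (absolute or percent;
percent denominator defaults to the reference value), bias, 1.96-SD
limits of agreement, t-based bias CI and p.

**Cross-population recalibration.** The study design's core step: fit
Passing–Bablok in healthy controls, map the pregnant group's assay
values onto the reference scale via $(v - \hat\alpha)/\hat\beta$, then
Bland–Altman the recalibrated values against the reference. The
resulting percent bias is the population-specific (matrix) deviation; it
is zero when the assay behaves identically in both populations.

**Group statistics.** Student/Welch t and Mann–Whitney U (exact
enumeration at pooled n ≤ 12, tie- and continuity-corrected normal
approximation otherwise), routed by a Shapiro–Wilk normality gate;
mean/95% CI and median/IQR summaries; per-assay paired tests against the
reference.

**Synthetic serum generator.** Cohorts are drawn on the free-fT4 scale
with group-specific fT4/TBG/albumin distributions, and each individual's
total T4 is back-computed from the mass-action equilibrium
`total = F + Σ P_i·Ka_i·F/(1 + Ka_i·F)` so the sera are
equilibrium-consistent. Association constants are calibrated so that, at
a control-typical serum, the bound pool splits 75:10:12 across
TBG:transthyretin:albumin with a free fraction of exactly 0.02%.
Measurements add reference-method noise (CV interpolated between 3.9% at
13.1 pmol/L and 3.1% at 32 pmol/L) and group-specific linear immunoassay
responses with 4% CV (a five-assay panel of published control/pregnant
calibrations ships as the default generating truth).

## Worked example

```r
library(ft4compare)

res <- run_pipeline(seed = 1)   # simulate 30 + 30 sera, 5 assays, analyse
res$deviation_report
#>        assay control_slope control_intercept n_pregnant deviation_pct loa_lo loa_hi        p
#> 1    Alinity         0.457             3.432         30         23.50   6.62   40.4 3.69e-15
#> 2   Atellica         0.742             0.666         30         29.81   6.16   53.5 4.62e-14
#> 3      Cobas         0.838            -0.287         30         19.09   3.85   34.3 5.46e-14
#> 4  Lumipulse         0.727            -0.241         30          5.89  -5.39   17.2 4.74e-06
#> 5 UniCel DXI         0.601            -1.077         30         17.48   1.48   33.5 1.57e-12
```

Each row is one assay's pregnancy-specific deviation: the Passing–Bablok
fit estimated in controls (`control_slope`, `control_intercept`), and the
mean percent deviation of the pregnant group's *recalibrated* readings
from the reference (`deviation_pct`, with limits of agreement and the
one-sample-t p-value). Every deviation is positive — all five simulated
assays read falsely high in the pregnant matrix after control-based
recalibration — ranging here from +5.9% (Lumipulse) to +29.8% (Atellica).

```r
res$group_comparisons[, c("variable", "test", "estimate_pregnant", "estimate_control", "p")]
#>      variable                  test estimate_pregnant estimate_control        p
#> 1  ft4_pmol_l t_independent_student              13.4             19.9 9.99e-15
#> 2  tbg_nmol_l t_independent_student             793.1            304.5 7.29e-19
#> 3 albumin_g_l t_independent_student              29.7             42.3 6.60e-20
```

The simulated populations separate exactly as the physiology dictates:
lower fT4, much higher TBG and lower albumin in pregnancy.

Individual stages are available directly — `pb_fit()`, `bland_altman()`,
`cross_population_deviation()`, `sample_cohort()`,
`simulate_measurements()` — and `run_pipeline(out_dir = ...)` writes the
full CSV report bundle plus a run manifest; reruns with the same seed are
byte-identical. A command-line wrapper lives at
`inst/scripts/ft4compare.R` (`simulate` / `analyze` / `report`).

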