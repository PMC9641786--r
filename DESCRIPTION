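Package: ft4compare
Title: Method Comparison of Free Thyroxine Immunoassays Against an
    Equilibrium-Dialysis LC-MS/MS Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the accuracy of automated free thyroxine
    (fT4) immunoassays against an equilibrium-dialysis LC-MS/MS reference
    method, with emphasis on population-specific matrix bias such as the
    falsely high immunoassay readings observed in pregnancy. Provides
    Passing-Bablok nonparametric regression with rank-based confidence
    intervals, Bland-Altman limits-of-agreement analysis in absolute and
    percent terms, a cross-population recalibration procedure that maps
    assay results onto the reference scale using a healthy-control fit and
    quantifies the residual bias in a second population, and the group
    comparison statistics used in method-comparison studies. A synthetic
    serum generator emulates the mass-action partitioning of thyroxine
    among thyroxine-binding globulin (TBG), transthyretin and albumin, the
    TBG/albumin shifts of pregnancy, group-specific linear immunoassay
    calibrations and reference-method imprecision, so the full pipeline can
    be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
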