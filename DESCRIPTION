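Package: ldltools
Title: LDL Cholesterol Estimation with Fixed and Adjustable Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates low-density lipoprotein cholesterol (LDL-C) from a
    standard lipid panel using the Friedewald formula, alternative fixed
    triglyceride-to-VLDL-C divisors, the McNamara triglyceride-banded factors,
    and Martin-style adjustable factors looked up in strata-specific median
    TG:VLDL-C ratio tables. Derives such factor tables (5-cell by triglyceride
    strata, 25-cell by triglyceride and non-HDL-C strata, or arbitrary grids)
    from any cohort with directly measured LDL-C, classifies values by the
    NCEP-ATP III guideline cutoffs, and evaluates estimators against direct
    measurement: concordance tables with Wald confidence intervals,
    under/over-classification direction, exact McNemar and Wilcoxon
    signed-rank tests, Mood's median test, one-way ANOVA with Tamhane T2
    letter groupings, difference-distribution summaries, and a multiple
    regression variance decomposition of VLDL-C. A seeded synthetic-cohort
    generator reproduces the statistical structure the method assumes so the
    whole pipeline is testable without survey microdata.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
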