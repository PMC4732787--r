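---
title: "Estimating LDL-C with fixed and adjustable triglyceride factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating LDL-C with fixed and adjustable triglyceride factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldltools)
```

## The estimation problem

A standard fasting lipid panel measures total cholesterol (TC), HDL-C and
triglycerides (TG) directly, but LDL-C — the quantity treatment guidelines
act on — is usually *calculated*. The classical route is the Friedewald
formula,

$$\widehat{LDL} = (TC - HDL) - TG/5,$$

which buries a strong assumption: that the cholesterol content of VLDL
particles is always one fifth of the triglyceride level. In reality the
TG:VLDL-C ratio varies systematically — it rises with TG itself and falls
with non-HDL-C — so a fixed divisor of 5 overestimates VLDL-C (and hence
underestimates LDL-C) in hypertriglyceridemic subjects and does the
opposite at low TG. The adjustable-factor family of methods replaces the 5
with a divisor looked up in a table of *strata-specific median TG:VLDL-C
ratios*, indexed by the subject's TG band and optionally their non-HDL-C
band:

$$\widehat{LDL} = (TC - HDL) - TG/AF(TG,\, \mathrm{nonHDL}).$$

Everything in this package lives in mg/dL; none of the equations survive a
silent unit change, so no mmol/L conversion is offered. All estimators
refuse TG at or above 400 mg/dL, the classical validity ceiling of the
whole divisor family (configurable via `tg_max` for sensitivity work).

The package provides four estimator variants: Friedewald
(`ldl_friedewald()`), an arbitrary fixed divisor (`ldl_fixed_factor()`,
covering the 4 and 6 proposed in the older literature), the TG-banded
McNamara divisors (`ldl_mcnamara()`: 4 for TG ≤ 50, 4.5 for 50–200, 5
above 200 mg/dL — note the closed lower band, the one interval convention
that differs from the rest of the package), and the table-driven
adjustable factor (`ldl_adjustable()`).

## Deriving factor tables

Given any cohort with directly measured LDL-C, `derive_ratio_table()`
computes VLDL-C by subtraction (`nonHDL − LDL_direct`), bins subjects into
a TG × non-HDL-C grid, and stores the *median* TG:VLDL-C ratio of each
cell. Conventions worth stating explicitly:

* **Half-open bins.** Every stratum is `[lo, hi)`; a value equal to an
  interior edge belongs to the band above. Printed band labels such as
  "50 to 99" tile the axis without gaps only under this reading, and it
  generalises to non-integer inputs. The default grids are TG edges
  50/100/150/200 (ceiling 400) and non-HDL-C edges 100/130/160/190.
* **Median.** Midpoint-of-two for even *n* — the common convention; no
  interpolation alternative changes any shipped value.
* **Non-positive VLDL-C.** A subject whose computed VLDL-C is ≤ 0 cannot
  contribute a meaningful ratio; such subjects are dropped from ratio
  computation only (with a logged count) and retained everywhere else.
* **No winsorising.** Extreme ratios are left alone; cell medians are
  robust to them by construction.
* **Empty cells** are stored as `NA` and *refuse lookups* rather than
  falling back to a neighbour — a silent fallback would disguise a table
  that is too fine for its cohort.

`stratum_summaries()` reports, per TG band, the median ratio with a
distribution-free 95% CI of the median (the order-statistic/binomial
interval: the widest symmetric pair of order statistics whose exact
coverage reaches 95%). The method is exact and assumption-free; because
coverage is discrete, the *achieved* coverage (always ≥ 95% where the
sample supports it) is reported alongside — this is also the natural
reading of the "95.1%"-style annotations that accompany published median
CIs in this literature. The reciprocal VLDL-C:TG ratio is summarised as
mean (SD), which is the scale on which the band comparison by one-way
ANOVA with Tamhane's T2 operates.

Two shipped tables (`ldl_table_5cell()`, `ldl_table_25cell()`) carry the
published Korean-adult median ratios at their printed precision (2 and
1 decimal places); they round-trip losslessly through the JSON and CSV
interchange formats. The 180-cell Martin table is accepted as a
user-supplied file in the same format but its values are deliberately not
bundled.

## Guideline concordance and the validation battery

`classify_ncep()` maps LDL-C to the six NCEP-ATP III categories cut at
70/100/130/160/190 mg/dL, half-open upward (a value of 70 is "70–99").
Estimates are classified **unrounded**: rounding is a formatting concern,
and no classification rule in the guideline mentions it. Negative
estimates — possible at high TG with a small non-HDL-C — are never
clipped; they flow into "<70", which is also where any clipping rule
would have put them, but without hiding the estimator's failure mode
(each estimate carries a `negative` flag).

`concordance_report()` cross-tabulates estimate-defined versus
direct-defined categories. One subtlety is load-bearing: per-category
rows are *estimate-defined* — the denominator of the "<70" row counts
subjects whose *estimate* says <70, while the direct-defined count per
category is reported separately as `n_direct`. The two disagree in
general (that is the point of the comparison), and conflating them is a
common reading error of published concordance tables. Partition
identities (category-wise and TG-stratum-wise concordant counts summing
to the overall count; under + over + concordant = total) are enforced by
construction and fuzz-tested.

The inferential toolkit is deliberately exact where sample sizes allow:

* `mcnemar_exact()` — exact binomial McNemar on the discordant pairs,
  `p = min(1, 2·P(X ≤ min(n01, n10)))`, `X ~ Bin(n01+n10, ½)`. Raw
  p-values are reported; no multiplicity adjustment is applied across
  method pairs, matching standard practice when each pairwise contrast is
  interpreted on its own.
* `wilcoxon_signed_rank()` — zeros dropped before ranking, midranks for
  ties, and the positive/negative rank sums SP and SN reported with the
  direction they imply. For ≤ 25 nonzero differences the null
  distribution of SP is computed *exactly under ties* by a dynamic
  program over the doubled midranks (doubling makes them integers);
  above that, the normal approximation with the usual tie correction and
  no continuity correction. The exact path is property-tested against
  full 2ⁿ sign enumeration.
* `mood_median_test()` — dichotomise at the grand median (strictly above
  versus at-or-below), Pearson chi-square without continuity correction,
  with a Fisher-exact fallback for sparse 2 × 2 tables.
* `anova_with_tamhane()` — one-way ANOVA, then Tamhane T2 (pairwise Welch
  t statistics, Šidák-adjusted) rendered as a compact letter display via
  the insert-and-absorb algorithm; groups sharing a letter are not
  significantly different at α = 0.05.
* `difference_summary()` — median, IQR, 5th–95th and 1st–99th percentile
  spans of estimate − direct. Quantiles use the (n+1)p
  linear-interpolation rule (`type = 6`), the convention of the major
  commercial statistics packages in which this class of lipid study is
  normally analysed; R's default type 7 differs in the second decimal at
  these sample sizes.
* `variance_decomposition()` — OLS of computed VLDL-C on any subset of
  TG, non-HDL-C, HDL-C and age, with zero-order and partial correlations
  (residual-on-residual) and adjusted R². This quantifies *why* TG is the
  first stratification axis and non-HDL-C the second: TG alone carries
  most of the explainable VLDL-C variance.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, so the full pipeline is testable without survey microdata:

* TG lognormal with median ≈ 106 and IQR ≈ 71–157 mg/dL below the
  ceiling (`meanlog = log 106`, `sdlog = 0.59`, the value implied by that
  IQR); about 2.6% of subjects drawn from a high-TG tail (median ≈ 505,
  `sdlog = 0.28`).
* VLDL-C:TG ratio Normal within TG bands — means
  0.398/0.255/0.197/0.180/0.167 and SDs 0.178/0.091/0.055/0.048/0.041 in
  the five default bands, truncated below at 0.02 (which caps TG:VLDL-C
  at 50; observed maxima in real cohorts are larger, but medians and
  every quantity this package computes from them are insensitive to that
  tail). The high-TG tail uses mean 0.15, SD 0.04 — the published
  dispersion for that band appears garbled in its source table, so the SD
  is chosen to continue the adjacent band's scale.
* VLDL-C is `ratio × TG` — *generated from the ratio model*, not drawn
  independently, so the over/under-estimation geometry of the fixed
  factor (too high at low TG, too low at high TG) emerges automatically
  from the decreasing ratio means.
* Direct LDL-C lognormal (median ≈ 111, `sdlog = 0.28`), HDL-C Normal
  (48, SD 10.4, truncated positive) — both drawn independently of TG,
  which suffices for every property tested here but is *not* a
  population claim.
* TC is assembled as `HDL + LDL_direct + VLDL (+ noise)`, never drawn:
  the subtraction identities the derivation relies on hold exactly by
  construction when `assay_noise_sd = 0` (the default), and the noise
  term, when used, enters TC so that subtraction-computed VLDL-C absorbs
  it, as it would with a real assay.
* Age and sex are uninformative placeholders (uniform 20–87,
  Bernoulli ½): no stage of this pipeline conditions on them, and
  pretending to model them would imply a fidelity the generator does not
  have.

What passing tests on this generator show: the derivation, lookup,
classification and testing machinery are correct, and the *qualitative*
pattern — the fixed factor 5 degrading most in the 200–399 mg/dL TG
stratum, adjustable factors recovering most of that loss — follows from
the ratio structure alone. What they do not show: the published
magnitudes for any real population, which depend on joint structure
(TG–LDL correlation, assay chemistry) the generator deliberately omits.

Two subtleties in the recovery tooling:

* **Truncation shifts medians.** With the widest band's ratio SD (0.178),
  truncating at 0.02 moves the band's true median TG:VLDL-C visibly
  (≈ 2.65 where 1/mean would say 2.71). `stratum_means_for_ratio_medians()`
  inverts the truncated-Normal median so "configure the generator so band
  medians equal these targets" means exactly that, and table recovery is
  a genuine parameter-recovery exercise rather than a biased one.
* **Exactness is engineered.** `generate_noiseless_cohort()` promises
  *bitwise* recovery of its configured ratios. Floating-point division
  does not round-trip for free, so the generator uses integer VLDL-C
  values (making the `TC − HDL − LDL` chain exact) and restricts TG to
  `vldl × ratio` products whose quotient reproduces `ratio` without
  rounding error.

## Numerical and interface choices

* Quantile rule, median CI method, tie handling and the exact-test
  switchover (`exact_limit = 25`) are all stated above; each is the
  choice a referee could reconstruct from the output.
* The identity `estimate + TG/factor + HDL = TC` is algebraically exact
  and holds bitwise for most panels, but double rounding can leave a
  1-ulp residual; tests assert it at machine precision
  (`≤ 4·eps·TC`), and the one identity that *is* asserted bitwise —
  a constant-5 table reproducing Friedewald — holds because both paths
  execute the same arithmetic.
* Wald proportion CIs are computed on the *unrounded* proportion and
  truncated to [0, 100]. Published tables in this area sometimes derive
  the CI from the already-rounded percentage, which can move an endpoint
  by 0.1; that quirk is intentionally not replicated.
* Report formatting follows the field's print conventions — percentages
  to one decimal, factors to two, mg/dL to one — while JSON output keeps
  full precision.
* Exit codes of the command-line wrapper: 0 success, 2 input/validation
  error, 3 when every subject is outside the TG validity range.

Problem sizes used in the shipped checks — cohorts of 5,642 for the
pipeline demonstrations (with ~2.6% landing above the TG ceiling and
being excluded, mirroring a realistic screening cohort), 10,000 subjects
per band for stochastic table recovery, 2ⁿ enumeration up to n = 10 and
exact-path verification to n = 25 — were chosen as the smallest sizes at
which each property is statistically unambiguous.

## Known limitations

* The generator models marginals and the band-wise ratio law, not the
  joint distribution of a real population; concordance magnitudes on it
  are indicative, not transferable.
* Direct-LDL assay chemistry (homogeneous assays versus β-quantification)
  biases any subtraction-defined VLDL-C and therefore any derived table;
  the package treats the measurement as given and takes no position on
  assay correction.
* Survey design weights are out of scope: all statistics are unweighted,
  so applying the toolkit to complex-survey data analyses the sample, not
  the population.
* The McNemar comparisons use per-subject concordance indicators; if a
  published comparison collapsed categories into a different paired
  table, its p-values need not match.
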