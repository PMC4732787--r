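test_that("derived lipid identities hold and ratios vanish with their denominators", {
  d <- compute_derived(lipid_panel(tc = 184, hdl = 48, tg = 106, ldl_direct = 111))
  expect_identical(d$non_hdl, 136)
  expect_identical(d$vldl, 25)
  expect_equal(d$tg_vldl_ratio, 4.24)
  expect_equal(d$tg_vldl_ratio * d$vldl_tg_ratio, 1)

  # zero TG: both ratios undefined or vldl_tg absent
  d0 <- compute_derived(lipid_panel(tc = 100, hdl = 100, tg = 0))
  expect_identical(d0$non_hdl, 0)
  expect_true(is.na(d0$vldl_tg_ratio))

  # zero VLDL-C: tg_vldl_ratio absent, not Inf
  dz <- compute_derived(lipid_panel(tc = 200, hdl = 50, tg = 80, ldl_direct = 150))
  expect_identical(dz$vldl, 0)
  expect_true(is.na(dz$tg_vldl_ratio))

  # missing direct LDL-C: vldl and ratios absent, no error
  dm <- compute_derived(lipid_panel(tc = 184, hdl = 48, tg = 106))
  expect_true(is.na(dm$vldl) && is.na(dm$tg_vldl_ratio))
})

test_that("cohort construction rejects invariant violations row-wise", {
  expect_error(lipid_cohort(data.frame(tc = 100, hdl = 120, tg = 50)), "tc >= hdl")
  expect_error(lipid_cohort(data.frame(tc = 100, hdl = 50, tg = -1)), "tg >= 0")
  expect_error(lipid_cohort(data.frame(tc = 100, tg = 50)), "hdl")
  expect_error(lipid_cohort(data.frame(tc = 100, hdl = 50, tg = 5, ldl_direct = -2)),
               "ldl_direct")
})

test_that("fixed-factor estimators reproduce hand arithmetic", {
  p <- lipid_panel(tc = 184, hdl = 48, tg = 106)
  expect_equal(ldl_friedewald(p)$value, 114.8)
  expect_identical(ldl_friedewald(p)$factor_used, 5)
  expect_equal(ldl_fixed_factor(p, 6)$value, 136 - 106 / 6)
  expect_equal(ldl_fixed_factor(p, 4)$value, 109.5)
  expect_identical(ldl_fixed_factor(p, 5)$value, ldl_friedewald(p)$value)
  # zero-TG identity
  expect_identical(ldl_friedewald(lipid_panel(tc = 184, hdl = 48, tg = 0))$value, 136)
  expect_error(ldl_fixed_factor(p, 0), "positive")
})

test_that("the TG validity ceiling is enforced with an informative error", {
  p400 <- lipid_panel(tc = 220, hdl = 40, tg = 400)
  expect_error(ldl_friedewald(p400), "400")
  expect_error(ldl_mcnamara(p400), "400")
  expect_error(ldl_adjustable(p400, ldl_table_5cell()), "400")
  # configurable ceiling
  expect_silent(ldl_friedewald(p400, tg_max = 500))
})

test_that("McNamara factors switch at 50 (closed) and 200 mg/dL", {
  at <- function(tg) ldl_mcnamara(lipid_panel(tc = 184, hdl = 48, tg = tg))$factor_used
  expect_identical(at(50), 4)
  expect_identical(at(50.01), 4.5)
  expect_identical(at(200), 4.5)
  expect_identical(at(250), 5)
  expect_equal(ldl_mcnamara(lipid_panel(tc = 184, hdl = 48, tg = 120))$value, 136 - 120 / 4.5)
})

test_that("factor lookup follows the half-open strata of the shipped tables", {
  t25 <- ldl_table_25cell()
  t5 <- ldl_table_5cell()
  expect_identical(lookup_factor(t25, tg = 120, non_hdl = 140), 5.1)
  expect_identical(lookup_factor(t25, tg = 30, non_hdl = 200), 2.1)
  expect_identical(lookup_factor(t5, tg = 250, non_hdl = 999), 6.21)
  expect_identical(lookup_factor(t5, tg = 250), 6.21)  # TG-only ignores non_hdl
  # boundary conventions: the edge belongs to the upper band
  expect_identical(lookup_factor(t25, tg = 100, non_hdl = 130), 5.1)
  expect_identical(lookup_factor(t25, tg = 99.999, non_hdl = 129.999), 4.2)
  expect_error(lookup_factor(t5, tg = 400), "validity")
})

test_that("adjustable estimator applies the looked-up factor", {
  t25 <- ldl_table_25cell()
  expect_equal(ldl_adjustable(lipid_panel(tc = 188, hdl = 48, tg = 120), t25)$value,
               140 - 120 / 5.1)
  expect_equal(ldl_adjustable(lipid_panel(tc = 160, hdl = 45, tg = 40), t25)$value,
               115 - 40 / 2.7)
})

test_that("an all-constant table reduces the adjustable estimator to its fixed twin", {
  cohort <- random_panels(500, seed = 4)
  for (f in c(4, 5, 6.5)) {
    tab <- constant_factor_table(f)
    # low factors push some random panels negative; the flag itself is
    # tested elsewhere
    expect_identical(suppressWarnings(ldl_adjustable(cohort, tab)$value),
                     suppressWarnings(ldl_fixed_factor(cohort, f)$value))
  }
})

test_that("estimates are monotone decreasing in TG and re-sum to total cholesterol", {
  set.seed(3)
  tg <- sort(runif(50, 0, 399))
  vals <- vapply(tg, function(t) ldl_friedewald(lipid_panel(tc = 200, hdl = 50, tg = t))$value,
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  # re-summing reconstructs total cholesterol to machine precision
  cohort <- random_panels(1000, seed = 8)
  est <- suppressWarnings(ldl_mcnamara(cohort))
  resid <- abs(cohort$hdl + est$value + cohort$tg / est$factor_used - cohort$tc)
  expect_true(all(resid <= 4 * .Machine$double.eps * cohort$tc))
})

test_that("negative estimates are flagged and returned unclipped", {
  p <- lipid_panel(tc = 100, hdl = 60, tg = 390)
  expect_warning(est <- ldl_friedewald(p), "negative")
  expect_lt(est$value, 0)
  expect_true(est$negative)
})

test_that("factor tables round-trip through JSON and CSV losslessly", {
  tab <- factor_table(tg_edges = c(50, 100, 150, 200),
                      factors = matrix(c(2.8, 2.7, NA, 3.9, 4.2,
                                         4.2, 4.0, 3.9, 3.8, 5.5,
                                         5.5, 5.1, 4.9, 4.5, 6.3,
                                         6.1, 5.9, 5.5, 4.9, 7.1,
                                         6.7, 6.4, 6.2, 5.5, 6.21), 5, 5),
                      nonhdl_edges = c(100, 130, 160, 190),
                      label = "round-trip demo", tg_max = 380)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_factor_table(tab, jpath)
  back <- read_factor_table(jpath)
  expect_identical(unclass(back), unclass(tab))
  write_factor_table_csv(tab, cpath)
  back2 <- read_factor_table_csv(cpath)
  expect_identical(unclass(back2), unclass(tab))
})

test_that("empty table cells refuse lookups by name", {
  tab <- factor_table(tg_edges = 100, factors = matrix(c(5, NA), 2, 1),
                      label = "sparse")
  expect_identical(lookup_factor(tab, 50), 5)
  expect_error(lookup_factor(tab, 150), "empty cell")
})

test_that("method specification strings dispatch to the right estimator", {
  cohort <- random_panels(20, seed = 2)
  expect_identical(ldl_estimate(cohort, "friedewald")$value, ldl_friedewald(cohort)$value)
  expect_identical(ldl_estimate(cohort, "fixed:6")$value, ldl_fixed_factor(cohort, 6)$value)
  expect_identical(ldl_estimate(cohort, "mcnamara")$value, ldl_mcnamara(cohort)$value)
  path <- withr::local_tempfile(fileext = ".json")
  write_factor_table(ldl_table_5cell(), path)
  expect_identical(ldl_estimate(cohort, paste0("table:", path))$value,
                   ldl_adjustable(cohort, ldl_table_5cell())$value)
  expect_error(ldl_estimate(cohort, "nonsense"), "unknown")
})
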