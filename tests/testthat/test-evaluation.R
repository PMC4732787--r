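test_that("guideline classification is half-open, total and monotone", {
  got <- classify_ncep(c(-3, 69.999, 70, 100, 129.9, 160, 189.999, 190, 500))
  expect_identical(as.character(got),
                   c("<70", "<70", "70-99", "100-129", "100-129", "160-189",
                     "160-189", ">=190", ">=190"))
  expect_error(classify_ncep(c(100, NA)), "finite")
  set.seed(6)
  x <- sort(runif(200, -20, 250))
  expect_true(!is.unsorted(as.integer(classify_ncep(x))))
})

test_that("Wald proportion CI matches hand computation and truncates", {
  ci <- proportion_ci(4414, 5642)
  p <- 4414 / 5642
  expect_equal(unname(ci[1]), 100 * (p - 1.96 * sqrt(p * (1 - p) / 5642)))
  expect_equal(round(ci, 1), c(lo = 77.2, hi = 79.3))
  expect_identical(unname(proportion_ci(10, 10)[2]), 100)
  expect_identical(unname(proportion_ci(0, 10)[1]), 0)
  expect_error(proportion_ci(1, 0), "positive")
})

test_that("concordance report counts by estimate-defined category", {
  # hand enumeration: categories (est, direct) = (0,0), (1,0), (0,1)
  est <- c(60, 80, 65)
  dir <- c(65, 60, 80)
  r <- concordance_report(est, dir, tg = c(50, 50, 50))
  expect_identical(r$overall$c, 1L)
  expect_identical(r$overall$t, 3L)
  expect_identical(r$under, 1L)
  expect_identical(r$over, 1L)
  bc <- r$by_estimate_category
  expect_identical(bc$t[bc$category == "<70"], 2L)
  expect_identical(bc$c[bc$category == "<70"], 1L)
  expect_identical(bc$n_direct[bc$category == "<70"], 2L)

  # perfect agreement
  r2 <- concordance_report(dir, dir, tg = c(50, 50, 50))
  expect_identical(r2$overall$c, r2$overall$t)
  expect_identical(r2$under + r2$over, 0L)

  expect_error(concordance_report(1:3, 1:2, 1:3), "equal lengths")
  expect_error(concordance_report(100, 100, 400), "400")
})

test_that("concordance partition identities hold on fuzzed cohorts", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    est <- runif(n, -10, 260)
    dir <- runif(n, 1, 260)
    tg <- runif(n, 0, 399.9)
    r <- concordance_report(est, dir, tg)
    expect_identical(sum(r$by_estimate_category$c), r$overall$c)
    expect_identical(sum(r$by_tg_stratum$c), r$overall$c)
    expect_identical(sum(r$by_estimate_category$t), r$overall$t)
    expect_identical(sum(r$by_estimate_category$n_direct), r$overall$t)
    expect_identical(sum(r$by_tg_stratum$t), r$overall$t)
    expect_identical(r$under + r$over + r$overall$c, r$overall$t)
  }
})

test_that("exact McNemar agrees with binomial enumeration and is symmetric", {
  expect_equal(mcnemar_exact(5, 1), 2 * 7 / 64)
  expect_equal(mcnemar_exact(10, 0), 2 / 2^10)
  expect_identical(mcnemar_exact(7, 7), 1)
  expect_identical(mcnemar_exact(3, 9), mcnemar_exact(9, 3))
  expect_warning(p <- mcnemar_exact(0, 0), "convention")
  expect_identical(p, 1)
  for (n in 1:12) {
    for (n01 in 0:n) {
      expect_equal(mcnemar_exact(n01, n - n01), mcnemar_enum_oracle(n01, n - n01))
    }
  }
})

test_that("exact McNemar is conservative under exchangeable nulls", {
  set.seed(21)
  rejections <- replicate(2000, {
    n <- 30
    a <- runif(n) < 0.5
    b <- runif(n) < 0.5
    mcnemar_exact(sum(a & !b), sum(!a & b)) < 0.05
  })
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("signed-rank SP/SN bookkeeping and exact p match the sign-vector oracle", {
  w <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_identical(w$sp, 6)
  expect_identical(w$sn, 0)
  expect_equal(w$p_two_sided, 0.25)
  expect_identical(w$direction, "over")

  # antisymmetric differences: SP = SN, p = 1
  wa <- wilcoxon_signed_rank(c(-3, 3), c(0, 0))
  expect_identical(wa$sp, wa$sn)
  expect_identical(wa$p_two_sided, 1)
  expect_identical(wa$direction, "none")

  expect_warning(wz <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_identical(wz$p_two_sided, 1)

  set.seed(14)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    # half-integer values force ties and zero differences to exercise midranks
    x <- round(rnorm(n, sd = 2) * 2) / 2
    y <- round(rnorm(n, sd = 2) * 2) / 2
    if (all(x == y)) x[1] <- x[1] + 1
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$p_two_sided, wilcoxon_enum_oracle(x, y))
    expect_equal(w$sp + w$sn, w$n_nonzero * (w$n_nonzero + 1) / 2)
  }
})

test_that("signed-rank exact path agrees with stats::wilcox.test when untied", {
  set.seed(15)
  x <- rnorm(12)
  y <- rnorm(12)
  w <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$p_two_sided, ref$p.value)
  expect_equal(w$sp, unname(ref$statistic))
})

test_that("large-sample signed-rank switches to the tie-corrected normal path", {
  set.seed(16)
  x <- rnorm(200)
  y <- rnorm(200)
  w <- wilcoxon_signed_rank(x, y)
  expect_identical(w$method, "normal")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(w$p_two_sided, ref$p.value)
})

test_that("difference summaries use (n+1)p interpolation and keep sign", {
  expect_identical(unlist(difference_summary(c(1, 2, 3), c(1, 2, 3))),
                   c(median = 0, q25 = 0, q75 = 0, p5 = 0, p95 = 0, p1 = 0, p99 = 0))
  d <- difference_summary(c(-2, -1, 0, 1, 2), rep(0, 5))
  expect_identical(d$median, 0)
  expect_identical(c(d$q25, d$q75), c(-1.5, 1.5))
  set.seed(17)
  dir <- runif(30, 50, 200)
  d3 <- difference_summary(dir + 3, dir)
  expect_equal(d3$median, 3)
  expect_error(difference_summary(numeric(0), numeric(0)), "empty")
})

test_that("Mood's median test dichotomises at the grand median", {
  same <- mood_median_test(list(c(1, 3, 5, 7, 9, 11), c(1, 3, 5, 7, 9, 11),
                                c(1, 3, 5, 7, 9, 11)))
  expect_identical(same$method, "chi_square")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  sep <- mood_median_test(list(rep(1, 4), rep(9, 4)))
  expect_identical(sep$method, "fisher_exact")
  expect_equal(sep$p, 2 / choose(8, 4))

  expect_error(mood_median_test(list(c(2, 2), c(2, 2))), "degenerate")
  expect_error(mood_median_test(list(1:3)), "length")
})

test_that("Mood's median test holds its type-I error rate", {
  set.seed(18)
  rej <- replicate(1000, {
    g <- list(rnorm(25), rnorm(25), rnorm(25))
    mood_median_test(g)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("ANOVA with Tamhane letters separates and merges groups correctly", {
  ident <- anova_with_tamhane(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_identical(unname(ident$letters), c("A", "A"))
  expect_equal(ident$f_statistic, 0)

  # two groups: Tamhane reduces to a single Welch t-test
  set.seed(19)
  g1 <- rnorm(20); g2 <- rnorm(20, 1)
  two <- anova_with_tamhane(list(g1 = g1, g2 = g2))
  expect_equal(two$pairwise$p_adj, stats::t.test(g1, g2, var.equal = FALSE)$p.value)

  # three well-separated groups get three letters; two close ones share
  close <- anova_with_tamhane(list(a = rnorm(40, 0, 0.1), b = rnorm(40, 0.01, 0.1),
                                   c = rnorm(40, 5, 0.1)))
  expect_identical(unname(close$letters[1]), unname(close$letters[2]))
  expect_false(close$letters[["c"]] %in% close$letters[c("a", "b")])
})

test_that("per-band ratio groups reproduce the five-letter separation", {
  means <- c(0.398, 0.255, 0.197, 0.180, 0.167)
  sds <- c(0.178, 0.091, 0.055, 0.048, 0.041)
  ns <- c(499, 2105, 1484, 784, 806)
  set.seed(20)
  groups <- Map(function(m, s, n) rnorm(n, m, s), means, sds, ns)
  names(groups) <- paste0("band", 1:5)
  res <- anova_with_tamhane(groups)
  expect_lt(res$p_omnibus, 0.001)
  expect_identical(length(unique(res$letters)), 5L)
})

test_that("variance decomposition recovers structure and reduces cleanly", {
  set.seed(22)
  n <- 300
  tg <- runif(n, 20, 390); hdl <- runif(n, 35, 70); non_hdl <- runif(n, 80, 220)
  vldl <- 0.120 * tg + 0.055 * non_hdl + 2.467
  cohort <- lipid_cohort(data.frame(tc = hdl + non_hdl, hdl = hdl, tg = tg,
                                    ldl_direct = non_hdl - vldl))
  vd <- suppressWarnings(variance_decomposition(cohort, c("tg", "non_hdl")))
  expect_equal(vd$coefficients$b, c(0.120, 0.055, 2.467), tolerance = 1e-10)
  expect_equal(vd$adj_r2, 1, tolerance = 1e-12)

  # single predictor: partial correlation equals zero-order correlation
  noisy <- cohort
  noisy$ldl_direct <- noisy$ldl_direct + rnorm(n, 0, 3)
  noisy$ldl_direct <- pmax(noisy$ldl_direct, 1)
  v1 <- variance_decomposition(noisy, "tg")
  expect_equal(v1$coefficients$r_partial[1], v1$coefficients$r_zero[1])

  # partial R on a 5-point hand dataset equals residual-correlation brute force
  h <- data.frame(tg = c(50, 80, 120, 200, 300), non_hdl = c(120, 100, 150, 160, 210),
                  hdl = rep(50, 5))
  h_vldl <- c(11, 14, 20, 30, 41)
  hc <- lipid_cohort(data.frame(tc = h$hdl + h$non_hdl, hdl = h$hdl, tg = h$tg,
                                ldl_direct = h$non_hdl - h_vldl))
  vh <- variance_decomposition(hc, c("tg", "non_hdl"))
  ry <- resid(lm(h_vldl ~ h$non_hdl))
  rx <- resid(lm(h$tg ~ h$non_hdl))
  expect_equal(vh$coefficients$r_partial[1], cor(ry, rx))

  # collinear predictors are refused by name
  col <- cohort
  col$age <- col$tg * 2
  expect_error(variance_decomposition(col, c("tg", "age")), "collinear")
})
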