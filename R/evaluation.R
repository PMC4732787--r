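#' NCEP-ATP III guideline classification of LDL-C
#'
#' Classifies LDL-C values (mg/dL) into the six ordered treatment-guideline
#' categories cut at 70, 100, 130, 160 and 190 mg/dL. Bands are half-open:
#' a value equal to a cutoff belongs to the band above it (70 is "70-99").
#' Negative estimates are valid input and fall in "<70". Values are
#' classified unrounded.
#'
#' @param ldl numeric vector, mg/dL; must be finite.
#' @return ordered factor with levels `<70`, `70-99`, `100-129`, `130-159`,
#'   `160-189`, `>=190`.
#' @examples
#' classify_ncep(c(-3, 69.999, 70, 190))
#' @export
classify_ncep <- function(ldl) {
  if (any(!is.finite(ldl))) stop("LDL-C values must be finite", call. = FALSE)
  cuts <- c(70, 100, 130, 160, 190)
  labs <- ncep_levels()
  factor(labs[findInterval(ldl, cuts) + 1L], levels = labs, ordered = TRUE)
}

ncep_levels <- function() c("<70", "70-99", "100-129", "130-159", "160-189", ">=190")

#' Wald confidence interval for a proportion, in percent
#'
#' \eqn{100 (p \pm 1.96 \sqrt{p(1-p)/t})} on the unrounded proportion,
#' truncated to \eqn{[0, 100]}.
#'
#' @param c concordant (success) count, `0 <= c <= t`.
#' @param t total count, `> 0`.
#' @return numeric vector `c(lo, hi)` in percent.
#' @examples
#' proportion_ci(4414, 5642)
#' @export
proportion_ci <- function(c, t) {
  stopifnot(length(c) == 1L, length(t) == 1L)
  if (t <= 0) stop("total count must be positive", call. = FALSE)
  if (c < 0 || c > t) stop("need 0 <= c <= t", call. = FALSE)
  p <- c / t
  half <- 1.96 * sqrt(p * (1 - p) / t)
  c(lo = max(0, 100 * (p - half)), hi = min(100, 100 * (p + half)))
}

#' Format a concordance rate the way guideline tables print it
#'
#' `"C/T  %.1f (lo-hi)"` with the percentage and Wald CI endpoints at one
#' decimal place.
#'
#' @inheritParams proportion_ci
#' @return character scalar like `"4414/5642 78.2 (77.2-79.3)"`.
#' @export
format_rate <- function(c, t) {
  ci <- proportion_ci(c, t)
  sprintf("%d/%d %.1f (%.1f-%.1f)", c, t, 100 * c / t, ci[1L], ci[2L])
}

#' Guideline-category concordance between estimated and direct LDL-C
#'
#' Cross-classifies subjects by the NCEP-ATP III category of their LDL-C
#' estimate versus that of their direct measurement. Per-category rows are
#' *estimate-defined*: the denominator `T` of a row counts subjects whose
#' estimate falls in that category, and `C` those whose direct value agrees
#' (the direct-defined counts per category are reported separately as
#' `n_direct`, which is why `T` and `n_direct` differ). TG-stratum rows use
#' the bands <100, 100-<150, 150-<200, 200-<400 mg/dL. Discordant subjects
#' are split by direction: *under* (estimate category ordinally below the
#' direct category) versus *over*.
#'
#' @param estimates numeric vector of LDL-C estimates, mg/dL (an
#'   `ldl_estimate` data frame is accepted).
#' @param direct numeric vector of directly measured LDL-C, mg/dL.
#' @param tg numeric vector of triglycerides, mg/dL; all `< 400`.
#' @return object of class `concordance_report`: list with `overall`
#'   (`c`, `t`), `by_estimate_category` (data frame: category, `c`, `t`,
#'   `n_direct`, `rate`, `ci_lo`, `ci_hi`), `by_tg_stratum` (same layout),
#'   `under`, `over`, and `rate`/`ci` for the overall row.
#' @examples
#' r <- concordance_report(c(65, 80, 120), c(66, 102, 118), tg = c(90, 120, 210))
#' r$overall
#' @export
concordance_report <- function(estimates, direct, tg) {
  if (inherits(estimates, "ldl_estimate")) estimates <- estimates$value
  n <- length(estimates)
  if (length(direct) != n || length(tg) != n) {
    stop("estimates, direct and tg must have equal lengths", call. = FALSE)
  }
  if (n == 0) stop("no subjects", call. = FALSE)
  if (any(tg >= 400)) stop("concordance is defined for TG < 400 mg/dL only", call. = FALSE)
  cat_e <- classify_ncep(estimates)
  cat_d <- classify_ncep(direct)
  agree <- cat_e == cat_d

  levs <- ncep_levels()
  by_cat <- data.frame(
    category = levs,
    c = as.integer(tapply(agree, cat_e, sum, default = 0L)[levs]),
    t = as.integer(table(cat_e)[levs]),
    n_direct = as.integer(table(cat_d)[levs])
  )
  tg_band <- assign_stratum(tg, c(100, 150, 200))
  tg_labs <- band_labels(c(100, 150, 200), upper = 400)
  by_tg <- data.frame(
    tg_band = tg_labs,
    c = as.integer(tapply(agree, factor(tg_band, levels = 1:4), sum, default = 0L)),
    t = as.integer(table(factor(tg_band, levels = 1:4)))
  )
  add_rates <- function(df) {
    ci <- t(mapply(function(c, t) if (t > 0) proportion_ci(c, t) else c(NA_real_, NA_real_),
                   df$c, df$t))
    df$rate <- ifelse(df$t > 0, 100 * df$c / df$t, NA_real_)
    df$ci_lo <- ci[, 1L]
    df$ci_hi <- ci[, 2L]
    df
  }
  overall_ci <- proportion_ci(sum(agree), n)
  structure(list(
    overall = list(c = sum(agree), t = n),
    rate = 100 * sum(agree) / n,
    ci = overall_ci,
    by_estimate_category = add_rates(by_cat),
    by_tg_stratum = add_rates(by_tg),
    under = sum(cat_e < cat_d),
    over = sum(cat_e > cat_d),
    agree = agree
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance in NCEP-ATP III classification (estimate vs direct LDL-C)\n")
  cat("LDL-C category (estimate-defined):\n")
  for (i in rev(seq_len(nrow(x$by_estimate_category)))) {
    r <- x$by_estimate_category[i, ]
    if (r$t > 0) {
      cat(sprintf("  %-8s (n_direct = %4d)  %s\n", r$category, r$n_direct,
                  format_rate(r$c, r$t)))
    }
  }
  cat("Triglyceride stratum:\n")
  for (i in rev(seq_len(nrow(x$by_tg_stratum)))) {
    r <- x$by_tg_stratum[i, ]
    if (r$t > 0) cat(sprintf("  %-9s %s\n", r$tg_band, format_rate(r$c, r$t)))
  }
  cat(sprintf("Overall    %s\n", format_rate(x$overall$c, x$overall$t)))
  cat(sprintf("Discordant: %d under (%.1f%%), %d over (%.1f%%)\n",
              x$under, 100 * x$under / x$overall$t,
              x$over, 100 * x$over / x$overall$t))
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' Exact binomial test for correlated proportions:
#' \eqn{p = \min(1,\; 2 P(X \le \min(n_{01}, n_{10})))} with
#' \eqn{X \sim Bin(n_{01} + n_{10}, 1/2)}. Used to compare the overall
#' concordance of two paired classifiers from their per-subject
#' agree/disagree indicators.
#'
#' @param n01 subjects where only the first classifier agrees with truth.
#' @param n10 subjects where only the second does.
#' @return two-sided exact p-value.
#' @examples
#' mcnemar_exact(5, 1)   # 0.21875
#' @export
mcnemar_exact <- function(n01, n10) {
  stopifnot(n01 >= 0, n10 >= 0)
  if (n01 + n10 == 0) {
    warning("no discordant pairs; p = 1 by convention", call. = FALSE)
    return(1)
  }
  min(1, 2 * stats::pbinom(min(n01, n10), n01 + n10, 0.5))
}

#' Wilcoxon signed-rank test with SP/SN reporting
#'
#' Paired signed-rank test of `x` versus `y`. Zero differences are dropped
#' before ranking; ties in `|x - y|` receive midranks. For
#' `n_nonzero <= exact_limit` the null distribution of the positive rank
#' sum is computed exactly over all sign assignments (a dynamic program
#' over the doubled midranks, correct under ties); above it, the normal
#' approximation with the usual tie correction is used. The sums of
#' positive (`sp`) and negative (`sn`) ranks are reported with the
#' direction they imply: `sp > sn` means `x` tends to exceed `y`
#' (overestimation when `y` is the reference).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest `n_nonzero` for which the exact distribution
#'   is enumerated (default 25).
#' @return object of class `signed_rank`: list with `sp`, `sn`,
#'   `n_nonzero`, `p_two_sided`, `direction` (`"over"`, `"under"`,
#'   `"none"`) and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))  # SP = 6, p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) stop("x and y must have equal lengths", call. = FALSE)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate test, p = 1", call. = FALSE)
    return(structure(list(sp = 0, sn = 0, n_nonzero = 0L, p_two_sided = 1,
                          direction = "none", method = "degenerate"),
                     class = "signed_rank"))
  }
  r <- rank(abs(d))
  sp <- sum(r[d > 0])
  sn <- sum(r[d < 0])
  if (n <= exact_limit) {
    # Exact null distribution of SP via DP on doubled midranks (integers).
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[s + 1] = #subsets with doubled sum s
    counts[1L] <- 1
    for (w in r2) {
      shifted <- c(numeric(w), counts[seq_len(total + 1L - w)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    sp2 <- as.integer(round(2 * sp))
    p_le <- sum(probs[seq_len(sp2 + 1L)])
    p_ge <- sum(probs[(sp2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (sp - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(sp = sp, sn = sn, n_nonzero = n, p_two_sided = p,
                 direction = if (sp > sn) "over" else if (sn > sp) "under" else "none",
                 method = method),
            class = "signed_rank")
}

#' @export
print.signed_rank <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: SP = %.1f, SN = %.1f (n nonzero = %d)\n",
              x$sp, x$sn, x$n_nonzero))
  cat(sprintf("  two-sided p = %.6g (%s); direction: %s\n",
              x$p_two_sided, x$method, x$direction))
  invisible(x)
}

#' Summary of the estimate-minus-direct difference distribution
#'
#' Median, interquartile range, 5th-95th and 1st-99th percentile span of
#' `estimates - direct`, in mg/dL, with sign retained. Quantiles use the
#' (n+1)p linear-interpolation rule (`stats::quantile` type 6).
#'
#' @inheritParams concordance_report
#' @return one-row data frame: `median`, `q25`, `q75`, `p5`, `p95`, `p1`,
#'   `p99`.
#' @export
difference_summary <- function(estimates, direct) {
  if (inherits(estimates, "ldl_estimate")) estimates <- estimates$value
  if (length(estimates) != length(direct)) stop("length mismatch", call. = FALSE)
  if (length(estimates) == 0) stop("empty input", call. = FALSE)
  d <- estimates - direct
  q <- stats::quantile(d, probs = c(0.5, 0.25, 0.75, 0.05, 0.95, 0.01, 0.99),
                       type = 6, names = FALSE)
  data.frame(median = q[1L], q25 = q[2L], q75 = q[3L],
             p5 = q[4L], p95 = q[5L], p1 = q[6L], p99 = q[7L])
}

#' Mood's median test
#'
#' Tests whether k groups share a common median: pool all values, split
#' each group at the grand median (above vs at-or-below), and apply a
#' Pearson chi-square test without continuity correction to the resulting
#' 2 x k table — falling back to Fisher's exact test when the table is
#' 2 x 2 and any expected count is below 5.
#'
#' @param groups list of numeric vectors (>= 2 nonempty groups).
#' @return list with `p`, `statistic` (chi-square, or `NA` for the Fisher
#'   path), `method`, `grand_median` and the 2 x k `table`.
#' @examples
#' mood_median_test(list(c(1, 2, 3, 7), c(5, 6, 8, 9)))
#' @export
mood_median_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("every group must be nonempty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  m <- stats::median(pooled)
  above <- vapply(groups, function(g) sum(g > m), integer(1))
  below <- lengths(groups) - above
  tab <- rbind(above = above, at_or_below = below)
  if (sum(above) == 0 || sum(below) == 0) {
    stop("degenerate split: every value is on one side of the grand median", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (ncol(tab) == 2 && any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    return(list(p = p, statistic = NA_real_, method = "fisher_exact",
                grand_median = m, table = tab))
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p = ch$p.value, statistic = unname(ch$statistic),
       method = "chi_square", grand_median = m, table = tab)
}

#' One-way ANOVA with Tamhane T2 letter grouping
#'
#' Omnibus F-test across k groups, followed by Tamhane's T2 multiple
#' comparisons — Welch t statistics for every pair, Sidak-adjusted
#' (\eqn{p_{adj} = 1 - (1 - p)^m}, \eqn{m = k(k-1)/2}) — and a compact
#' letter display: groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param groups named (or unnamed) list of numeric vectors, each `n >= 2`.
#' @param alpha significance level for the letter grouping.
#' @return list with `p_omnibus`, `f_statistic`, `pairwise` (data frame:
#'   `group1`, `group2`, `p`, `p_adj`, `significant`) and `letters`
#'   (character vector, one entry per group).
#' @examples
#' anova_with_tamhane(list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5), c = c(9, 10, 11)))
#' @export
anova_with_tamhane <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    if (length(unique(vapply(groups, function(g) g[1L], numeric(1)))) == 1L) {
      # identical constant groups: F = 0 by convention, one shared letter
      return(list(p_omnibus = 1, f_statistic = 0,
                  pairwise = data.frame(group1 = character(0), group2 = character(0),
                                        p = numeric(0), p_adj = numeric(0),
                                        significant = logical(0)),
                  letters = stats::setNames(rep("A", length(groups)), names(groups))))
    }
    stop("zero within-group variance in every group", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::anova(stats::lm(values ~ g))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- data.frame(
    group1 = names(groups)[pairs[1L, ]],
    group2 = names(groups)[pairs[2L, ]],
    p = apply(pairs, 2L, function(ij) {
      stats::t.test(groups[[ij[1L]]], groups[[ij[2L]]], var.equal = FALSE)$p.value
    })
  )
  pw$p_adj <- pmin(1, 1 - (1 - pw$p)^m)
  pw$significant <- pw$p_adj < alpha
  sig <- matrix(FALSE, k, k)
  sig[t(pairs)[pw$significant, , drop = FALSE]] <- TRUE
  sig <- sig | t(sig)
  list(p_omnibus = fit$`Pr(>F)`[1L],
       f_statistic = fit$`F value`[1L],
       pairwise = pw,
       letters = stats::setNames(compact_letters(sig, order(-vapply(groups, mean, numeric(1)))),
                                 names(groups)))
}

# Insert-and-absorb compact letter display from a k x k logical matrix of
# significant pairs; `ord` fixes letter order (first letter = first group).
compact_letters <- function(sig, ord = seq_len(nrow(sig))) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!sig[i, j]) next
      hit <- vapply(sets, function(s) all(c(i, j) %in% s), logical(1))
      if (!any(hit)) next
      new_sets <- list()
      for (idx in seq_along(sets)) {
        s <- sets[[idx]]
        if (all(c(i, j) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- vapply(seq_along(new_sets), function(a) {
        !any(vapply(seq_along(new_sets), function(b) {
          b != a && length(new_sets[[b]]) > length(new_sets[[a]]) &&
            all(new_sets[[a]] %in% new_sets[[b]])
        }, logical(1)))
      }, logical(1))
      new_sets <- new_sets[keep]
      sets <- unique(lapply(new_sets, sort))
    }
  }
  # order letters by the position of each set's first group in `ord`
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- character(k)
  for (idx in seq_along(sets)) {
    for (gi in sets[[idx]]) out[gi] <- paste0(out[gi], LETTERS[idx])
  }
  out
}

#' Regression variance decomposition of VLDL-C
#'
#' Ordinary least squares of computed VLDL-C (`non_hdl - ldl_direct`) on a
#' subset of `tg`, `non_hdl`, `hdl`, `age`: unstandardized coefficients
#' with 95% CIs, the zero-order correlation of each predictor with VLDL-C,
#' its partial correlation (correlation of the residuals of outcome and
#' predictor after regressing each on the remaining predictors), and the
#' adjusted \eqn{R^2}. Subjects with `tg >= 400` mg/dL or missing direct
#' LDL-C are excluded first.
#'
#' @param cohort a [lipid_cohort()] with direct LDL-C.
#' @param predictors character subset of
#'   `c("tg", "non_hdl", "hdl", "age")`.
#' @return object of class `regression_summary`: list with `coefficients`
#'   (data frame: `term`, `b`, `ci_lo`, `ci_hi`, `p`, `r_zero`,
#'   `r_partial`; intercept row carries `NA` correlations), `r2`,
#'   `adj_r2`, `n`.
#' @export
variance_decomposition <- function(cohort, predictors = c("tg", "non_hdl")) {
  cohort <- as_lipid_cohort(cohort)
  predictors <- match.arg(predictors, c("tg", "non_hdl", "hdl", "age"),
                          several.ok = TRUE)
  keep <- !is.na(cohort$ldl_direct) & cohort$tg < 400
  cohort <- cohort[keep, , drop = FALSE]
  d <- compute_derived(cohort)
  df <- data.frame(vldl = d$vldl, tg = cohort$tg, non_hdl = d$non_hdl,
                   hdl = cohort$hdl, age = cohort$age)
  df <- df[, c("vldl", predictors)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(predictors) + 2L) stop("too few subjects for the model", call. = FALSE)
  if (length(predictors) > 1) {
    cm <- abs(stats::cor(df[predictors]))
    diag(cm) <- 0
    if (any(cm > 1 - 1e-10)) {
      hit <- sort(which(cm == max(cm), arr.ind = TRUE)[1L, ])
      stop(sprintf("collinear predictors: %s and %s",
                   predictors[hit[1L]], predictors[hit[2L]]), call. = FALSE)
    }
  }
  fit <- stats::lm(vldl ~ ., data = df)
  ci <- stats::confint(fit)
  sm <- summary(fit)
  partial_r <- vapply(predictors, function(pr) {
    others <- setdiff(predictors, pr)
    if (length(others) == 0) return(stats::cor(df$vldl, df[[pr]]))
    ry <- stats::resid(stats::lm(stats::reformulate(others, "vldl"), data = df))
    rx <- stats::resid(stats::lm(stats::reformulate(others, pr), data = df))
    stats::cor(ry, rx)
  }, numeric(1))
  terms <- c(predictors, "(Intercept)")
  coefs <- data.frame(
    term = terms,
    b = unname(stats::coef(fit)[terms]),
    ci_lo = ci[terms, 1L],
    ci_hi = ci[terms, 2L],
    p = sm$coefficients[terms, 4L],
    r_zero = c(vapply(predictors, function(pr) stats::cor(df$vldl, df[[pr]]), numeric(1)), NA_real_),
    r_partial = c(partial_r, NA_real_),
    row.names = NULL
  )
  structure(list(coefficients = coefs, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, n = nrow(df)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS of VLDL-C on %d predictor(s), n = %d\n",
              nrow(x$coefficients) - 1L, x$n))
  print(transform(x$coefficients,
                  b = round(b, 3), ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  r_zero = round(r_zero, 3), r_partial = round(r_partial, 3)))
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}
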