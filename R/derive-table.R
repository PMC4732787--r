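#' Derive a strata-specific median TG:VLDL-C factor table from a cohort
#'
#' For every cell of the TG x non-HDL-C grid, the adjustable factor is the
#' median TG:VLDL-C ratio of the cohort subjects falling in that cell, with
#' VLDL-C obtained by subtraction (`non_hdl - ldl_direct`). Subjects with
#' `tg >= tg_max` are excluded before derivation (the divisor equations are
#' not valid there) and subjects with non-positive computed VLDL-C are
#' dropped from the ratio computation only; both exclusion counts are
#' reported via `message()`.
#'
#' Cells containing no eligible subject are stored as `NA`; the resulting
#' table refuses lookups that land in such a cell.
#'
#' @param cohort a [lipid_cohort()]; every retained subject must carry
#'   `ldl_direct`.
#' @param tg_edges interior TG boundaries, mg/dL. Default
#'   `c(50, 100, 150, 200)` (the 5-band grid).
#' @param nonhdl_edges interior non-HDL-C boundaries, mg/dL;
#'   `numeric(0)` for a TG-only table, `c(100, 130, 160, 190)` gives the
#'   25-cell grid.
#' @param tg_max validity ceiling, mg/dL.
#' @param label provenance string stored in the table.
#' @return a [factor_table()].
#' @examples
#' cohort <- generate_noiseless_cohort(ratios = c(2.71, 4.11, 5.19, 5.70, 6.21),
#'                                     n_per_band = 20, seed = 1)
#' derive_ratio_table(cohort)
#' @export
derive_ratio_table <- function(cohort,
                               tg_edges = c(50, 100, 150, 200),
                               nonhdl_edges = numeric(0),
                               tg_max = 400,
                               label = "derived median TG:VLDL-C") {
  prep <- ratio_cohort(cohort, tg_max)
  i <- assign_stratum(prep$tg, tg_edges)
  nr <- length(tg_edges) + 1L
  nc <- max(1L, length(nonhdl_edges) + 1L)
  j <- if (length(nonhdl_edges)) assign_stratum(prep$non_hdl, nonhdl_edges) else rep(1L, length(i))
  cell <- split(prep$ratio, factor(i, levels = seq_len(nr)):factor(j, levels = seq_len(nc)))
  med <- vapply(cell, function(v) if (length(v)) stats::median(v) else NA_real_, numeric(1))
  factors <- matrix(med, nrow = nr, ncol = nc, byrow = TRUE)
  factor_table(tg_edges = tg_edges, factors = factors,
               nonhdl_edges = nonhdl_edges, label = label, tg_max = tg_max)
}

# Shared preparation: keep subjects with direct LDL-C and tg < tg_max,
# compute ratios, drop non-positive VLDL-C from ratio work (logged).
ratio_cohort <- function(cohort, tg_max) {
  cohort <- as_lipid_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  has_direct <- !is.na(cohort$ldl_direct)
  if (!any(has_direct)) stop("no subjects with directly measured LDL-C", call. = FALSE)
  if (any(!has_direct)) {
    message(sum(!has_direct), " subject(s) without direct LDL-C dropped from ratio derivation")
    cohort <- cohort[has_direct, , drop = FALSE]
  }
  high <- cohort$tg >= tg_max
  if (any(high)) {
    message(sum(high), " subject(s) with TG >= ", tg_max, " mg/dL excluded")
    cohort <- cohort[!high, , drop = FALSE]
  }
  if (nrow(cohort) == 0) stop("no subjects below the TG validity ceiling", call. = FALSE)
  d <- compute_derived(cohort)
  nonpos <- d$vldl <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " subject(s) with non-positive computed VLDL-C dropped from ratio computation")
  }
  keep <- !nonpos
  list(tg = cohort$tg[keep], non_hdl = d$non_hdl[keep],
       ratio = d$tg_vldl_ratio[keep], vldl_tg = d$vldl_tg_ratio[keep])
}

#' Per-stratum TG:VLDL-C ratio summaries
#'
#' For each TG band: subject count, the median TG:VLDL-C ratio with a
#' distribution-free 95% confidence interval of the median
#' (order-statistic/binomial method, achieved coverage reported), and the
#' mean and SD of the reciprocal VLDL-C:TG ratio.
#'
#' @inheritParams derive_ratio_table
#' @param conf confidence level for the median interval.
#' @return data frame with one row per TG band: `tg_band`, `n`,
#'   `median_ratio`, `median_ci_lo`, `median_ci_hi`, `ci_coverage`
#'   (achieved coverage, percent), `mean_vldl_tg`, `sd_vldl_tg`. Bands with
#'   no subjects carry `NA` statistics.
#' @export
stratum_summaries <- function(cohort, tg_edges = c(50, 100, 150, 200),
                              tg_max = 400, conf = 0.95) {
  prep <- ratio_cohort(cohort, tg_max)
  nr <- length(tg_edges) + 1L
  band <- factor(assign_stratum(prep$tg, tg_edges), levels = seq_len(nr))
  labels <- band_labels(tg_edges, upper = tg_max)
  rows <- lapply(seq_len(nr), function(b) {
    r <- prep$ratio[band == b]
    v <- prep$vldl_tg[band == b]
    if (length(r) == 0) {
      return(data.frame(tg_band = labels[b], n = 0L, median_ratio = NA_real_,
                        median_ci_lo = NA_real_, median_ci_hi = NA_real_,
                        ci_coverage = NA_real_, mean_vldl_tg = NA_real_,
                        sd_vldl_tg = NA_real_))
    }
    ci <- median_ci(r, conf = conf)
    data.frame(tg_band = labels[b], n = length(r),
               median_ratio = stats::median(r),
               median_ci_lo = ci$lo, median_ci_hi = ci$hi,
               ci_coverage = ci$coverage * 100,
               mean_vldl_tg = mean(v),
               sd_vldl_tg = if (length(v) > 1) stats::sd(v) else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_summary", class(out))
  out
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval: the widest symmetric pair of order
#' statistics \eqn{(x_{(l)}, x_{(n+1-l)})} whose exact coverage
#' \eqn{1 - 2 P(B \le l - 1)}, \eqn{B \sim Bin(n, 1/2)}, is at least
#' `conf`. Exact and assumption-free; the achieved coverage (always
#' \eqn{\ge} `conf` for `n` large enough to support it) is returned.
#'
#' @param x numeric values.
#' @param conf nominal coverage.
#' @return list with `lo`, `hi`, `coverage` (achieved, as a proportion) and
#'   `l` (the order-statistic rank used). For samples too small to reach
#'   `conf` the full range is returned with its achieved coverage.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) stop("empty sample", call. = FALSE)
  alpha <- 1 - conf
  # largest k with P(B <= k) <= alpha/2, hence l = k + 1 maximises the rank
  # while keeping coverage 1 - 2 P(B <= l - 1) >= conf
  k <- as.integer(stats::qbinom(alpha / 2, n, 0.5))
  if (stats::pbinom(k, n, 0.5) > alpha / 2) k <- k - 1L
  l <- max(1L, k + 1L)
  cov <- 1 - 2 * stats::pbinom(l - 1L, n, 0.5)
  list(lo = x[l], hi = x[n + 1L - l], coverage = cov, l = l)
}
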