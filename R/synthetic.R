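#' Configuration for the synthetic lipid-cohort generator
#'
#' Defaults emulate the marginal structure of a Korean adult screening
#' population: triglycerides roughly lognormal (median about 106,
#' IQR about 71-157 mg/dL below the 400 mg/dL ceiling), VLDL-C:TG ratios
#' Normal within TG bands with means falling as TG rises
#' (0.398/0.255/0.197/0.180/0.167, SDs 0.178/0.091/0.055/0.048/0.041,
#' truncated to > 0.02), direct LDL-C lognormal (median about 111 mg/dL),
#' HDL-C Normal (median about 48 mg/dL), and about 2.6% of subjects with
#' TG at or above 400 mg/dL (drawn around a median of 505 mg/dL with a
#' VLDL-C:TG ratio near 0.15). Total cholesterol is derived, not drawn,
#' so `tc = hdl + ldl_direct + vldl (+ assay noise)` holds by
#' construction — exactly when `assay_noise_sd = 0`.
#'
#' @param n number of subjects.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param tg_log_mu,tg_log_sigma lognormal parameters of TG below the
#'   ceiling (log mg/dL scale).
#' @param tg_edges interior TG band boundaries for the ratio model, mg/dL.
#' @param stratum_ratio_means,stratum_ratio_sds per-band Normal parameters
#'   of the VLDL-C:TG ratio (`length(tg_edges) + 1` each).
#' @param ratio_floor lower truncation of the VLDL-C:TG ratio
#'   (bounds TG:VLDL-C above by its reciprocal).
#' @param ldl_log_mu,ldl_log_sigma lognormal parameters of direct LDL-C.
#' @param hdl_mu,hdl_sigma Normal parameters of HDL-C, truncated positive.
#' @param assay_noise_sd additive mg/dL noise entering total cholesterol
#'   (so the subtraction-derived VLDL-C absorbs it). Default 0.
#' @param include_high_tg_fraction proportion of subjects with TG >= 400.
#' @param high_tg_log_mu,high_tg_log_sigma lognormal parameters of TG in
#'   the high-TG tail.
#' @param high_tg_ratio_mean,high_tg_ratio_sd VLDL-C:TG Normal parameters
#'   in the high-TG tail.
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n,
                                    seed = 1L,
                                    tg_log_mu = log(106),
                                    tg_log_sigma = 0.59,
                                    tg_edges = c(50, 100, 150, 200),
                                    stratum_ratio_means = c(0.398, 0.255, 0.197, 0.180, 0.167),
                                    stratum_ratio_sds = c(0.178, 0.091, 0.055, 0.048, 0.041),
                                    ratio_floor = 0.02,
                                    ldl_log_mu = log(111),
                                    ldl_log_sigma = 0.28,
                                    hdl_mu = 48,
                                    hdl_sigma = 10.4,
                                    assay_noise_sd = 0,
                                    include_high_tg_fraction = 0.026,
                                    high_tg_log_mu = log(505),
                                    high_tg_log_sigma = 0.28,
                                    high_tg_ratio_mean = 0.15,
                                    high_tg_ratio_sd = 0.04) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              tg_log_mu = tg_log_mu, tg_log_sigma = tg_log_sigma,
              tg_edges = tg_edges,
              stratum_ratio_means = stratum_ratio_means,
              stratum_ratio_sds = stratum_ratio_sds,
              ratio_floor = ratio_floor,
              ldl_log_mu = ldl_log_mu, ldl_log_sigma = ldl_log_sigma,
              hdl_mu = hdl_mu, hdl_sigma = hdl_sigma,
              assay_noise_sd = assay_noise_sd,
              include_high_tg_fraction = include_high_tg_fraction,
              high_tg_log_mu = high_tg_log_mu, high_tg_log_sigma = high_tg_log_sigma,
              high_tg_ratio_mean = high_tg_ratio_mean, high_tg_ratio_sd = high_tg_ratio_sd)
  validate_config(cfg)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_config <- function(cfg) {
  nb <- length(cfg$tg_edges) + 1L
  if (cfg$n < 0) stop("n must be >= 0", call. = FALSE)
  if (length(cfg$stratum_ratio_means) != nb || length(cfg$stratum_ratio_sds) != nb) {
    stop(sprintf("need %d per-band ratio means and sds (one per TG band)", nb), call. = FALSE)
  }
  scales <- c(cfg$tg_log_sigma, cfg$stratum_ratio_sds, cfg$ldl_log_sigma,
              cfg$hdl_sigma, cfg$high_tg_log_sigma, cfg$high_tg_ratio_sd)
  if (any(!is.finite(scales) | scales <= 0)) stop("all scale parameters must be positive", call. = FALSE)
  if (any(cfg$stratum_ratio_means <= 0) || cfg$high_tg_ratio_mean <= 0) {
    stop("ratio means must be positive", call. = FALSE)
  }
  if (cfg$assay_noise_sd < 0) stop("assay_noise_sd must be >= 0", call. = FALSE)
  if (cfg$include_high_tg_fraction < 0 || cfg$include_high_tg_fraction > 1) {
    stop("include_high_tg_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$ratio_floor <= 0) stop("ratio_floor must be positive", call. = FALSE)
  invisible(cfg)
}

# Vectorised rejection sampler for a truncated draw.
draw_truncated <- function(n, rdraw, keep) {
  out <- rdraw(n)
  bad <- !keep(out)
  while (any(bad)) {
    out[bad] <- rdraw(sum(bad))
    bad <- !keep(out)
  }
  out
}

#' Generate a synthetic lipid cohort
#'
#' Per subject: TG is drawn (lognormal below 400 mg/dL; a configurable
#' fraction from the high-TG tail at or above 400); the VLDL-C:TG ratio is
#' drawn from the TG band's truncated Normal; `vldl = ratio * tg`; direct
#' LDL-C and HDL-C are drawn from their marginals; and total cholesterol
#' is assembled as `hdl + ldl_direct + vldl` plus the optional assay noise
#' term. Age and sex are uninformative placeholders (uniform 20-87;
#' Bernoulli 1/2) — no downstream stage conditions on them.
#'
#' @param config a [synthetic_cohort_config()], or `n` when the remaining
#'   arguments are given via `...`.
#' @param ... passed to [synthetic_cohort_config()] when `config` is a
#'   count.
#' @param tg_range optional `c(lo, hi)`: condition the below-ceiling TG
#'   draw on `lo <= tg < hi` (stratum-targeted generation, e.g. a fixed
#'   number of subjects per TG band). The high-TG tail is disabled when
#'   `hi <= 400`.
#' @return a [lipid_cohort()] with `n` rows.
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_config(n = 100, seed = 42))
#' @export
generate_cohort <- function(config, ..., tg_range = NULL) {
  if (is.numeric(config)) config <- synthetic_cohort_config(n = config, ...)
  stopifnot(inherits(config, "synthetic_cohort_config"))
  validate_config(config)
  n <- config$n
  if (n == 0) {
    return(lipid_cohort(data.frame(subject_id = character(0), age = numeric(0),
                                   sex = character(0), tc = numeric(0),
                                   hdl = numeric(0), tg = numeric(0),
                                   ldl_direct = numeric(0))))
  }
  lo <- 0; hi <- 400
  high_frac <- config$include_high_tg_fraction
  if (!is.null(tg_range)) {
    stopifnot(length(tg_range) == 2L, tg_range[1L] < tg_range[2L])
    lo <- max(0, tg_range[1L]); hi <- min(400, tg_range[2L])
    if (tg_range[2L] <= 400) high_frac <- 0
  }
  with_seed(config$seed, {
    high <- stats::rbinom(n, 1L, high_frac) == 1L
    tg <- numeric(n)
    tg[!high] <- draw_truncated(sum(!high),
      function(k) stats::rlnorm(k, config$tg_log_mu, config$tg_log_sigma),
      function(v) v >= lo & v < hi)
    tg[high] <- draw_truncated(sum(high),
      function(k) stats::rlnorm(k, config$high_tg_log_mu, config$high_tg_log_sigma),
      function(v) v >= 400)
    band <- assign_stratum(tg, config$tg_edges)
    rmean <- ifelse(high, config$high_tg_ratio_mean, config$stratum_ratio_means[band])
    rsd <- ifelse(high, config$high_tg_ratio_sd, config$stratum_ratio_sds[band])
    # per-subject truncated Normal: redraw each rejected subject against
    # its own band's parameters
    ratio <- stats::rnorm(n, rmean, rsd)
    bad <- ratio <= config$ratio_floor
    while (any(bad)) {
      ratio[bad] <- stats::rnorm(sum(bad), rmean[bad], rsd[bad])
      bad <- ratio <= config$ratio_floor
    }
    vldl <- ratio * tg
    ldl <- stats::rlnorm(n, config$ldl_log_mu, config$ldl_log_sigma)
    hdl <- draw_truncated(n,
      function(k) stats::rnorm(k, config$hdl_mu, config$hdl_sigma),
      function(v) v > 0)
    noise <- if (config$assay_noise_sd > 0) stats::rnorm(n, 0, config$assay_noise_sd) else 0
    tc <- hdl + ldl + vldl + noise
    lipid_cohort(data.frame(
      subject_id = as.character(seq_len(n)),
      age = floor(stats::runif(n, 20, 88)),
      sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
      tc = tc, hdl = hdl, tg = tg, ldl_direct = ldl,
      stringsAsFactors = FALSE
    ))
  })
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ratio-model means that realise target stratum TG:VLDL-C medians
#'
#' The generator draws the VLDL-C:TG ratio from a Normal truncated below
#' at `floor`; truncation pulls the distribution's median above its mean,
#' so a band configured with mean `1/M` does not have TG:VLDL-C median
#' exactly `M` when the band SD is large. This helper inverts the
#' truncated-Normal median: it returns the `stratum_ratio_means` for which
#' each band's *true* median TG:VLDL-C ratio equals the target, so that
#' table derivation on generator output is a genuine parameter-recovery
#' exercise.
#'
#' @param medians target per-band median TG:VLDL-C ratios.
#' @param sds per-band ratio SDs (default the generator defaults).
#' @param floor lower truncation of the VLDL-C:TG ratio.
#' @return numeric vector usable as `stratum_ratio_means`.
#' @examples
#' stratum_means_for_ratio_medians(c(2.71, 4.11, 5.19, 5.70, 6.21))
#' @export
stratum_means_for_ratio_medians <- function(medians,
                                            sds = c(0.178, 0.091, 0.055, 0.048, 0.041),
                                            floor = 0.02) {
  stopifnot(length(medians) == length(sds), all(medians > 0), all(sds > 0))
  vapply(seq_along(medians), function(b) {
    target <- 1 / medians[b]  # VLDL-C:TG scale
    sd <- sds[b]
    trunc_median <- function(m) {
      t <- stats::pnorm(floor, m, sd)
      stats::qnorm(0.5 * (1 + t), m, sd)
    }
    stats::uniroot(function(m) trunc_median(m) - target,
                   interval = c(floor, target + 6 * sd), tol = 1e-12)$root
  }, numeric(1))
}

#' Generate a noiseless cohort with exact per-band TG:VLDL-C ratios
#'
#' Oracle fixture for the table-derivation machinery: within each TG band,
#' every subject's computed VLDL-C equals `tg / ratio` *exactly in double
#' precision*, so [derive_ratio_table()] must recover the configured
#' ratios exactly. Exactness is engineered, not assumed: VLDL-C values are
#' integers (so the subtraction chain `tc - hdl - ldl_direct` is exact)
#' and TG is taken as `vldl * ratio` restricted to integers `vldl` whose
#' quotient round-trips to `ratio` without rounding error.
#'
#' @param ratios one positive TG:VLDL-C ratio per TG band.
#' @param n_per_band subjects per band (scalar or per-band vector).
#' @param seed integer RNG seed.
#' @param tg_edges interior TG band boundaries, mg/dL.
#' @param tg_max upper TG bound of the last band, mg/dL.
#' @return a [lipid_cohort()].
#' @examples
#' cohort <- generate_noiseless_cohort(c(2.71, 4.11, 5.19, 5.70, 6.21),
#'                                     n_per_band = 9, seed = 7)
#' derive_ratio_table(cohort)$factors
#' @export
generate_noiseless_cohort <- function(ratios, n_per_band, seed,
                                      tg_edges = c(50, 100, 150, 200),
                                      tg_max = 400) {
  nb <- length(tg_edges) + 1L
  stopifnot(length(ratios) == nb, all(ratios > 0))
  n_per_band <- rep_len(as.integer(n_per_band), nb)
  bounds <- c(0, tg_edges, tg_max)
  with_seed(seed, {
    rows <- lapply(seq_len(nb), function(b) {
      if (n_per_band[b] == 0L) return(NULL)
      r <- ratios[b]
      v_lo <- max(1L, as.integer(ceiling(bounds[b] / r)))
      v_hi <- as.integer(floor(bounds[b + 1L] / r))
      cand <- if (v_hi >= v_lo) seq(v_lo, v_hi) else integer(0)
      cand <- cand[cand * r >= bounds[b] & cand * r < bounds[b + 1L]]
      # keep integers whose TG = vldl * ratio divides back exactly
      cand <- cand[(cand * r) / cand == r]
      if (length(cand) == 0) {
        stop(sprintf("no integer VLDL-C value reproduces ratio %g exactly in band %d", r, b),
             call. = FALSE)
      }
      vldl <- cand[sample.int(length(cand), n_per_band[b], replace = TRUE)]
      data.frame(vldl = vldl, tg = vldl * r)
    })
    base <- do.call(rbind, rows)
    n <- nrow(base)
    hdl <- sample(35:65, n, replace = TRUE)
    ldl <- sample(70:160, n, replace = TRUE)
    lipid_cohort(data.frame(
      subject_id = as.character(seq_len(n)),
      age = floor(stats::runif(n, 20, 88)),
      sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
      tc = hdl + ldl + base$vldl,
      hdl = hdl, tg = base$tg, ldl_direct = ldl,
      stringsAsFactors = FALSE
    ))
  })
}
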