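#' LDL-C estimators
#'
#' All estimators share the same identity
#' \deqn{\widehat{LDL} = (TC - HDL) - TG / f}
#' and differ only in the divisor \eqn{f} applied to triglycerides:
#'
#' * `ldl_friedewald()` — the fixed Friedewald factor \eqn{f = 5};
#' * `ldl_fixed_factor()` — any positive fixed \eqn{f} (e.g. the 4 or 6
#'   proposed as alternatives in the literature);
#' * `ldl_mcnamara()` — TG-banded factors: 4 for TG \eqn{\le} 50 mg/dL,
#'   4.5 for (50, 200], 5 for (200, 400) mg/dL;
#' * `ldl_adjustable()` — the Martin-style adjustable factor looked up in a
#'   strata-specific median TG:VLDL-C [factor_table()].
#'
#' Estimates can be negative; they are returned as-is (flagged, never
#' clipped) because downstream guideline classification handles any value
#' below 70 mg/dL uniformly. All estimators refuse subjects with
#' `tg >= tg_max` (default 400 mg/dL), the validity ceiling of the
#' triglyceride-divisor family of equations.
#'
#' @param cohort a [lipid_cohort()] (or data frame coercible to one).
#' @param tg_max validity ceiling in mg/dL.
#' @return data frame of class `ldl_estimate` with one row per subject:
#'   `value` (mg/dL), `factor_used` (dimensionless), `method`, and
#'   `negative` (logical flag). `value = non_hdl - tg / factor_used`
#'   exactly.
#' @examples
#' p <- lipid_panel(tc = 184, hdl = 48, tg = 106)
#' ldl_friedewald(p)$value             # 114.8
#' ldl_fixed_factor(p, factor = 6)$value
#' ldl_adjustable(p, ldl_table_5cell())$value
#' @name ldl_estimators
NULL

new_ldl_estimate <- function(non_hdl, tg, factor_used, method) {
  value <- non_hdl - tg / factor_used
  out <- data.frame(value = value, factor_used = factor_used,
                    method = method, negative = value < 0,
                    stringsAsFactors = FALSE)
  if (any(out$negative)) {
    warning(sprintf("%d estimate(s) are negative; returned unclipped", sum(out$negative)),
            call. = FALSE)
  }
  class(out) <- c("ldl_estimate", class(out))
  out
}

#' @rdname ldl_estimators
#' @export
ldl_friedewald <- function(cohort, tg_max = 400) {
  ldl_fixed_factor(cohort, factor = 5, tg_max = tg_max, method = "friedewald")
}

#' @rdname ldl_estimators
#' @param factor positive fixed TG:VLDL-C divisor.
#' @param method method label carried in the result.
#' @export
ldl_fixed_factor <- function(cohort, factor, tg_max = 400, method = "fixed") {
  cohort <- as_lipid_cohort(cohort)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  check_tg_validity(cohort$tg, tg_max)
  new_ldl_estimate(cohort$tc - cohort$hdl, cohort$tg, rep(factor, nrow(cohort)), method)
}

#' @rdname ldl_estimators
#' @export
ldl_mcnamara <- function(cohort, tg_max = 400) {
  cohort <- as_lipid_cohort(cohort)
  check_tg_validity(cohort$tg, tg_max)
  f <- ifelse(cohort$tg <= 50, 4, ifelse(cohort$tg <= 200, 4.5, 5))
  new_ldl_estimate(cohort$tc - cohort$hdl, cohort$tg, f, "mcnamara")
}

#' @rdname ldl_estimators
#' @param table a [factor_table()] supplying the adjustable factor per
#'   TG (and non-HDL-C) stratum.
#' @export
ldl_adjustable <- function(cohort, table, tg_max = NULL) {
  cohort <- as_lipid_cohort(cohort)
  stopifnot(inherits(table, "factor_table"))
  if (!is.null(tg_max)) table$tg_max <- tg_max
  non_hdl <- cohort$tc - cohort$hdl
  f <- lookup_factor(table, cohort$tg, non_hdl)
  new_ldl_estimate(non_hdl, cohort$tg, f, paste0("adjustable:", table$label))
}

#' Dispatch an estimator from a method specification string
#'
#' Accepts `"friedewald"`, `"mcnamara"`, `"fixed:<f>"` (e.g. `"fixed:6"`),
#' or `"table:<path>"` naming a factor-table JSON/CSV file; a
#' [factor_table()] object is accepted directly.
#'
#' @param cohort a [lipid_cohort()].
#' @param method specification string or `factor_table`.
#' @return an `ldl_estimate` data frame (see [ldl_estimators]).
#' @export
ldl_estimate <- function(cohort, method) {
  if (inherits(method, "factor_table")) return(ldl_adjustable(cohort, method))
  stopifnot(is.character(method), length(method) == 1L)
  if (method == "friedewald") return(ldl_friedewald(cohort))
  if (method == "mcnamara") return(ldl_mcnamara(cohort))
  if (startsWith(method, "fixed:")) {
    return(ldl_fixed_factor(cohort, factor = as.numeric(sub("^fixed:", "", method))))
  }
  if (startsWith(method, "table:")) {
    path <- sub("^table:", "", method)
    tab <- if (grepl("\\.csv$", path)) read_factor_table_csv(path) else read_factor_table(path)
    return(ldl_adjustable(cohort, tab))
  }
  stop("unknown estimator specification: ", method, call. = FALSE)
}
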