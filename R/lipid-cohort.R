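#' Construct a lipid cohort
#'
#' A lipid cohort is a data frame with one row per subject and the measured
#' lipid panel in mg/dL: total cholesterol (`tc`), HDL-C (`hdl`),
#' triglycerides (`tg`) and, optionally, directly measured LDL-C
#' (`ldl_direct`). Demographics (`subject_id`, `age`, `sex`) are carried
#' along but never used by the estimators.
#'
#' Invariants enforced on every row: `tc > 0`, `hdl > 0`, `tg >= 0`,
#' `tc >= hdl`, and `ldl_direct >= 0` where present. Units are mg/dL
#' throughout the package; no mmol/L conversion is ever applied.
#'
#' @param data data frame with columns `tc`, `hdl`, `tg` and optionally
#'   `subject_id`, `age`, `sex`, `ldl_direct`.
#' @return the validated data frame with class `lipid_cohort` prepended.
#' @examples
#' lipid_cohort(data.frame(tc = 184, hdl = 48, tg = 106, ldl_direct = 111))
#' @export
lipid_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("tc", "hdl", "tg")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("lipid cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!("subject_id" %in% names(data))) data$subject_id <- as.character(seq_len(nrow(data)))
  if (!("age" %in% names(data))) data$age <- NA_real_
  if (!("sex" %in% names(data))) data$sex <- "unknown"
  if (!("ldl_direct" %in% names(data))) data$ldl_direct <- NA_real_
  for (col in c("tc", "hdl", "tg", "ldl_direct")) data[[col]] <- as.numeric(data[[col]])
  bad <- panel_violations(data)
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop(sprintf("row %d violates lipid panel invariants: %s", i, bad[i]),
         call. = FALSE)
  }
  data$sex <- match_sex(data$sex)
  class(data) <- unique(c("lipid_cohort", class(data)))
  data
}

match_sex <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x) | !(x %in% c("male", "female"))] <- "unknown"
  x
}

# Per-row invariant check; NA where the row is valid, otherwise the reason.
panel_violations <- function(data) {
  reason <- rep(NA_character_, nrow(data))
  flag <- function(cond, msg) {
    hit <- is.na(reason) & cond
    reason[hit] <<- msg
  }
  num_bad <- function(x) !is.finite(x)
  flag(num_bad(data$tc) | num_bad(data$hdl) | num_bad(data$tg),
       "non-finite lipid value")
  flag(data$tc <= 0, "tc > 0 violated")
  flag(data$hdl <= 0, "hdl > 0 violated")
  flag(data$tg < 0, "tg >= 0 violated")
  flag(data$tc < data$hdl, "tc >= hdl violated")
  flag(!is.na(data$ldl_direct) & (data$ldl_direct < 0 | !is.finite(data$ldl_direct)),
       "ldl_direct >= 0 violated")
  reason
}

#' Construct a single-subject lipid panel
#'
#' Convenience wrapper around [lipid_cohort()] for one subject.
#'
#' @param tc,hdl,tg measured values in mg/dL.
#' @param ldl_direct directly measured LDL-C in mg/dL, or `NA` if unavailable.
#' @param subject_id opaque identifier.
#' @param age years.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @return a one-row `lipid_cohort`.
#' @export
lipid_panel <- function(tc, hdl, tg, ldl_direct = NA_real_,
                        subject_id = "1", age = NA_real_, sex = "unknown") {
  lipid_cohort(data.frame(
    subject_id = subject_id, age = age, sex = sex,
    tc = tc, hdl = hdl, tg = tg, ldl_direct = ldl_direct,
    stringsAsFactors = FALSE
  ))
}

#' Derived lipid quantities
#'
#' Computes, per subject, the subtraction identities the estimators and the
#' factor-table derivation rest on:
#' \deqn{\mathrm{nonHDL} = TC - HDL,\qquad VLDL = \mathrm{nonHDL} - LDL_D}
#' so that \eqn{TC = HDL + LDL_D + VLDL} holds exactly, plus the TG:VLDL-C
#' and VLDL-C:TG ratios.
#'
#' Ratio fields are `NA` (absent), not zero, whenever their denominator is
#' not strictly positive; `vldl` and both ratios are `NA` when `ldl_direct`
#' is missing. No error is raised for missing `ldl_direct`.
#'
#' @param cohort a [lipid_cohort()].
#' @return data frame with columns `non_hdl`, `vldl`, `tg_vldl_ratio`,
#'   `vldl_tg_ratio` (all mg/dL or dimensionless), one row per subject.
#' @examples
#' compute_derived(lipid_panel(tc = 184, hdl = 48, tg = 106, ldl_direct = 111))
#' @export
compute_derived <- function(cohort) {
  cohort <- as_lipid_cohort(cohort)
  non_hdl <- cohort$tc - cohort$hdl
  vldl <- ifelse(is.na(cohort$ldl_direct), NA_real_, non_hdl - cohort$ldl_direct)
  tg_vldl <- ifelse(!is.na(vldl) & vldl > 0, cohort$tg / vldl, NA_real_)
  vldl_tg <- ifelse(cohort$tg > 0 & !is.na(vldl), vldl / cohort$tg, NA_real_)
  data.frame(non_hdl = non_hdl, vldl = vldl,
             tg_vldl_ratio = tg_vldl, vldl_tg_ratio = vldl_tg)
}

as_lipid_cohort <- function(x) {
  if (inherits(x, "lipid_cohort")) x else lipid_cohort(x)
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("Lipid cohort: %d subject(s), %d with direct LDL-C (mg/dL)\n",
              nrow(x), sum(!is.na(x$ldl_direct))))
  NextMethod()
}
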