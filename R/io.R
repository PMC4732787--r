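#' Read a lipid-panel file
#'
#' Reads a delimited text file (comma or tab separated, UTF-8, header row)
#' with columns `subject_id`, `age`, `sex`, `tc`, `hdl`, `tg` and
#' optionally `ldl_direct`. Rows violating the panel invariants (or with
#' unparseable numbers) are rejected individually, with their file line
#' number and reason collected in the rejection log; a missing required
#' column is an error naming the column, and a file yielding no valid row
#' is an error.
#'
#' @param path file path.
#' @return a [lipid_cohort()]; the rejection log (data frame with `line`,
#'   `reason`) is attached as attribute `"rejections"` and echoed via
#'   `message()` when nonempty.
#' @export
read_panels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = TRUE, fill = TRUE, comment.char = "")
  required <- c("subject_id", "age", "sex", "tc", "hdl", "tg")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("panel file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("panel file contains no data rows", call. = FALSE)
  if (!("ldl_direct" %in% names(raw))) raw$ldl_direct <- NA_character_
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(subject_id = raw$subject_id,
                   age = num(raw$age),
                   sex = match_sex(raw$sex),
                   tc = num(raw$tc), hdl = num(raw$hdl), tg = num(raw$tg),
                   ldl_direct = ifelse(raw$ldl_direct %in% c("", "NA"), NA,
                                       num(raw$ldl_direct)),
                   stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(df))
  unparsed <- is.na(df$tc) | is.na(df$hdl) | is.na(df$tg)
  reason[unparsed] <- "unparseable or missing numeric value"
  ok <- is.na(reason)
  reason[ok] <- panel_violations(df[ok, , drop = FALSE])
  rejected <- data.frame(line = which(!is.na(reason)) + 1L,  # +1 for header
                         reason = reason[!is.na(reason)])
  if (nrow(rejected)) {
    message(nrow(rejected), " row(s) rejected; see attr(x, 'rejections')")
  }
  keep <- df[is.na(reason), , drop = FALSE]
  if (nrow(keep) == 0) stop("no valid rows in panel file", call. = FALSE)
  out <- lipid_cohort(keep)
  attr(out, "rejections") <- rejected
  out
}

#' Write a lipid cohort to the standard panel CSV
#'
#' @param cohort a [lipid_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panels <- function(cohort, path) {
  cohort <- as_lipid_cohort(cohort)
  cols <- c("subject_id", "age", "sex", "tc", "hdl", "tg", "ldl_direct")
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate LDL-C estimators against direct measurement
#'
#' Runs the full method-comparison battery on a cohort with directly
#' measured LDL-C: for each estimator, the difference-distribution summary,
#' a Wilcoxon signed-rank test of estimate versus direct, and the guideline
#' concordance report; and for every estimator pair, McNemar's exact test
#' on the per-subject concordance indicators plus a Wilcoxon signed-rank
#' test on the absolute deviations from direct (which method tracks the
#' measurement more closely). Subjects with `tg >= 400` mg/dL are excluded
#' first with a logged count.
#'
#' @param cohort a [lipid_cohort()]; every retained subject must carry
#'   `ldl_direct`.
#' @param methods list (or character vector) of estimator specifications
#'   as understood by [ldl_estimate()] — e.g.
#'   `list("friedewald", ldl_table_5cell())`. Names, if given, label the
#'   methods in the report.
#' @return object of class `ldl_validation`: list with `n`, `n_excluded`,
#'   `methods` (per-method list: `estimate`, `difference`, `wilcoxon`,
#'   `concordance`) and `pairwise` (data frame: `method1`, `method2`,
#'   `n01`, `n10`, `mcnemar_p`, `abs_dev_wilcoxon_p`).
#' @export
run_validate <- function(cohort, methods) {
  cohort <- as_lipid_cohort(cohort)
  if (length(methods) == 0) stop("no estimation method specified", call. = FALSE)
  if (is.character(methods)) methods <- as.list(methods)
  labels <- names(methods)
  auto <- vapply(methods, function(m) {
    if (inherits(m, "factor_table")) paste0("table:", m$label) else as.character(m)
  }, character(1))
  if (is.null(labels)) labels <- auto else labels[labels == ""] <- auto[labels == ""]
  if (anyNA(cohort$ldl_direct)) {
    stop("validation requires directly measured LDL-C for every subject", call. = FALSE)
  }
  high <- cohort$tg >= 400
  if (all(high)) stop("all subjects have TG >= 400 mg/dL; nothing to validate", call. = FALSE)
  if (any(high)) {
    message(sum(high), " subject(s) with TG >= 400 mg/dL excluded from validation")
    cohort <- cohort[!high, , drop = FALSE]
  }
  per_method <- lapply(methods, function(m) {
    est <- ldl_estimate(cohort, m)
    list(estimate = est,
         difference = difference_summary(est$value, cohort$ldl_direct),
         wilcoxon = wilcoxon_signed_rank(est$value, cohort$ldl_direct),
         concordance = concordance_report(est$value, cohort$ldl_direct, cohort$tg))
  })
  names(per_method) <- labels
  pairwise <- NULL
  if (length(methods) > 1) {
    pairs <- utils::combn(length(methods), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      a1 <- per_method[[i]]$concordance$agree
      a2 <- per_method[[j]]$concordance$agree
      n01 <- sum(a1 & !a2)
      n10 <- sum(!a1 & a2)
      dev1 <- abs(per_method[[i]]$estimate$value - cohort$ldl_direct)
      dev2 <- abs(per_method[[j]]$estimate$value - cohort$ldl_direct)
      data.frame(method1 = labels[i], method2 = labels[j],
                 n01 = n01, n10 = n10,
                 mcnemar_p = if (n01 + n10 == 0) NA_real_ else mcnemar_exact(n01, n10),
                 abs_dev_wilcoxon_p = wilcoxon_signed_rank(dev1, dev2)$p_two_sided)
    }))
  }
  structure(list(n = nrow(cohort), n_excluded = sum(high),
                 methods = per_method, pairwise = pairwise),
            class = "ldl_validation")
}

#' @export
print.ldl_validation <- function(x, ...) {
  cat(sprintf("LDL-C estimator validation: %d subjects (%d excluded at TG >= 400)\n",
              x$n, x$n_excluded))
  for (nm in names(x$methods)) {
    m <- x$methods[[nm]]
    cat(sprintf("\n== %s ==\n", nm))
    cat(sprintf("  estimate - direct: median %.1f (IQR %.1f to %.1f; 5th-95th %.1f to %.1f) mg/dL\n",
                m$difference$median, m$difference$q25, m$difference$q75,
                m$difference$p5, m$difference$p95))
    cat(sprintf("  overall concordance: %s; under %d (%.1f%%), over %d (%.1f%%)\n",
                format_rate(m$concordance$overall$c, m$concordance$overall$t),
                m$concordance$under, 100 * m$concordance$under / m$concordance$overall$t,
                m$concordance$over, 100 * m$concordance$over / m$concordance$overall$t))
  }
  if (!is.null(x$pairwise)) {
    cat("\nPairwise comparisons (McNemar exact on concordance; Wilcoxon on |deviation|):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Write a validation report to JSON and markdown
#'
#' `write_validation_json()` emits every count, rate and p-value at full
#' precision. `write_validation_md()` renders the concordance tables in
#' the conventional guideline layout — one `C/T` and one `% (95% CI)`
#' column per method, LDL-C category rows (estimate-defined denominators),
#' TG-stratum rows, and the overall row — percentages at one decimal.
#' `write_discordance_csv()` emits the under/over-classification counts
#' and percentages per method.
#'
#' @param validation an [run_validate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(validation, path) {
  stopifnot(inherits(validation, "ldl_validation"))
  meth <- lapply(validation$methods, function(m) {
    list(difference = as.list(m$difference),
         wilcoxon = list(sp = m$wilcoxon$sp, sn = m$wilcoxon$sn,
                         n_nonzero = m$wilcoxon$n_nonzero,
                         p_two_sided = m$wilcoxon$p_two_sided,
                         direction = m$wilcoxon$direction),
         concordance = list(
           overall = validation_rate_row(m$concordance$overall$c, m$concordance$overall$t),
           by_estimate_category = m$concordance$by_estimate_category,
           by_tg_stratum = m$concordance$by_tg_stratum,
           under = m$concordance$under, over = m$concordance$over,
           under_pct = 100 * m$concordance$under / m$concordance$overall$t,
           over_pct = 100 * m$concordance$over / m$concordance$overall$t))
  })
  obj <- list(n = validation$n, n_excluded = validation$n_excluded,
              methods = meth, pairwise = validation$pairwise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

validation_rate_row <- function(c, t) {
  ci <- proportion_ci(c, t)
  list(c = c, t = t, rate = 100 * c / t, ci_lo = ci[[1L]], ci_hi = ci[[2L]])
}

#' @rdname write_validation_json
#' @export
write_validation_md <- function(validation, path) {
  stopifnot(inherits(validation, "ldl_validation"))
  labels <- names(validation$methods)
  cell <- function(c, t) {
    if (t == 0) return("- | -")
    ci <- proportion_ci(c, t)
    sprintf("%d/%d | %.1f (%.1f-%.1f)", c, t, 100 * c / t, ci[1L], ci[2L])
  }
  header <- paste0("| | ", paste(vapply(labels, function(l) paste0(l, " C/T | % (95% CI)"),
                                        character(1)), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", 1 + 2 * length(labels)), collapse = "|"), "|")
  lines <- c(sprintf("Concordance with direct LDL-C (n = %d, TG < 400 mg/dL)", validation$n),
             "", header, rule)
  cats <- validation$methods[[1L]]$concordance$by_estimate_category$category
  for (i in rev(seq_along(cats))) {
    cells <- vapply(validation$methods, function(m) {
      r <- m$concordance$by_estimate_category[i, ]
      cell(r$c, r$t)
    }, character(1))
    nd <- validation$methods[[1L]]$concordance$by_estimate_category$n_direct[i]
    lines <- c(lines, paste0("| LDL-C ", cats[i], " (n = ", nd, ") | ",
                             paste(cells, collapse = " | "), " |"))
  }
  strata <- validation$methods[[1L]]$concordance$by_tg_stratum$tg_band
  for (i in rev(seq_along(strata))) {
    cells <- vapply(validation$methods, function(m) {
      r <- m$concordance$by_tg_stratum[i, ]
      cell(r$c, r$t)
    }, character(1))
    lines <- c(lines, paste0("| TG ", strata[i], " | ", paste(cells, collapse = " | "), " |"))
  }
  overall <- vapply(validation$methods, function(m) {
    cell(m$concordance$overall$c, m$concordance$overall$t)
  }, character(1))
  lines <- c(lines, paste0("| Overall | ", paste(overall, collapse = " | "), " |"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_validation_json
#' @export
write_discordance_csv <- function(validation, path) {
  stopifnot(inherits(validation, "ldl_validation"))
  rows <- do.call(rbind, lapply(names(validation$methods), function(nm) {
    cc <- validation$methods[[nm]]$concordance
    data.frame(method = nm, under = cc$under, over = cc$over,
               under_pct = 100 * cc$under / cc$overall$t,
               over_pct = 100 * cc$over / cc$overall$t)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
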