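#' Construct an adjustable-factor table
#'
#' A factor table maps a subject's triglyceride (TG) level — and optionally
#' their non-HDL-C level — to a positive divisor (the adjustable factor, AF)
#' used in place of the Friedewald 5 in
#' \deqn{LDL = \mathrm{nonHDL} - TG / AF.}
#' Strata are half-open `[lo, hi)` bins over each axis; the last bin of each
#' axis is open-ended above (TG lookups beyond `tg_max` are refused).
#'
#' Cells may be `NA` to mark strata with no eligible subjects in the deriving
#' cohort; lookups falling in such a cell are an error rather than a silent
#' fallback.
#'
#' @param tg_edges ascending interior boundaries (mg/dL) of the TG bins.
#' @param factors numeric matrix, rows = TG bins (`length(tg_edges) + 1`),
#'   cols = non-HDL-C bins (1 column for a TG-only table). All entries must
#'   be positive and finite, or `NA` for empty cells.
#' @param nonhdl_edges ascending interior boundaries (mg/dL) of the
#'   non-HDL-C bins; `numeric(0)` (the default) for a TG-only table.
#' @param label provenance string.
#' @param tg_max validity ceiling in mg/dL; estimates are refused at
#'   `tg >= tg_max`. Default 400.
#' @return an object of class `factor_table`.
#' @examples
#' factor_table(tg_edges = c(50, 100, 150, 200),
#'              factors = c(2.71, 4.11, 5.19, 5.70, 6.21),
#'              label = "demo 5-cell")
#' @export
factor_table <- function(tg_edges, factors, nonhdl_edges = numeric(0),
                         label = "unlabelled", tg_max = 400) {
  tg_edges <- as.numeric(tg_edges)
  nonhdl_edges <- as.numeric(nonhdl_edges)
  if (is.vector(factors)) factors <- matrix(as.numeric(factors), ncol = max(1L, length(nonhdl_edges) + 1L))
  storage.mode(factors) <- "double"
  nr <- length(tg_edges) + 1L
  nc <- length(nonhdl_edges) + 1L
  if (!identical(dim(factors), c(nr, nc))) {
    stop(sprintf("factor matrix must be %d x %d (TG bins x non-HDL-C bins), got %d x %d",
                 nr, nc, nrow(factors), ncol(factors)), call. = FALSE)
  }
  if (length(tg_edges) && any(diff(tg_edges) <= 0)) stop("tg_edges must be strictly increasing", call. = FALSE)
  if (length(nonhdl_edges) > 1 && any(diff(nonhdl_edges) <= 0)) stop("nonhdl_edges must be strictly increasing", call. = FALSE)
  ok <- is.na(factors) | (is.finite(factors) & factors > 0)
  if (!all(ok)) stop("all factors must be positive and finite (or NA for empty cells)", call. = FALSE)
  if (all(is.na(factors))) stop("factor table has no populated cells", call. = FALSE)
  if (!is.numeric(tg_max) || length(tg_max) != 1L || tg_max <= max(c(tg_edges, 0))) {
    stop("tg_max must be a single value above the last TG edge", call. = FALSE)
  }
  dimnames(factors) <- list(band_labels(tg_edges, upper = tg_max),
                            band_labels(nonhdl_edges))
  structure(list(tg_edges = tg_edges, nonhdl_edges = nonhdl_edges,
                 factors = factors, label = as.character(label)[1L],
                 tg_max = as.numeric(tg_max)),
            class = "factor_table")
}

#' Assign values to half-open strata
#'
#' Bins `value` into the half-open bands `[-Inf, e1), [e1, e2), ...,
#' [ek, Inf)` defined by ascending interior edges; the band containing an
#' edge is the one above it, and the last band is open-ended.
#'
#' @param value numeric vector (mg/dL).
#' @param edges strictly increasing interior boundaries.
#' @return integer band index, 1-based (1 = below the first edge).
#' @examples
#' assign_stratum(c(10, 99.9, 100), c(50, 100, 150, 200))  # 1, 2, 3
#' @export
assign_stratum <- function(value, edges) {
  if (length(edges) > 1 && any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  findInterval(value, edges) + 1L
}

band_labels <- function(edges, upper = NULL) {
  if (length(edges) == 0) return("all")
  lab <- character(length(edges) + 1L)
  fmt <- function(x) format(x, trim = TRUE)
  lab[1L] <- paste0("<", fmt(edges[1L]))
  if (length(edges) > 1) {
    lab[2:length(edges)] <- paste0(fmt(edges[-length(edges)]), "-<", fmt(edges[-1L]))
  }
  last <- length(edges) + 1L
  lab[last] <- if (is.null(upper)) paste0(">=", fmt(edges[length(edges)]))
               else paste0(fmt(edges[length(edges)]), "-<", fmt(upper))
  lab
}

#' Look up the adjustable factor for a subject
#'
#' Vectorised over `tg` and `non_hdl`. TG-only tables ignore `non_hdl`.
#'
#' @param table a [factor_table()].
#' @param tg triglycerides, mg/dL; must satisfy `0 <= tg < table$tg_max`.
#' @param non_hdl non-HDL-C, mg/dL; may be missing for TG-only tables.
#' @return numeric vector of positive factors.
#' @examples
#' lookup_factor(ldl_table_25cell(), tg = 120, non_hdl = 140)  # 5.1
#' @export
lookup_factor <- function(table, tg, non_hdl = NULL) {
  stopifnot(inherits(table, "factor_table"))
  check_tg_validity(tg, table$tg_max)
  i <- assign_stratum(tg, table$tg_edges)
  if (length(table$nonhdl_edges) == 0) {
    j <- rep(1L, length(tg))
  } else {
    if (is.null(non_hdl)) stop("this factor table is stratified by non-HDL-C; supply non_hdl", call. = FALSE)
    j <- assign_stratum(rep_len(non_hdl, length(tg)), table$nonhdl_edges)
  }
  f <- table$factors[cbind(i, j)]
  if (anyNA(f)) {
    k <- which(is.na(f))[1L]
    stop(sprintf("factor table '%s' has no factor for TG band %s, non-HDL-C band %s (empty cell)",
                 table$label, rownames(table$factors)[i[k]],
                 colnames(table$factors)[j[k]]), call. = FALSE)
  }
  f
}

check_tg_validity <- function(tg, tg_max) {
  if (any(!is.finite(tg) | tg < 0)) stop("tg must be finite and >= 0", call. = FALSE)
  if (any(tg >= tg_max)) {
    stop(sprintf("triglyceride levels of %g mg/dL and higher are outside the method's validity range (tg_max = %g)",
                 tg_max, tg_max), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.factor_table <- function(x, ...) {
  dims <- dim(x$factors)
  cat(sprintf("Adjustable-factor table '%s': %d TG x %d non-HDL-C cells (TG < %g mg/dL)\n",
              x$label, dims[1L], dims[2L], x$tg_max))
  print(round(x$factors, 2))
  invisible(x)
}

#' Read or write a factor table as JSON
#'
#' The JSON layout has keys `label`, `tg_edges`, `nonhdl_edges`, `tg_max`
#' and `factors` (row-major matrix, rows = TG bins). Empty cells are `null`.
#' Reading and writing round-trip losslessly at full precision.
#'
#' @param table a [factor_table()].
#' @param path file path.
#' @return `read_factor_table()` returns a `factor_table`;
#'   `write_factor_table()` returns `path` invisibly.
#' @export
write_factor_table <- function(table, path) {
  stopifnot(inherits(table, "factor_table"))
  obj <- list(label = table$label,
              tg_edges = table$tg_edges,
              nonhdl_edges = table$nonhdl_edges,
              tg_max = table$tg_max,
              factors = apply(table$factors, 1L, function(r) as.list(unname(r)), simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_factor_table
#' @export
read_factor_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$factors, function(r) vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)))
  factors <- do.call(rbind, rows)
  factor_table(tg_edges = unlist(obj$tg_edges),
               factors = factors,
               nonhdl_edges = if (length(obj$nonhdl_edges)) unlist(obj$nonhdl_edges) else numeric(0),
               label = obj$label %||% "unlabelled",
               tg_max = obj$tg_max %||% 400)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a factor table as CSV
#'
#' A human-editable rendering: first column holds TG band labels of the form
#' `<50`, `50-<100`, ..., the header holds non-HDL-C band labels (a single
#' `all` column for TG-only tables). `label` and `tg_max` travel in `#`
#' comment lines so the file round-trips losslessly.
#'
#' @inheritParams write_factor_table
#' @export
write_factor_table_csv <- function(table, path) {
  stopifnot(inherits(table, "factor_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", table$label),
               paste0("# tg_max: ", format(table$tg_max, digits = 17))), con)
  df <- data.frame(tg_band = rownames(table$factors), table$factors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_factor_table_csv
#' @export
read_factor_table_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1L]) else default
  }
  label <- get_meta("label", "unlabelled")
  tg_max <- as.numeric(get_meta("tg_max", "400"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE,
                        stringsAsFactors = FALSE)
  tg_edges <- edges_from_labels(df$tg_band)
  col_labels <- setdiff(names(df), "tg_band")
  nonhdl_edges <- if (identical(col_labels, "all")) numeric(0) else edges_from_labels(col_labels)
  factor_table(tg_edges = tg_edges,
               factors = as.matrix(df[, col_labels, drop = FALSE]),
               nonhdl_edges = nonhdl_edges, label = label, tg_max = tg_max)
}

# Recover interior edges from labels "<50", "50-<100", ..., ">=190" / "200-<400".
edges_from_labels <- function(labels) {
  labels <- as.character(labels)
  first <- as.numeric(sub("^<", "", labels[1L]))
  mids <- labels[-1L]
  lower <- suppressWarnings(as.numeric(sub("^(>=)?([0-9.]+).*$", "\\2", mids)))
  if (anyNA(c(first, lower))) stop("cannot parse band labels: ", paste(labels, collapse = ", "), call. = FALSE)
  edges <- c(first, lower[-length(lower)], lower[length(lower)])
  unique(edges)
}

#' Shipped factor tables (Korean adult cohort, 2009-2011)
#'
#' `ldl_table_5cell()` returns the 5-cell table of median TG:VLDL-C ratios by
#' TG strata (`<50`, `50-<100`, `100-<150`, `150-<200`, `200-<400` mg/dL);
#' `ldl_table_25cell()` the 25-cell table stratified additionally by
#' non-HDL-C (`<100`, `100-<130`, `130-<160`, `160-<190`, `>=190` mg/dL).
#' Values carry the published precision (2 d.p. and 1 d.p. respectively).
#'
#' @return a [factor_table()].
#' @examples
#' lookup_factor(ldl_table_5cell(), tg = 250)  # 6.21
#' @export
ldl_table_5cell <- function() {
  read_factor_table(system.file("extdata", "factor_table_5cell.json",
                                package = "ldltools", mustWork = TRUE))
}

#' @rdname ldl_table_5cell
#' @export
ldl_table_25cell <- function() {
  read_factor_table(system.file("extdata", "factor_table_25cell.json",
                                package = "ldltools", mustWork = TRUE))
}

#' A constant-factor table (Friedewald as a special case)
#'
#' Builds a one-cell table whose every lookup returns `factor`; with
#' `factor = 5` the adjustable-factor estimator reduces exactly to
#' Friedewald.
#'
#' @param factor positive divisor.
#' @param tg_max validity ceiling, mg/dL.
#' @return a [factor_table()].
#' @export
constant_factor_table <- function(factor, tg_max = 400) {
  factor_table(tg_edges = numeric(0), factors = matrix(factor, 1, 1),
               label = sprintf("constant factor %g", factor), tg_max = tg_max)
}
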