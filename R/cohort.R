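#' Plausibility limits for per-eye biometry
#'
#' Package-policy validation ranges for pseudophakic biometry records. These
#' are wide clinical plausibility bounds, not study inclusion criteria (the
#' source datasets this package is designed for are screened upstream); they
#' exist to catch unit errors and corrupted rows. All intervals are open.
#'
#' @return Named list of `c(lower, upper)` bounds for `al`, `acd`, `lt`,
#'   `r1`, `r2` (mm), `iolp` (D), and `seq_achieved` (D).
#' @export
biometry_limits <- function() {
  list(
    al = c(15, 40), acd = c(1.5, 6), lt = c(2.5, 7),
    r1 = c(5.5, 11), r2 = c(5.5, 11),
    iolp = c(-10, 40), seq_achieved = c(-15, 10)
  )
}

.cohort_cols <- c("eye_id", "al", "acd", "lt", "r1", "r2", "iolp", "seq_achieved")

.validate_records <- function(df, limits) {
  num_cols <- setdiff(.cohort_cols, "eye_id")
  bad <- rep(FALSE, nrow(df))
  reasons <- character(nrow(df))
  for (col in num_cols) {
    v <- df[[col]]
    lim <- limits[[col]]
    off <- !is.finite(v) | v <= lim[1] | v >= lim[2]
    note <- ifelse(off & !bad, sprintf("%s=%s outside (%g, %g)", col, format(v), lim[1], lim[2]), "")
    reasons <- ifelse(off & !bad, note, reasons)
    bad <- bad | off
  }
  list(bad = bad, reasons = reasons)
}

#' Construct a pseudophakic cohort
#'
#' Assembles per-eye biometry, implanted IOL power, and achieved postoperative
#' spherical-equivalent refraction into a validated cohort object (a
#' `data.frame` subclass). Rows violating the biometry plausibility limits are
#' rejected with row-indexed diagnostics.
#'
#' @param records data.frame with columns `eye_id`, `al`, `acd`, `lt`, `r1`,
#'   `r2` (mm), `iolp` (D), `seq_achieved` (D).
#' @param label Cohort label (free text).
#' @param limits Validation ranges, see [biometry_limits()].
#' @param on_invalid `"error"` (default) to fail on any invalid row,
#'   `"drop"` to discard invalid rows with a warning listing them.
#' @return Object of class `iol_cohort` (a data.frame).
#' @export
cohort <- function(records, label = "cohort", limits = biometry_limits(),
                   on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  missing_cols <- setdiff(.cohort_cols, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(records)[, .cohort_cols]
  df$eye_id <- as.character(df$eye_id)
  if (nrow(df) < 1) stop("a cohort needs at least one record", call. = FALSE)
  if (anyDuplicated(df$eye_id)) {
    stop("eye_id values must be unique within a cohort", call. = FALSE)
  }
  chk <- .validate_records(df, limits)
  if (any(chk$bad)) {
    msg <- paste(sprintf("row %d (eye_id %s): %s", which(chk$bad),
                         df$eye_id[chk$bad], chk$reasons[chk$bad]),
                 collapse = "; ")
    if (on_invalid == "error") {
      stop("invalid biometry records: ", msg, call. = FALSE)
    }
    warning("dropped ", sum(chk$bad), " invalid record(s): ", msg, call. = FALSE)
    df <- df[!chk$bad, , drop = FALSE]
    if (nrow(df) < 1) stop("all records were invalid", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, label = label, class = c("iol_cohort", "data.frame"))
}

#' @export
print.iol_cohort <- function(x, ...) {
  cat(sprintf("<iol_cohort> '%s': %d eyes\n", attr(x, "label"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Default CSV column dialect
#'
#' Canonical column names used by [read_cohort()] / [write_cohort()]. Supply
#' a modified copy of this mapping to read foreign CSV exports; names are the
#' internal fields, values the column headers in the file.
#'
#' @return Named character vector mapping internal field names to CSV headers.
#' @export
cohort_dialect <- function() {
  c(eye_id = "eye_id", al = "al_mm", acd = "acd_mm", lt = "lt_mm",
    r1 = "r1_mm", r2 = "r2_mm", iolp = "iolp_d", seq_achieved = "seq_d")
}

#' Read a cohort from CSV
#'
#' Reads a UTF-8, header-row, period-decimal CSV of per-eye biometry into an
#' [cohort()] object. Unparseable numeric cells and rows violating the
#' plausibility limits are reported with their line numbers and eye ids.
#'
#' @param path CSV file path.
#' @param dialect Column-name mapping, see [cohort_dialect()].
#' @param label Cohort label; defaults to the file name.
#' @inheritParams cohort
#' @return An `iol_cohort`.
#' @export
read_cohort <- function(path, dialect = cohort_dialect(), label = basename(path),
                        limits = biometry_limits(),
                        on_invalid = c("error", "drop")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 1) stop("no data rows in ", path, call. = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(eye_id = raw[[dialect[["eye_id"]]]], stringsAsFactors = FALSE)
  for (field in setdiff(.cohort_cols, "eye_id")) {
    txt <- raw[[dialect[[field]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- is.na(val) & !is.na(txt) & nzchar(trimws(txt))
    bad <- bad | is.na(val)
    if (any(bad)) {
      stop(sprintf("unparseable %s in %s: %s", field, path,
                   paste(sprintf("row %d (eye_id %s, value '%s')",
                                 which(bad), df$eye_id[bad], txt[bad]),
                         collapse = "; ")), call. = FALSE)
    }
    df[[field]] <- val
  }
  cohort(df, label = label, limits = limits, on_invalid = match.arg(on_invalid))
}

#' Write a cohort to CSV
#'
#' @param x An `iol_cohort`.
#' @param path Output CSV path.
#' @param dialect Column-name mapping, see [cohort_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, dialect = cohort_dialect()) {
  stopifnot(inherits(x, "iol_cohort"))
  out <- as.data.frame(x)[, .cohort_cols]
  names(out) <- unname(dialect[.cohort_cols])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive statistics of a cohort
#'
#' Mean, SD, median, and 2.5%/97.5% quantiles for axial length (AL), anterior
#' chamber depth (ACD), lens thickness (LT), mean corneal radius (R12,
#' harmonic mean of the meridional radii), keratometric power (K12, converted
#' from R12 with the Javal index nk = 1.3375), implanted IOL power (PIOL), and
#' achieved spherical-equivalent refraction (SEQ). Quantiles use linear
#' interpolation between order statistics (R's default type 7).
#'
#' @param x An `iol_cohort` with at least two records.
#' @param nk Keratometer index for the K12 column. Default 1.3375 (Javal).
#' @return data.frame of class `iol_desc_table` with rows
#'   `Mean`, `SD`, `Median`, `Quantile 2.5%`, `Quantile 97.5%` and columns
#'   `AL`, `ACD`, `LT`, `R12`, `K12`, `PIOL`, `SEQ`.
#' @export
describe_cohort <- function(x, nk = 1.3375) {
  stopifnot(inherits(x, "iol_cohort"))
  if (nrow(x) < 2) stop("need at least 2 records for descriptive statistics",
                        call. = FALSE)
  r12 <- mean_corneal_radius(x$r1, x$r2)
  vars <- list(AL = x$al, ACD = x$acd, LT = x$lt, R12 = r12,
               K12 = keratometric_power(r12, nk), PIOL = x$iolp,
               SEQ = x$seq_achieved)
  stat_rows <- c("Mean", "SD", "Median", "Quantile 2.5%", "Quantile 97.5%")
  tab <- vapply(vars, function(v) {
    c(mean(v), sd(v), median(v),
      quantile(v, 0.025, names = FALSE, type = 7),
      quantile(v, 0.975, names = FALSE, type = 7))
  }, numeric(5))
  out <- as.data.frame(tab, row.names = stat_rows)
  class(out) <- c("iol_desc_table", "data.frame")
  attr(out, "label") <- attr(x, "label")
  out
}

#' @export
print.iol_desc_table <- function(x, digits = 4, ...) {
  cat(sprintf("Descriptive statistics — %s\n", attr(x, "label")))
  print(round(as.data.frame(x), digits))
  invisible(x)
}
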