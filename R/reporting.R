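#' Descriptive-statistics command
#'
#' Reads a cohort CSV, computes the descriptive table (mean/SD/median and
#' 2.5%/97.5% quantiles of AL, ACD, LT, R12, K12, PIOL, SEQ), and writes it
#' as CSV with a `statistic` first column. Deterministic: identical inputs
#' produce identical output bytes.
#'
#' @param cohort_path Input cohort CSV.
#' @param out_path Output CSV path.
#' @param dialect Column dialect for the input, see [cohort_dialect()].
#' @return `out_path`, invisibly.
#' @export
cmd_stats <- function(cohort_path, out_path, dialect = cohort_dialect()) {
  co <- read_cohort(cohort_path, dialect = dialect)
  tab <- describe_cohort(co)
  out <- cbind(data.frame(statistic = rownames(tab)), as.data.frame(tab))
  write.csv(out, out_path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(out_path)
}

#' Simulation command
#'
#' Generates a synthetic cohort from a dataset preset and writes the cohort
#' CSV together with a sidecar truth JSON recording the generating
#' parameters.
#'
#' @param out_path Output cohort CSV path; the truth JSON is written next to
#'   it with extension `.truth.json`.
#' @param dataset Preset dataset id (1-4).
#' @param ... Overrides forwarded to [preset_config()] (e.g. `n`, `seed`,
#'   `noise_sd`, `true_formula`, `fc_true`, `ro_true`).
#' @return Named character vector of the two files written, invisibly.
#' @export
cmd_simulate <- function(out_path, dataset = 1, ...) {
  cfg <- preset_config(dataset, ...)
  gen <- generate_cohort(cfg)
  write_cohort(gen$cohort, out_path)
  truth_path <- sub("\\.csv$", "", out_path)
  truth_path <- paste0(truth_path, ".truth.json")
  truth <- gen$truth
  truth$config <- unclass(truth$config)
  truth$config$true_constants <- unclass(truth$config$true_constants)
  truth$config$correlation <- as.data.frame(truth$config$correlation)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(cohort = out_path, truth = truth_path))
}

#' Strategy-suite command
#'
#' Reads a cohort CSV, runs the six-strategy optimization suite for the
#' requested formulae, and writes `constants.csv` (fitted constant /
#' refractive offset / keratometer index per formula and strategy),
#' `metrics.csv` (MPE/SDPE/RMSPE plus absolute-error quartiles and
#' 2.5%/97.5% quantiles per formula and strategy), and `manifest.json`
#' (settings, package version, per-cell convergence flags, failures).
#'
#' @param cohort_path Input cohort CSV.
#' @param out_dir Output directory (created if missing).
#' @param formulas Formula ids to run.
#' @param settings An [optimizer_settings()] object.
#' @param dialect Column dialect for the input.
#' @return Named character vector of files written, invisibly. Raises an
#'   error if any cell failed or did not converge (after writing the files),
#'   so that script callers exit with nonzero status on partial results.
#' @export
cmd_suite <- function(cohort_path, out_dir, formulas = .formula_ids,
                      settings = optimizer_settings(),
                      dialect = cohort_dialect()) {
  co <- read_cohort(cohort_path, dialect = dialect)
  suite <- run_strategy_suite(co, formulas = formulas, settings = settings)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(constants = file.path(out_dir, "constants.csv"),
             metrics = file.path(out_dir, "metrics.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write.csv(constants_table(suite), paths[["constants"]], row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  write.csv(metrics_table(suite), paths[["metrics"]], row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  conv <- vapply(suite$results, function(r)
    if (is.character(r)) FALSE else r$converged, logical(1))
  manifest <- list(
    input = normalizePath(cohort_path),
    cohort_label = suite$cohort_label, n = suite$n,
    formulas = suite$formulas, strategies = suite$strategies,
    settings = unclass(settings),
    package = "iolconst",
    version = as.character(utils::packageVersion("iolconst")),
    converged = as.list(conv),
    failures = suite$failures)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (length(suite$failures) || !all(conv)) {
    stop("strategy suite finished with failures or non-converged cells; see ",
         paths[["manifest"]], call. = FALSE)
  }
  invisible(paths)
}
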