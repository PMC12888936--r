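#' Optimizer settings
#'
#' Stopping criteria and search bounds for the constant-optimization
#' routines. Defaults follow the conventions of iterative nonlinear constant
#' optimization: a step-size tolerance of 1e-10 and a function tolerance of
#' 1e-12.
#'
#' @param step_tol Tolerance on the constant (search-space step), > 0.
#' @param fun_tol Tolerance on the objective value, > 0.
#' @param fc_bounds Search bounds for the primary constant: `NULL` for the
#'   per-formula defaults (A \[110, 125\], pACD \[2, 9\], SF \[-2, 5\],
#'   a0 \[-3, 5\]), or a length-2 numeric vector.
#' @param nk_bounds Search bounds for the keratometer index.
#' @param max_iter Iteration/evaluation cap for the polishing loops.
#' @param two_step_mode `"exact"`: the first stage of the two-step procedure
#'   minimizes SDPE to tolerance; `"single_update"`: a single damped Newton
#'   update from the start constant (central differences, step 1e-4),
#'   mirroring one-iteration clinical use.
#' @param min_n Minimum cohort size accepted without `allow_small`.
#' @return Object of class `iol_opt_settings`.
#' @export
optimizer_settings <- function(step_tol = 1e-10, fun_tol = 1e-12,
                               fc_bounds = NULL, nk_bounds = c(1.30, 1.38),
                               max_iter = 200L,
                               two_step_mode = c("exact", "single_update"),
                               min_n = 10L) {
  stopifnot(step_tol > 0, fun_tol > 0, max_iter >= 1,
            length(nk_bounds) == 2, nk_bounds[1] < nk_bounds[2])
  structure(list(step_tol = step_tol, fun_tol = fun_tol,
                 fc_bounds = fc_bounds, nk_bounds = nk_bounds,
                 max_iter = as.integer(max_iter),
                 two_step_mode = match.arg(two_step_mode),
                 min_n = as.integer(min_n)),
            class = "iol_opt_settings")
}

.strategy_ids <- c("A_ZERO_MPE", "B_MIN_SDPE", "C_MIN_RMSPE",
                   "D_JOINT_FC_RO", "E_JOINT_FC_NK", "F_TWO_STEP")

.get_fc_bounds <- function(settings, formula) {
  settings$fc_bounds %||% .fc_bounds_default[[formula]]
}

.check_cohort_size <- function(cohort, settings, allow_small) {
  n <- nrow(cohort)
  if (n < settings$min_n) {
    if (!allow_small) {
      stop(sprintf("cohort has %d eyes (< %d); constant optimization on such small samples is unreliable. Use allow_small = TRUE to proceed anyway.",
                   n, settings$min_n), call. = FALSE)
    }
    warning(sprintf("optimizing constants on only %d eyes", n), call. = FALSE)
  }
}

# Objective closure over the primary constant with clamp-warning accounting.
.make_objective <- function(cohort, template, metric) {
  counter <- new.env(parent = emptyenv())
  counter$evals <- 0L
  counter$clamps <- 0L
  fun <- function(fc, ro = template$ro, nk = template$nk) {
    counter$evals <- counter$evals + 1L
    k <- template
    k$fc <- fc
    k$ro <- ro
    k$nk <- nk
    pe <- withCallingHandlers(
      prediction_errors(k, cohort),
      iolconst_clamp = function(w) {
        counter$clamps <- counter$clamps + 1L
        invokeRestart("muffleWarning")
      })
    switch(metric,
           mpe = mean(pe),
           sdpe = sd(pe),
           rmspe = sqrt(mean(pe^2)))
  }
  list(fun = fun, counter = counter)
}

.quiet_stats <- function(constants, cohort) {
  withCallingHandlers(
    summarize_pe(prediction_errors(constants, cohort)),
    iolconst_clamp = function(w) invokeRestart("muffleWarning"))
}

.opt_result <- function(strategy, constants, cohort, objective_value,
                        converged, iterations, diagnostics = list()) {
  structure(list(strategy = strategy, formula = constants$formula,
                 constants = constants,
                 stats = .quiet_stats(constants, cohort),
                 objective_value = objective_value,
                 converged = converged, iterations = iterations,
                 diagnostics = diagnostics),
            class = "iol_opt_result")
}

#' @export
print.iol_opt_result <- function(x, ...) {
  cat(sprintf("<iol_opt_result> %s / %s%s\n", x$formula, x$strategy,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  nk <- x$constants$nk
  cat(sprintf("  %s = %.4f%s%s\n", .fc_name[x$formula], x$constants$fc,
              if (x$constants$ro != 0) sprintf(", RO = %.4f D", x$constants$ro) else "",
              if (!is.null(nk)) sprintf(", nK = %.4f", nk) else ""))
  cat(sprintf("  MPE %.4f, SDPE %.4f, RMSPE %.4f D (n = %d, %d evaluations)\n",
              x$stats$mpe, x$stats$sdpe, x$stats$rmspe, x$stats$n, x$iterations))
  invisible(x)
}

# Bounded scalar minimization: coarse bracketing grid, then Brent refinement
# on the bracketing interval. Assumes a unimodal objective (empirically true
# for all four formulae over the plausibility bounds).
.minimize_scalar <- function(f, bounds, tol, n_grid = 41L) {
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- optimize(f, interval = c(lo, hi), tol = tol)
  # keep whichever is better in case Brent stops on a shoulder
  if (vals[i] < opt$objective) list(minimum = grid[i], objective = vals[i])
  else opt
}

# Zero of a monotone scalar function: uniroot bracket, then secant polish to
# the function tolerance.
.root_scalar <- function(f, bounds, step_tol, fun_tol, max_iter) {
  f_lo <- f(bounds[1]); f_hi <- f(bounds[2])
  if (!is.finite(f_lo) || !is.finite(f_hi) || sign(f_lo) == sign(f_hi)) {
    stop(sprintf("objective does not change sign over [%g, %g] (f = %.4g / %.4g); cannot bracket a root",
                 bounds[1], bounds[2], f_lo, f_hi), call. = FALSE)
  }
  r <- uniroot(f, interval = bounds, f.lower = f_lo, f.upper = f_hi,
               tol = step_tol)
  x0 <- r$root; f0 <- f(x0)
  x1 <- x0 + max(abs(x0), 1) * 1e-7; f1 <- f(x1)
  it <- 0L
  while (abs(f1) > fun_tol && it < max_iter && f1 != f0) {
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    x2 <- min(max(x2, bounds[1]), bounds[2])
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- f(x1)
    it <- it + 1L
  }
  list(root = x1, f_root = f1, converged = abs(f1) <= fun_tol, iter = it)
}

#' Single-constant optimization
#'
#' Optimizes the primary formula constant for one of three objectives:
#' zeroing the mean prediction error (`zero_mpe`, bracketed root finding),
#' minimizing its standard deviation (`min_sdpe`), or minimizing the root
#' mean squared prediction error (`min_rmspe`) — both by bounded scalar
#' minimization. The refractive offset and keratometer index are held at the
#' values of the template `constants` (defaults: 0 and the native index).
#'
#' @param formula Formula id (`"SRKT"`, `"HOFFERQ"`, `"HOLLADAY1"`,
#'   `"HAIGIS"`).
#' @param cohort An `iol_cohort`.
#' @param objective `"zero_mpe"`, `"min_sdpe"`, or `"min_rmspe"`.
#' @param settings An [optimizer_settings()] object.
#' @param constants Optional template [formula_constants()] supplying
#'   `ro`/`nk`/`a1`/`a2` and the start value.
#' @param allow_small Proceed (with a warning) on cohorts smaller than
#'   `settings$min_n`.
#' @return An `iol_opt_result`: fitted constants, prediction-error summary,
#'   objective value, convergence flag, evaluation count.
#' @export
optimize_fc <- function(formula, cohort,
                        objective = c("zero_mpe", "min_sdpe", "min_rmspe"),
                        settings = optimizer_settings(), constants = NULL,
                        allow_small = FALSE) {
  formula <- .match_formula(formula)
  objective <- match.arg(objective)
  stopifnot(inherits(cohort, "iol_cohort"))
  .check_cohort_size(cohort, settings, allow_small)
  template <- constants %||% formula_constants(formula)
  stopifnot(template$formula == formula)
  bounds <- .get_fc_bounds(settings, formula)

  strategy <- switch(objective, zero_mpe = "A_ZERO_MPE",
                     min_sdpe = "B_MIN_SDPE", min_rmspe = "C_MIN_RMSPE")
  metric <- switch(objective, zero_mpe = "mpe", min_sdpe = "sdpe",
                   min_rmspe = "rmspe")
  obj <- .make_objective(cohort, template, metric)

  if (objective == "zero_mpe") {
    r <- .root_scalar(obj$fun, bounds, settings$step_tol, settings$fun_tol,
                      settings$max_iter)
    fitted <- template; fitted$fc <- r$root
    return(.opt_result(strategy, fitted, cohort, objective_value = r$f_root,
                       converged = r$converged, iterations = obj$counter$evals,
                       diagnostics = list(clamp_events = obj$counter$clamps)))
  }

  flat_check <- abs(obj$fun(bounds[1]) - obj$fun(bounds[2]))
  mid <- obj$fun(mean(bounds))
  if (flat_check < settings$fun_tol &&
      abs(mid - obj$fun(bounds[1])) < settings$fun_tol) {
    stop("objective is flat to the function tolerance across the constant bounds; the cohort does not identify the constant", call. = FALSE)
  }
  opt <- .minimize_scalar(obj$fun, bounds, tol = max(settings$step_tol, 1e-11))
  at_bound <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum) < 1e-6
  fitted <- template; fitted$fc <- opt$minimum
  .opt_result(strategy, fitted, cohort, objective_value = opt$objective,
              converged = !at_bound, iterations = obj$counter$evals,
              diagnostics = list(clamp_events = obj$counter$clamps,
                                 fc_at_bound = at_bound))
}

#' Joint optimization of the formula constant and a second parameter
#'
#' Minimizes the root mean squared prediction error over the primary
#' constant together with either the refractive offset (`second = "ro"`) or
#' the keratometer index (`second = "nk"`).
#'
#' For `second = "ro"` the offset is profiled out analytically: because the
#' offset is purely additive, the inner optimum for any constant is the mean
#' prediction error at zero offset, and the residual objective is the
#' standard deviation of the prediction error. The joint problem therefore
#' reduces to the same bounded scalar minimization used by the
#' `min_sdpe` objective (the SD denominator does not affect the argmin),
#' followed by setting the offset to the mean error — which also makes this
#' strategy analytically equivalent to the exact two-step procedure. Set
#' `profile = FALSE` for a naive 2-D Nelder-Mead search over the
#' near-degenerate (constant, offset) ridge, kept for comparison.
#'
#' For `second = "nk"` a nested bounded search is used: an outer Brent
#' search over the keratometer index with an inner constant minimization per
#' candidate index. A solution with the index at a search bound is flagged
#' as not converged.
#'
#' @inheritParams optimize_fc
#' @param second `"ro"` or `"nk"`.
#' @param profile Use the analytic profile for `second = "ro"` (default).
#' @return An `iol_opt_result`.
#' @export
optimize_joint <- function(formula, cohort, second = c("ro", "nk"),
                           settings = optimizer_settings(), constants = NULL,
                           profile = TRUE, allow_small = FALSE) {
  formula <- .match_formula(formula)
  second <- match.arg(second)
  stopifnot(inherits(cohort, "iol_cohort"))
  .check_cohort_size(cohort, settings, allow_small)
  template <- constants %||% formula_constants(formula)
  stopifnot(template$formula == formula)
  bounds <- .get_fc_bounds(settings, formula)

  if (second == "ro") {
    template$ro <- 0
    if (profile) {
      sd_obj <- .make_objective(cohort, template, "sdpe")
      opt <- .minimize_scalar(sd_obj$fun, bounds,
                              tol = max(settings$step_tol, 1e-11))
      mpe_obj <- .make_objective(cohort, template, "mpe")
      fitted <- template
      fitted$fc <- opt$minimum
      fitted$ro <- mpe_obj$fun(opt$minimum)
      rmspe_at <- .make_objective(cohort, fitted, "rmspe")$fun(fitted$fc)
      at_bound <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum) < 1e-6
      return(.opt_result("D_JOINT_FC_RO", fitted, cohort,
                         objective_value = rmspe_at, converged = !at_bound,
                         iterations = sd_obj$counter$evals + 1L,
                         diagnostics = list(clamp_events = sd_obj$counter$clamps,
                                            method = "profile")))
    }
    obj <- .make_objective(cohort, template, "rmspe")
    pen_fun <- function(par) {
      if (par[1] < bounds[1] || par[1] > bounds[2]) return(1e6 + par[1]^2)
      obj$fun(par[1], ro = par[2])
    }
    fit <- optim(c(template$fc, 0), pen_fun, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    fitted <- template
    fitted$fc <- fit$par[1]
    fitted$ro <- fit$par[2]
    return(.opt_result("D_JOINT_FC_RO", fitted, cohort,
                       objective_value = fit$value,
                       converged = fit$convergence == 0,
                       iterations = obj$counter$evals,
                       diagnostics = list(clamp_events = obj$counter$clamps,
                                          method = "nelder-mead")))
  }

  # second == "nk": nested bounded search
  obj <- .make_objective(cohort, template, "rmspe")
  nkb <- settings$nk_bounds
  inner <- function(nk) {
    .minimize_scalar(function(fc) obj$fun(fc, nk = nk), bounds,
                     tol = max(settings$step_tol, 1e-9), n_grid = 25L)
  }
  outer <- .minimize_scalar(function(nk) inner(nk)$objective, nkb,
                            tol = 1e-7, n_grid = 17L)
  nk_star <- outer$minimum
  fc_star <- inner(nk_star)$minimum
  fitted <- template
  fitted$fc <- fc_star
  fitted$nk <- nk_star
  nk_at_bound <- min(nk_star - nkb[1], nkb[2] - nk_star) < 1e-6
  .opt_result("E_JOINT_FC_NK", fitted, cohort,
              objective_value = outer$objective, converged = !nk_at_bound,
              iterations = obj$counter$evals,
              diagnostics = list(clamp_events = obj$counter$clamps,
                                 nk_at_bound = nk_at_bound))
}

#' Two-step constant optimization (constant for precision, offset for accuracy)
#'
#' The sequential two-step procedure: step 1 tunes the primary formula
#' constant to minimize the standard deviation of the prediction error
#' (precision); step 2 sets the refractive offset to the mean prediction
#' error obtained at that constant, which zeroes the mean exactly under the
#' achieved-minus-predicted sign convention (accuracy).
#'
#' In `two_step_mode = "exact"` (default) step 1 is a bounded minimization
#' to tolerance; in `"single_update"` it is a single damped Newton update of
#' the start constant based on central finite differences of the SD
#' objective (step 1e-4), emulating one-iteration clinical use. The update is
#' damped (halved) until the SD at the updated constant does not exceed the
#' SD at the start value.
#'
#' @inheritParams optimize_fc
#' @return An `iol_opt_result` whose constants carry both the fitted primary
#'   constant and the refractive offset.
#' @export
optimize_two_step <- function(formula, cohort, settings = optimizer_settings(),
                             constants = NULL, allow_small = FALSE) {
  formula <- .match_formula(formula)
  stopifnot(inherits(cohort, "iol_cohort"))
  .check_cohort_size(cohort, settings, allow_small)
  template <- constants %||% formula_constants(formula)
  stopifnot(template$formula == formula)
  template$ro <- 0
  bounds <- .get_fc_bounds(settings, formula)
  sd_obj <- .make_objective(cohort, template, "sdpe")

  if (settings$two_step_mode == "exact") {
    opt <- .minimize_scalar(sd_obj$fun, bounds,
                            tol = max(settings$step_tol, 1e-11))
    fc_star <- opt$minimum
    converged <- min(fc_star - bounds[1], bounds[2] - fc_star) >= 1e-6
  } else {
    fc0 <- template$fc
    h <- 1e-4
    f0 <- sd_obj$fun(fc0)
    fp <- sd_obj$fun(fc0 + h); fm <- sd_obj$fun(fc0 - h)
    g <- (fp - fm) / (2 * h)
    hess <- (fp - 2 * f0 + fm) / h^2
    step <- if (is.finite(hess) && hess > 0) -g / hess else -sign(g) * 0.05 * diff(bounds)
    it <- 0L
    fc_star <- min(max(fc0 + step, bounds[1]), bounds[2])
    while (sd_obj$fun(fc_star) > f0 && it < 30L) {
      step <- step / 2
      fc_star <- min(max(fc0 + step, bounds[1]), bounds[2])
      it <- it + 1L
    }
    converged <- TRUE  # single-update mode is one damped step by design
  }

  mpe_obj <- .make_objective(cohort, template, "mpe")
  fitted <- template
  fitted$fc <- fc_star
  fitted$ro <- mpe_obj$fun(fc_star)
  rmspe_at <- .make_objective(cohort, fitted, "rmspe")$fun(fc_star)
  .opt_result("F_TWO_STEP", fitted, cohort, objective_value = rmspe_at,
              converged = converged, iterations = sd_obj$counter$evals + 1L,
              diagnostics = list(clamp_events = sd_obj$counter$clamps,
                                 mode = settings$two_step_mode))
}

#' Run the full strategy suite
#'
#' Runs all six optimization strategies for each requested formula:
#' (a) constant for zero mean PE, (b) constant for minimal SD of PE,
#' (c) constant for minimal RMS PE, (d) joint constant/refractive-offset for
#' minimal RMS PE, (e) joint constant/keratometer-index for minimal RMS PE,
#' and (f) the sequential two-step procedure. Failures of individual cells
#' are recorded and the suite continues.
#'
#' @inheritParams optimize_fc
#' @param formulas Character vector of formula ids.
#' @param strategies Character vector of strategy ids (default all six).
#' @param start_constants Optional named list of template
#'   [formula_constants()] per formula (e.g. manufacturer-nominal values).
#' @return Object of class `iol_suite`: a list with `results` (per
#'   formula/strategy `iol_opt_result` or error message), `cohort_label`,
#'   `n`, and `settings`. See [constants_table()] and [metrics_table()].
#' @export
run_strategy_suite <- function(cohort, formulas = .formula_ids,
                               strategies = .strategy_ids,
                               settings = optimizer_settings(),
                               start_constants = NULL, allow_small = FALSE) {
  stopifnot(inherits(cohort, "iol_cohort"))
  formulas <- vapply(formulas, .match_formula, character(1))
  strategies <- match.arg(strategies, .strategy_ids, several.ok = TRUE)
  results <- list()
  failures <- list()
  for (fm in formulas) {
    template <- start_constants[[fm]] %||% formula_constants(fm)
    for (st in strategies) {
      key <- paste(fm, st, sep = ".")
      res <- tryCatch(
        switch(st,
               A_ZERO_MPE = optimize_fc(fm, cohort, "zero_mpe", settings,
                                        template, allow_small),
               B_MIN_SDPE = optimize_fc(fm, cohort, "min_sdpe", settings,
                                        template, allow_small),
               C_MIN_RMSPE = optimize_fc(fm, cohort, "min_rmspe", settings,
                                         template, allow_small),
               D_JOINT_FC_RO = optimize_joint(fm, cohort, "ro", settings,
                                              template, allow_small = allow_small),
               E_JOINT_FC_NK = optimize_joint(fm, cohort, "nk", settings,
                                              template, allow_small = allow_small),
               F_TWO_STEP = optimize_two_step(fm, cohort, settings, template,
                                             allow_small)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) failures[[key]] <- res
      results[[key]] <- res
    }
  }
  structure(list(results = results, failures = failures,
                 cohort_label = attr(cohort, "label"), n = nrow(cohort),
                 formulas = formulas, strategies = strategies,
                 settings = settings),
            class = "iol_suite")
}

#' @export
print.iol_suite <- function(x, ...) {
  cat(sprintf("<iol_suite> cohort '%s' (n = %d): %d formulae x %d strategies\n",
              x$cohort_label, x$n, length(x$formulas), length(x$strategies)))
  if (length(x$failures)) {
    cat("failures:\n")
    for (k in names(x$failures)) cat(sprintf("  %s: %s\n", k, x$failures[[k]]))
  }
  print(metrics_table(x), digits = 4)
  invisible(x)
}

#' Fitted-constants table of a strategy suite
#'
#' One row per formula and strategy with the fitted primary constant and,
#' where the strategy tunes them, the refractive offset and keratometer
#' index (wide over constants, long over strategies).
#'
#' @param suite An `iol_suite`.
#' @return data.frame with columns `formula`, `strategy`, `fc`, `ro`, `nk`,
#'   `converged`.
#' @export
constants_table <- function(suite) {
  stopifnot(inherits(suite, "iol_suite"))
  rows <- lapply(names(suite$results), function(key) {
    r <- suite$results[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (is.character(r)) {
      return(data.frame(formula = parts[1], strategy = parts[2], fc = NA_real_,
                        ro = NA_real_, nk = NA_real_, converged = FALSE))
    }
    data.frame(formula = r$formula, strategy = r$strategy, fc = r$constants$fc,
               ro = if (r$strategy %in% c("D_JOINT_FC_RO", "F_TWO_STEP"))
                 r$constants$ro else NA_real_,
               nk = if (r$strategy == "E_JOINT_FC_NK")
                 r$constants$nk else NA_real_,
               converged = r$converged)
  })
  do.call(rbind, rows)
}

#' Prediction-error metrics table of a strategy suite
#'
#' One row per formula and strategy with the prediction-error summary at the
#' fitted constants: MPE, SDPE, RMSPE, and the absolute-error median,
#' quartiles, and 2.5%/97.5% quantiles (the numbers underlying the usual
#' absolute-PE boxplots).
#'
#' @param suite An `iol_suite`.
#' @return data.frame with columns `formula`, `strategy`, `n`, `mpe`,
#'   `sdpe`, `rmspe`, `medae`, `abs_q25`, `abs_q75`, `abs_ci_lo`,
#'   `abs_ci_hi`, `converged`.
#' @export
metrics_table <- function(suite) {
  stopifnot(inherits(suite, "iol_suite"))
  rows <- lapply(names(suite$results), function(key) {
    r <- suite$results[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (is.character(r)) {
      out <- data.frame(formula = parts[1], strategy = parts[2], n = NA_integer_,
                        mpe = NA_real_, sdpe = NA_real_, rmspe = NA_real_,
                        medae = NA_real_, abs_q25 = NA_real_, abs_q75 = NA_real_,
                        abs_ci_lo = NA_real_, abs_ci_hi = NA_real_,
                        converged = FALSE)
      return(out)
    }
    cbind(data.frame(formula = r$formula, strategy = r$strategy),
          as.data.frame(r$stats), data.frame(converged = r$converged))
  })
  do.call(rbind, rows)
}
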