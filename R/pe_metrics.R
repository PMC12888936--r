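#' Refraction prediction errors of a cohort
#'
#' The per-eye formula prediction error, defined as achieved minus predicted
#' spherical-equivalent refraction:
#' `PE_i = seq_achieved_i - seq_pred_i`. With this sign convention a positive
#' refractive offset `ro` in the constant set lowers every PE by the same
#' amount, and the offset that zeroes the mean PE equals the mean PE obtained
#' at `ro = 0`.
#'
#' @param constants An [formula_constants()] object.
#' @param cohort An `iol_cohort`.
#' @return Numeric vector of prediction errors, D, named by `eye_id`.
#' @export
prediction_errors <- function(constants, cohort) {
  stopifnot(inherits(cohort, "iol_cohort"))
  pred <- predict_refraction(constants, cohort)
  pe <- cohort$seq_achieved - pred$seq_pred
  names(pe) <- cohort$eye_id
  pe
}

#' Summary metrics of a prediction-error vector
#'
#' Computes the mean prediction error (MPE), its sample standard deviation
#' (SDPE, n-1 denominator), the root mean squared prediction error
#' (RMSPE = sqrt(mean(PE^2))), and summaries of the absolute prediction
#' error: median, quartiles, and the 2.5%/97.5% quantiles (the whisker limits
#' of the usual absolute-PE boxplots). Quantiles use linear interpolation
#' between order statistics (R type 7). The three global metrics satisfy the
#' exact decomposition `RMSPE^2 = MPE^2 + SDPE^2 * (n-1)/n`.
#'
#' @param pe Numeric vector of prediction errors, D (n >= 1, finite).
#' @return Object of class `pe_stats`: list with `n`, `mpe`, `sdpe` (NA when
#'   n = 1), `rmspe`, `medae`, `abs_q25`, `abs_q75`, `abs_ci_lo`, `abs_ci_hi`.
#' @export
summarize_pe <- function(pe) {
  stopifnot(is.numeric(pe), length(pe) >= 1, all(is.finite(pe)))
  n <- length(pe)
  ape <- abs(pe)
  q <- quantile(ape, c(0.25, 0.75, 0.025, 0.975), names = FALSE, type = 7)
  structure(list(
    n = n,
    mpe = mean(pe),
    sdpe = if (n >= 2) sd(pe) else NA_real_,
    rmspe = sqrt(mean(pe^2)),
    medae = median(ape),
    abs_q25 = q[1], abs_q75 = q[2],
    abs_ci_lo = q[3], abs_ci_hi = q[4]
  ), class = "pe_stats")
}

#' @export
print.pe_stats <- function(x, digits = 4, ...) {
  cat(sprintf("<pe_stats> n = %d\n", x$n))
  cat(sprintf("  MPE %.*f D, SDPE %s D, RMSPE %.*f D\n", digits, x$mpe,
              if (is.na(x$sdpe)) "NA (n = 1)" else formatC(x$sdpe, digits = digits, format = "f"),
              digits, x$rmspe))
  cat(sprintf("  |PE|: median %.*f, IQR [%.*f, %.*f], 95%% CI [%.*f, %.*f]\n",
              digits, x$medae, digits, x$abs_q25, digits, x$abs_q75,
              digits, x$abs_ci_lo, digits, x$abs_ci_hi))
  invisible(x)
}

#' @export
as.data.frame.pe_stats <- function(x, ...) {
  data.frame(n = x$n, mpe = x$mpe, sdpe = x$sdpe, rmspe = x$rmspe,
             medae = x$medae, abs_q25 = x$abs_q25, abs_q75 = x$abs_q75,
             abs_ci_lo = x$abs_ci_lo, abs_ci_hi = x$abs_ci_hi)
}
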