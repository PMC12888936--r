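#' @name iol-formulas
#' @title The four classical IOL power formulae
#'
#' @description
#' The package implements refraction prediction and IOL power calculation for
#' four classical, fully disclosed formulae: SRK/T, Hoffer Q, Holladay 1, and
#' the simplified Haigis formula (ELP coefficients a1/a2 preset to 0.4/0.1 so
#' that only the intercept a0 is tuned). All four are thin-lens vergence
#' models of the pseudophakic eye and differ only in (i) how corneal power is
#' obtained from the measured radius, (ii) the effective lens position (ELP)
#' model, and (iii) the optical axial length (retinal-thickness correction).
#' The package therefore evaluates them through one shared vergence chain
#' (aqueous/vitreous index 1.336, spectacle vertex distance 12 mm),
#' parameterized per formula:
#'
#' * **SRK/T**: corneal height ELP from the A-constant
#'   (`ACDconst = 0.62467*A - 68.747`, offset `-3.336`), axial length
#'   corrected for long eyes (`LCOR`), retinal thickness
#'   `0.65696 - 0.02029*AL`, corneal vergence power `333/r`.
#' * **Hoffer Q**: tangent-based ELP from pACD with the published AL clamps
#'   (18.5/31 mm) and the `M`/`G` piecewise terms; corneal power used
#'   directly; chamber depth enters the vergence as `ELP + 0.05` mm.
#' * **Holladay 1**: anatomical ACD from the corneal-height model
#'   (`Rag >= 7` mm, `AG <= 13.5` mm) plus the surgeon factor SF; optical
#'   axial length `AL + 0.2`; corneal vergence power `(4/3 - 1)*1000/r`.
#' * **Haigis** (simplified): `ELP = a0 + a1*ACD + a2*AL`; corneal power from
#'   the radius with index 1.3315.
#'
#' Keratometric power is always computed from the harmonic-mean corneal
#' radius with the formula's working keratometer index (1.3375 for SRK/T,
#' Hoffer Q and Holladay 1; 1.3315 for Haigis); setting the `nk` field of
#' [formula_constants()] replaces that index uniformly, i.e. rescales the
#' keratometric power, which is how the keratometer index is used as a second
#' tuning constant. The refractive offset `ro` is added to the predicted
#' spherical equivalent as a terminal term and never interacts with the ELP.
#'
#' Out-of-domain intermediate values are clamped exactly where the original
#' publications clamp them (SRK/T corneal-height square root, Hoffer Q axial
#' length, Holladay 1 corneal radius and anterior-segment width); each clamp
#' raises a warning of class `iolconst_clamp` that callers may count or
#' muffle, never a silent adjustment.
NULL

.formula_ids <- c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS")
.native_nk <- c(SRKT = 1.3375, HOFFERQ = 1.3375, HOLLADAY1 = 1.3375,
                HAIGIS = 1.3315)
.fc_bounds_default <- list(SRKT = c(110, 125), HOFFERQ = c(2, 9),
                           HOLLADAY1 = c(-2, 5), HAIGIS = c(-3, 5))
.fc_default <- c(SRKT = 119.0, HOFFERQ = 5.6, HOLLADAY1 = 1.8, HAIGIS = 1.3)
.fc_name <- c(SRKT = "A", HOFFERQ = "pACD", HOLLADAY1 = "SF", HAIGIS = "a0")

`%||%` <- function(a, b) if (is.null(a)) b else a

.match_formula <- function(formula) {
  match.arg(toupper(formula), .formula_ids)
}

#' Formula constant set
#'
#' Bundles a formula's tunable constants: the primary constant `fc`
#' (A-constant for SRK/T, pACD for Hoffer Q, surgeon factor SF for
#' Holladay 1, a0 for Haigis), the Haigis ELP slopes `a1`/`a2` (preset
#' 0.4/0.1), an additive refractive offset `ro` (D, added to the predicted
#' spherical equivalent), and an optional keratometer index override `nk`.
#'
#' @param formula One of `"SRKT"`, `"HOFFERQ"`, `"HOLLADAY1"`, `"HAIGIS"`.
#' @param fc Primary constant; default is a nominal per-formula start value
#'   (A 119.0, pACD 5.6, SF 1.8, a0 1.3). Plausibility bounds: A in
#'   \[110, 125\], pACD in \[2, 9\], SF in \[-2, 5\], a0 in \[-3, 5\].
#' @param a1,a2 Haigis ELP coefficients (ignored by the other formulae).
#' @param ro Refractive offset, D. Default 0.
#' @param nk Keratometer index override in (1.30, 1.38), or `NULL` (default)
#'   for the formula's native index.
#' @return Object of class `iol_constants`.
#' @examples
#' formula_constants("SRKT", fc = 119.0)
#' formula_constants("HAIGIS", fc = 1.3, ro = 0.5)
#' @export
formula_constants <- function(formula, fc = NULL, a1 = 0.4, a2 = 0.1,
                              ro = 0, nk = NULL) {
  formula <- .match_formula(formula)
  fc <- fc %||% unname(.fc_default[formula])
  bounds <- .fc_bounds_default[[formula]]
  stopifnot(is.numeric(fc), length(fc) == 1, is.finite(fc))
  if (fc < bounds[1] || fc > bounds[2]) {
    stop(sprintf("%s constant %g outside plausibility bounds [%g, %g] for %s",
                 .fc_name[formula], fc, bounds[1], bounds[2], formula),
         call. = FALSE)
  }
  if (!is.null(nk)) {
    stopifnot(is.numeric(nk), length(nk) == 1, is.finite(nk))
    if (nk <= 1.30 || nk >= 1.38) {
      stop("keratometer index override must lie in (1.30, 1.38)", call. = FALSE)
    }
  }
  stopifnot(is.numeric(ro), length(ro) == 1, is.finite(ro),
            is.numeric(a1), is.numeric(a2), is.finite(a1), is.finite(a2))
  structure(list(formula = formula, fc = fc, a1 = a1, a2 = a2,
                 ro = ro, nk = nk),
            class = "iol_constants")
}

#' @export
print.iol_constants <- function(x, ...) {
  nk <- x$nk %||% unname(.native_nk[x$formula])
  cat(sprintf("<iol_constants> %s: %s = %.4f, ro = %.4f D, nk = %.4f%s\n",
              x$formula, .fc_name[x$formula], x$fc, x$ro, nk,
              if (is.null(x$nk)) " (native)" else " (tuned)"))
  if (x$formula == "HAIGIS") cat(sprintf("  a1 = %.2f, a2 = %.2f\n", x$a1, x$a2))
  invisible(x)
}

.set_fc <- function(k, fc) { k$fc <- fc; k }

#' Conversions between single formula constants
#'
#' Published regression conversions from the manufacturer A-constant to the
#' internal ACD-type constants of the classical formulae: the SRK/T internal
#' ACD constant (`0.62467*A - 68.747`), the Hoffer Q personalized ACD
#' (`0.58357*A - 63.896`) and the Holladay surgeon factor
#' (`0.5663*A - 65.60`). These are starting-point conversions only and are
#' never applied implicitly; optimized constants should always be derived
#' from outcome data.
#'
#' @param a Manufacturer A-constant.
#' @param to One of `"acd"` (SRK/T internal), `"pacd"` (Hoffer Q),
#'   `"sf"` (Holladay 1).
#' @return Converted constant.
#' @export
convert_a_constant <- function(a, to = c("acd", "pacd", "sf")) {
  to <- match.arg(to)
  switch(to,
         acd  = 0.62467 * a - 68.747,
         pacd = 0.58357 * a - 63.896,
         sf   = 0.5663 * a - 65.60)
}

.signal_clamp <- function(what, n) {
  warning(warningCondition(
    sprintf("%s clamped for %d record(s)", what, n),
    class = "iolconst_clamp"))
}

.as_records <- function(rec) {
  if (inherits(rec, "iol_cohort")) return(as.data.frame(rec))
  if (is.data.frame(rec)) return(rec)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Per-formula optics: corneal vergence power Dc (D), effective lens position
# elp (mm, from the corneal front apex), chamber distance c_eff used in the
# vergence chain (mm), and optical axial length L (mm).
.formula_optics <- function(k, rec) {
  rec <- .as_records(rec)
  al <- rec$al
  r12 <- mean_corneal_radius(rec$r1, rec$r2)
  nk <- k$nk %||% unname(.native_nk[k$formula])
  kd <- keratometric_power(r12, nk)
  switch(k$formula,
    SRKT = {
      r <- 337.5 / kd  # radius on the 1.3375 keratometric scale
      lcor <- ifelse(al > 24.2, -3.446 + 1.716 * al - 0.0237 * al^2, al)
      cw <- -5.41 + 0.58412 * lcor + 0.098 * kd
      disc <- r^2 - cw^2 / 4
      if (any(disc < 0)) .signal_clamp("SRK/T corneal-height square root", sum(disc < 0))
      h <- r - sqrt(pmax(disc, 0))
      elp <- h + 0.62467 * k$fc - 68.747 - 3.336
      list(Dc = 333 / r, elp = elp, c_eff = elp,
           L = al + 0.65696 - 0.02029 * al)
    },
    HOFFERQ = {
      n_clamped <- sum(al < 18.5 | al > 31)
      if (n_clamped) .signal_clamp("Hoffer Q axial length (18.5-31 mm)", n_clamped)
      alc <- pmin(pmax(al, 18.5), 31)
      m <- ifelse(alc <= 23, 1, -1)
      g <- ifelse(alc <= 23, 28, 23.5)
      tand <- function(x) tan(x * pi / 180)
      elp <- k$fc + 0.3 * (alc - 23.5) + tand(kd)^2 +
        0.1 * m * (23.5 - alc)^2 * tand(0.1 * (g - alc)^2) - 0.99166
      list(Dc = kd, elp = elp, c_eff = elp + 0.05, L = al)
    },
    HOLLADAY1 = {
      r <- 337.5 / kd
      if (any(r < 7)) .signal_clamp("Holladay 1 corneal radius (>= 7 mm)", sum(r < 7))
      rag <- pmax(r, 7)
      ag <- pmin(12.5 * al / 23.45, 13.5)
      elp <- 0.56 + rag - sqrt(rag^2 - ag^2 / 4) + k$fc
      list(Dc = (4 / 3 - 1) * 1000 / r, elp = elp, c_eff = elp, L = al + 0.2)
    },
    HAIGIS = {
      elp <- k$fc + k$a1 * rec$acd + k$a2 * al
      list(Dc = kd, elp = elp, c_eff = elp, L = al)
    })
}

# Thin-lens vergence chain of the pseudophakic eye. Distances in mm, powers
# in D, media index n = 1.336, spectacle vertex 12 mm. Forward: spectacle
# refraction that focuses a distant object on the retina given IOL power P.
.vergence_refraction <- function(Dc, c_eff, L, P, n = 1.336, vertex = 12) {
  v3 <- 1000 * n / (L - c_eff) - P            # vergence entering the IOL
  v2 <- 1000 * n / (1000 * n / v3 + c_eff)    # vergence leaving the cornea
  v1 <- v2 - Dc                               # vergence entering the cornea
  v1 / (1 + vertex / 1000 * v1)               # back to the spectacle plane
}

# Inverse chain: IOL power that achieves spectacle refraction S.
.vergence_power <- function(Dc, c_eff, L, S, n = 1.336, vertex = 12) {
  v1 <- S / (1 - vertex / 1000 * S)
  v2 <- v1 + Dc
  v3 <- 1000 * n / (1000 * n / v2 - c_eff)
  1000 * n / (L - c_eff) - v3
}

#' Effective lens position
#'
#' The formula-specific effective lens position (ELP): the fictitious axial
#' position of a thin IOL behind the corneal front apex that the formula uses
#' internally. Tuned by the primary formula constant (and, for Haigis, the
#' a1/a2 slopes).
#'
#' @param constants An [formula_constants()] object.
#' @param records An `iol_cohort`, or a data.frame/list with fields `al`,
#'   `acd`, `r1`, `r2` (mm).
#' @return Numeric vector of ELP values, mm.
#' @export
effective_lens_position <- function(constants, records) {
  stopifnot(inherits(constants, "iol_constants"))
  .formula_optics(constants, records)$elp
}

#' Predict postoperative refraction
#'
#' Back-calculates the spectacle-plane spherical-equivalent refraction that
#' the formula predicts for the implanted IOL power of each record, and adds
#' the refractive offset `ro` of the constant set.
#'
#' @inheritParams effective_lens_position
#' @param records As in [effective_lens_position()], additionally requiring
#'   the implanted power `iolp` (D).
#' @return data.frame with columns `seq_pred` (D) and `elp` (mm), one row per
#'   record.
#' @export
predict_refraction <- function(constants, records) {
  stopifnot(inherits(constants, "iol_constants"))
  rec <- .as_records(records)
  opt <- .formula_optics(constants, rec)
  s <- .vergence_refraction(opt$Dc, opt$c_eff, opt$L, rec$iolp)
  bad <- !is.finite(s)
  if (any(bad)) {
    ids <- if (!is.null(rec$eye_id)) rec$eye_id[bad] else which(bad)
    stop("non-physical vergence chain for record(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  data.frame(seq_pred = s + constants$ro, elp = opt$elp)
}

#' Calculate IOL power for a target refraction
#'
#' Inverts the formula: the IOL power that makes the predicted
#' spherical-equivalent refraction (including the refractive offset `ro`)
#' equal to `target_seq`, optionally rounded to the manufacturing step.
#'
#' @inheritParams effective_lens_position
#' @param target_seq Target spherical-equivalent refraction, D (scalar or one
#'   per record).
#' @param rounding_step Labelling step in D (e.g. 0.5), or `NULL` for the
#'   exact power.
#' @param power_range Admissible power range, D; powers outside raise an
#'   error naming the offending record.
#' @return Numeric vector of IOL powers, D.
#' @export
calc_iol_power <- function(constants, records, target_seq,
                           rounding_step = NULL, power_range = c(-10, 40)) {
  stopifnot(inherits(constants, "iol_constants"), all(is.finite(target_seq)))
  rec <- .as_records(records)
  opt <- .formula_optics(constants, rec)
  p <- .vergence_power(opt$Dc, opt$c_eff, opt$L, target_seq - constants$ro)
  if (!is.null(rounding_step)) {
    stopifnot(rounding_step > 0)
    p <- round(p / rounding_step) * rounding_step
  }
  bad <- !is.finite(p) | p < power_range[1] | p > power_range[2]
  if (any(bad)) {
    ids <- if (!is.null(rec$eye_id)) rec$eye_id[bad] else which(bad)
    stop(sprintf("no IOL power in [%g, %g] D achieves the target for record(s): %s",
                 power_range[1], power_range[2], paste(ids, collapse = ", ")),
         call. = FALSE)
  }
  p
}
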