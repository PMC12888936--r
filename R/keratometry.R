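#' Mean corneal radius
#'
#' Harmonic mean of the corneal front-surface radii of curvature measured in
#' the flat and steep meridians. The harmonic mean of the radii corresponds to
#' the arithmetic mean of the keratometric powers in the two meridians, which
#' is why it (rather than the arithmetic mean of the radii) is the standard
#' summary radius in IOL power calculation.
#'
#' @param r1 Flat-meridian corneal front radius, mm.
#' @param r2 Steep-meridian corneal front radius, mm. Vectors are recycled in
#'   the usual way.
#' @return Mean corneal radius `2*r1*r2/(r1 + r2)`, mm.
#' @examples
#' mean_corneal_radius(7.6, 7.8)
#' @export
mean_corneal_radius <- function(r1, r2) {
  if (any(!is.finite(r1)) || any(!is.finite(r2)) || any(r1 <= 0) || any(r2 <= 0)) {
    stop("corneal radii must be finite and positive", call. = FALSE)
  }
  2 * r1 * r2 / (r1 + r2)
}

#' Keratometric corneal power
#'
#' Converts a corneal radius of curvature into keratometric power using a
#' fictitious keratometer index `nk` via `k = (nk - 1) * 1000 / r12`. The
#' classical Javal index is 1.3375; the Haigis formula uses 1.3315.
#'
#' @param r12 Corneal radius, mm (typically the harmonic-mean radius from
#'   [mean_corneal_radius()]).
#' @param nk Keratometer index, dimensionless, in (1.0, 1.5). Default 1.3375.
#' @return Keratometric power, diopters.
#' @examples
#' keratometric_power(7.5)          # 45 D
#' keratometric_power(7.7626)       # dataset-typical median cornea
#' @export
keratometric_power <- function(r12, nk = 1.3375) {
  if (any(!is.finite(r12)) || any(r12 <= 0)) {
    stop("corneal radius must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(nk)) || any(nk <= 1.0) || any(nk >= 1.5)) {
    stop("keratometer index must lie in (1.0, 1.5)", call. = FALSE)
  }
  (nk - 1) * 1000 / r12
}
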