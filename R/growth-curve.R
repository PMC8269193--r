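## Log-quadratic median weight curves.
##
## Median fetal/birth weight is modelled as
##   log w(ga) = log w_ref + b1 * (ga - ga_ref) + b2 * (ga - ga_ref)^2
## with gestational age in days.  The same parametric family serves the
## synthetic generator's ground-truth curve, the z-score-curve standards and
## the Gardosi-style proportionality term (where it is normalised so that
## the curve equals 1 at the reference term age).

#' Median weight of a log-quadratic growth curve
#'
#' @param ga_days gestational age in days.
#' @param curve list with `w_ref_g` (grams at `ga_ref`), `ga_ref` (days),
#'   `b1`, `b2` (per-day log-scale slope and curvature), and optionally
#'   `scale_log` (additive log-scale calibration shift, default 0).
#' @return median weight in grams.
#' @export
curve_median <- function(ga_days, curve) {
  d <- ga_days - curve$ga_ref
  shift <- if (is.null(curve$scale_log)) 0 else curve$scale_log
  curve$w_ref_g * exp(curve$b1 * d + curve$b2 * d^2 + shift)
}

#' Proportionality: fraction of term weight at a gestational age
#'
#' The Gardosi customization model scales an individualized term optimal
#' weight by a GA-dependent proportion.  Here the proportion is the
#' log-quadratic curve normalised to 1 at `ga_ref`.
#'
#' @param ga_days gestational age in days.
#' @param curve list with `ga_ref`, `b1`, `b2`.
#' @return proportion in (0, 1] over the supported antenatal span.
#' @export
proportionality <- function(ga_days, curve) {
  d <- ga_days - curve$ga_ref
  exp(curve$b1 * d + curve$b2 * d^2)
}
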