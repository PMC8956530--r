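#' Sigmoidal vulnerability-curve model
#'
#' The specific-conductivity reformulation of the Pammenter-Vander Willigen
#' sigmoid models the expected conductivity of a branch segment spun at
#' xylem pressure \eqn{\Psi} (MPa, negative) as
#' \deqn{K_s(\Psi) = K_{max} \left(1 - \frac{1}{1 + \exp(s (\Psi - P_{50}))}\right),}
#' so the fractional loss of conductivity is the logistic
#' \eqn{L(\Psi) = 1 / (1 + \exp(s(\Psi - P_{50})))}. `loss_fraction()`
#' evaluates \eqn{L}; `vc_conductivity()` evaluates \eqn{K_s}.
#'
#' @param pressure Xylem pressure \eqn{\Psi} in MPa (negative under tension).
#' @param p50 Pressure at 50\% loss of conductivity, MPa.
#' @param slope Logit-scale slope \eqn{s} in MPa\eqn{^{-1}}; must be > 0.
#' @return `loss_fraction()`: loss fraction in \[0, 1\];
#'   `vc_conductivity()`: expected conductivity (same units as `kmax`).
#' @examples
#' loss_fraction(-3, p50 = -3, slope = 2)   # 0.5 at the midpoint
#' loss_fraction(-2, p50 = -3, slope = 2)   # 1 / (1 + e^2)
#' @export
loss_fraction <- function(pressure, p50, slope) {
  if (!all(is.finite(pressure)) || !all(is.finite(p50)) ||
      !all(is.finite(slope)))
    stopf("loss_fraction(): all inputs must be finite")
  if (any(slope <= 0)) stopf("loss_fraction(): `slope` must be > 0")
  stats::plogis(-(slope * (pressure - p50)))
}

#' @param kmax Maximum (fully flushed) conductivity \eqn{K_{max}}.
#' @rdname loss_fraction
#' @export
vc_conductivity <- function(pressure, kmax, p50, slope) {
  kmax * (1 - loss_fraction(pressure, p50, slope))
}

#' Pressure at a given loss of conductivity
#'
#' Inverts the logistic loss function: the xylem pressure at which the
#' modelled loss of conductivity equals `q` is
#' \deqn{\Psi_q = P_{50} + \log((1 - q)/q) / s.}
#' The conventional summary pressures are `q = 0.12` (P12, air-entry
#' region), `q = 0.5` (P50) and `q = 0.88` (P88, full-embolism region).
#'
#' @inheritParams loss_fraction
#' @param q Target loss fraction, strictly inside (0, 1). Vectorised.
#' @return Pressure in MPa at which the modelled loss equals `q`.
#' @examples
#' pressure_at_loss(-3, 2, 0.5)    # exactly P50
#' pressure_at_loss(-3, 2, 0.12)   # P12, less negative than P50
#' @export
pressure_at_loss <- function(p50, slope, q) {
  if (!all(is.finite(p50)) || !all(is.finite(slope)) || !all(is.finite(q)))
    stopf("pressure_at_loss(): all inputs must be finite")
  if (any(slope <= 0)) stopf("pressure_at_loss(): `slope` must be > 0")
  if (any(q <= 0 | q >= 1))
    stopf("pressure_at_loss(): `q` must lie strictly in (0, 1)")
  p50 + log((1 - q) / q) / slope
}
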