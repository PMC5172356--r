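#' Lipari-Szabo model-free spectral density
#'
#' Evaluates
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2}
#'   + \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right], \quad
#'   \tau^{-1} = \tau_m^{-1} + \tau_e^{-1}}
#' the standard two-parameter motional model for a backbone N-H vector riding
#' on isotropic overall tumbling. Used here as the generative ground truth for
#' simulated relaxation data and as the rigid-rotor reference
#' (\eqn{S^2 = 1, \tau_e = 0}, where \eqn{J(0) = 2\tau_m/5}).
#'
#' @param omega angular frequency, rad/s (vectorized).
#' @param s2 order parameter in `[0, 1]`.
#' @param tau_m overall rotational correlation time, ns.
#' @param tau_e effective internal correlation time, ps (0 = none).
#' @return J(omega) in seconds (s/rad), same length as `omega`.
#' @examples
#' model_free_j(0, s2 = 1, tau_m = 10) * 1e9  # 4 ns
#' @export
model_free_j <- function(omega, s2, tau_m, tau_e = 0) {
  if (s2 < 0 || s2 > 1) stop("s2 must lie in [0, 1]")
  if (tau_m <= 0) stop("tau_m must be positive")
  if (tau_e < 0) stop("tau_e must be non-negative")
  tm <- tau_m * 1e-9
  te <- tau_e * 1e-12
  tau <- if (te > 0) 1 / (1 / tm + 1 / te) else 0
  (2 / 5) * (s2 * tm / (1 + (omega * tm)^2) +
               (1 - s2) * tau / (1 + (omega * tau)^2))
}

#' Forward 15N relaxation equations (full five-frequency form)
#'
#' Computes the longitudinal rate R1, the transverse rate R2 and the
#' steady-state heteronuclear NOE from a spectral density evaluator:
#' \deqn{R_1 = \tfrac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + \tfrac{c^2}{6}[4J(0) +
#'   3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \tfrac{d^2}{4}\frac{\gamma_H}{\gamma_N}
#'   \frac{6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)}{R_1}}
#' When R1 is zero the cross-relaxation term is undefined; the NOE is then
#' returned as exactly 1 (no enhancement).
#'
#' This function is the shared oracle between the simulator and the reduced
#' spectral density mapping: simulated data are generated from it, and the
#' mapping is validated against it.
#'
#' @param j function of angular frequency (rad/s) returning J in seconds, or a
#'   named numeric vector/list with entries `j0`, `j_wn`, `j_wh` in seconds to
#'   use the high-frequency-lumped (reduced) form.
#' @param constants a [spin_constants()] object.
#' @param rex exchange contribution to R2, s^-1.
#' @return list with `r1`, `r2` (s^-1) and `noe` (dimensionless).
#' @examples
#' sc <- spin_constants()
#' forward_rates(function(w) model_free_j(w, 1, 10), sc)
#' @export
forward_rates <- function(j, constants = spin_constants(), rex = 0) {
  if (!inherits(constants, "spin_constants"))
    stop("constants must be a spin_constants object")
  if (rex < 0) stop("rex must be non-negative")
  wh <- constants$omega_h
  wn <- constants$omega_n
  if (is.function(j)) {
    j0 <- j(0); jn <- j(abs(wn)); jh <- j(wh)
    jhmn <- j(abs(wh - wn)); jhpn <- j(wh + abs(wn))
  } else {
    j <- as.list(j)
    if (!all(c("j0", "j_wn", "j_wh") %in% names(j)))
      stop("j must be a function or carry j0, j_wn, j_wh")
    # reduced form: lump J(wH-wN) = J(wH) = J(wH+wN) = J(0.87 wH)
    j0 <- j$j0; jn <- j$j_wn; jh <- jhmn <- jhpn <- j$j_wh
  }
  jv <- c(j0, jn, jh, jhmn, jhpn)
  if (any(!is.finite(jv)) || any(jv < 0))
    stop("spectral density must be finite and non-negative at the five frequencies")
  d2 <- constants$d2
  c2 <- constants$c2
  r1 <- d2 / 4 * (jhmn + 3 * jn + 6 * jhpn) + c2 * jn
  r2 <- d2 / 8 * (4 * j0 + jhmn + 3 * jn + 6 * jh + 6 * jhpn) +
    c2 / 6 * (4 * j0 + 3 * jn) + rex
  sigma <- d2 / 4 * (6 * jhpn - jhmn)
  noe <- if (r1 > 0) 1 + (constants$gamma_h / constants$gamma_n) * sigma / r1 else 1
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Forward rates from reduced (three-frequency) spectral densities
#'
#' Convenience wrapper around [forward_rates()] for the high-frequency-lumped
#' form used by reduced spectral density mapping, taking J values in ns as
#' produced by [reduced_spectral_density()]. The composition
#' `reduced_spectral_density(forward_rates_reduced(...))` is the identity.
#'
#' @param j0,j_wn,j_wh spectral densities in ns.
#' @inheritParams forward_rates
#' @return list with `r1`, `r2`, `noe`.
#' @export
forward_rates_reduced <- function(j0, j_wn, j_wh, constants = spin_constants(),
                                  rex = 0) {
  forward_rates(list(j0 = j0 * 1e-9, j_wn = j_wn * 1e-9, j_wh = j_wh * 1e-9),
                constants = constants, rex = rex)
}
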