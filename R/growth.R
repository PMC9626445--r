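# Growth-rate laws and the pointwise updates of the growth stretch g and the
# solid volume fraction. All rates in 1/day; stresses in MPa.

#' Nutrient-limited, contact-inhibited proliferation rate
#'
#' \eqn{\Gamma_s = \gamma \phi_s (\phi_{max} - \phi_s)(c_n - c_0)_+},
#' optionally multiplied by the compressive-stress inhibition factor when a
#' compression measure `Sigma` is supplied. Vectorized over its field
#' arguments.
#'
#' @param phi_s Solid volume fraction(s) in (0, 1).
#' @param c_n Normalized nutrient concentration(s).
#' @param params A [growth_params()] object.
#' @param Sigma Optional compression measure (MPa); when given, the rate is
#'   multiplied by [stress_inhibition_factor()].
#' @return Net growth rate (1/day), zero when `c_n <= c0` or
#'   `phi_s >= phi_max`.
#' @export
growth_rate <- function(phi_s, c_n, params = growth_params(), Sigma = NULL) {
  stopifnot(inherits(params, "gm_growth_params"))
  rate <- params$gamma * phi_s * pmax(params$phi_max - phi_s, 0) *
    pmax(c_n - params$c0, 0)
  if (!is.null(Sigma))
    rate <- rate * stress_inhibition_factor(Sigma, params$delta1, params$delta2)
  rate
}

#' Growth inhibition factor under compressive stress
#'
#' \eqn{1 - \delta_1 \Sigma_+ / (\Sigma_+ + \delta_2)}: equal to 1 under
#' traction (`Sigma <= 0`), monotone non-increasing in `Sigma`, saturating at
#' `1 - delta1` under strong compression. Vectorized over `Sigma`.
#'
#' @param Sigma Compression measure (MPa); positive in compression.
#' @param delta1 Maximum fractional inhibition (`0 <= delta1 < 1`).
#' @param delta2 Compression scale (MPa, > 0).
#' @return Factor in `(1 - delta1, 1]`.
#' @export
stress_inhibition_factor <- function(Sigma, delta1, delta2) {
  stopifnot(delta1 >= 0, delta1 < 1, delta2 > 0)
  Sp <- pmax(Sigma, 0)
  1 - delta1 * Sp / (Sp + delta2)
}

#' Net nutrient source
#'
#' \eqn{G_n = -\zeta \phi_s \phi_l c_n + S_n (1 - c_n) \phi_l}: uptake by
#' tumour cells at constant rate `zeta` plus vascular supply at rate `S_n`
#' whenever the concentration is below the physiological value 1.
#'
#' @param phi_s,phi_l Solid and fluid volume fractions (must satisfy
#'   `phi_s + phi_l = 1`).
#' @param c_n Normalized nutrient concentration.
#' @param params A [growth_params()] object.
#' @return Source term (1/day).
#' @export
nutrient_source <- function(phi_s, phi_l, c_n, params = growth_params()) {
  stopifnot(inherits(params, "gm_growth_params"))
  if (max(abs(phi_s + phi_l - 1)) > 1e-12)
    stop("saturation violated: phi_s + phi_l must equal 1")
  -params$zeta * phi_s * phi_l * c_n + params$S_n * (1 - c_n) * phi_l
}

#' Explicit Euler update of the growth stretch
#'
#' \eqn{g^{k+1} = g^k (1 + \Delta t\, \Gamma_s^k / (3 \phi_s^k)\, \chi)}.
#' The growth stretch never decreases (`Gamma_s >= 0`) and is frozen at 1
#' wherever the reference tumour indicator `chi_ref` is zero. Vectorized.
#'
#' @param g_k Current growth stretch(es), `>= 1`.
#' @param Gamma_s_k Growth rate(s) at the current level (1/day).
#' @param phi_s_k Current solid fraction(s), `> 0`.
#' @param chi_ref Reference tumour indicator value(s) in `[0, 1]`.
#' @param dt Time step (day).
#' @return Updated growth stretch(es).
#' @export
update_g <- function(g_k, Gamma_s_k, phi_s_k, chi_ref, dt) {
  stopifnot(dt > 0)
  if (any(phi_s_k <= 0))
    stop("phi_s must be positive in the growth update (corrupted state)")
  g_k * (1 + dt * Gamma_s_k / (3 * phi_s_k) * chi_ref)
}

#' Solid fraction from the growth/volume constraint
#'
#' Mass conservation of the growing solid gives
#' \eqn{J_s \phi_s = J_g \phi_{sn}}, hence
#' \eqn{\phi_s = (g^3 / J_s)\, \phi_{sn}}. Errors if the result leaves
#' `(0, 1)`, which signals elastic compression beyond the physical bound.
#'
#' @param J_s Volume ratio(s) `det F_s > 0`.
#' @param g Growth stretch(es) `>= 1`.
#' @param phi_sn Natural-state solid fraction.
#' @return Solid fraction(s) `phi_s`.
#' @export
update_phi_s <- function(J_s, g, phi_sn) {
  stopifnot(all(J_s > 0), all(g >= 1), phi_sn > 0, phi_sn < 1)
  phi_s <- g^3 / J_s * phi_sn
  if (any(phi_s >= 1) || any(phi_s <= 0))
    stop("saturation violation: phi_s outside (0, 1) ",
         "(elastic compression exceeded the physical bound)")
  phi_s
}
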