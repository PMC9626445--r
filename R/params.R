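#' Mooney--Rivlin material parameters for tumour and healthy tissue
#'
#' The solid (cell) phase of both tissues is an isotropic hyperelastic material
#' with an isochoric Mooney--Rivlin energy (parameters `mu1`, `mu2`) and a
#' logarithmic volumetric energy (modulus `kappa`). Units are MPa throughout.
#' Defaults are the literature estimates for glioma (tumour roughly ten times
#' stiffer than host brain).
#'
#' @param mu1_t,mu2_t,kappa_t Tumour-region moduli (MPa).
#' @param mu1_h,mu2_h,kappa_h Healthy-region moduli (MPa).
#' @return An object of class `gm_material_params`.
#' @export
material_params <- function(mu1_t = 1.53e-3, mu2_t = 2.97e-3, kappa_t = 1.40e-3,
                            mu1_h = 1.53e-4, mu2_h = 2.97e-4, kappa_h = 1.40e-4) {
  p <- list(mu1_t = mu1_t, mu2_t = mu2_t, kappa_t = kappa_t,
            mu1_h = mu1_h, mu2_h = mu2_h, kappa_h = kappa_h)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("material_params: '", nm, "' must be a single positive number")
  }
  structure(p, class = "gm_material_params")
}

#' Holmes--Mow permeability parameters
#'
#' The scalar hydraulic mobility is
#' \deqn{k(J_e) = k_0 \left(\frac{J_e - \phi_{sn}}{1 - \phi_{sn}}\right)^{\alpha_0}
#'       e^{m (J_e^2 - 1)/2},}
#' an exponential power law in the elastic volume ratio that vanishes as the
#' pores close (`J_e -> phi_sn`). `k0` has units mm^2 MPa^-1 day^-1.
#'
#' @param k0 Reference mobility at `J_e = 1` (mm^2 MPa^-1 day^-1).
#' @param alpha0,m Dimensionless exponents.
#' @param phi_sn Solid volume fraction in the natural (stress-free) state.
#' @return An object of class `gm_permeability_params`.
#' @export
permeability_params <- function(k0 = 2.17e5, alpha0 = 0.0848, m = 4.638,
                                phi_sn = 0.3) {
  stopifnot(is.numeric(k0), length(k0) == 1L, k0 > 0,
            is.numeric(alpha0), length(alpha0) == 1L, alpha0 > 0,
            is.numeric(m), length(m) == 1L,
            is.numeric(phi_sn), length(phi_sn) == 1L,
            phi_sn > 0, phi_sn < 1)
  structure(list(k0 = k0, alpha0 = alpha0, m = m, phi_sn = phi_sn),
            class = "gm_permeability_params")
}

#' Growth-law and nutrient parameters
#'
#' Parameters of the nutrient-limited, contact-inhibited proliferation rate
#' \deqn{\Gamma_s = \gamma \phi_s (\phi_{max} - \phi_s)(c_n - c_0)_+}
#' optionally multiplied by the compressive-stress inhibition factor
#' \eqn{1 - \delta_1 \Sigma_+ / (\Sigma_+ + \delta_2)}, and of the nutrient
#' source \eqn{G_n = -\zeta \phi_s \phi_l c_n + S_n (1 - c_n)\phi_l}.
#'
#' @param gamma Cell proliferation constant (1/day).
#' @param c0 Hypoxia threshold (normalized concentration).
#' @param phi_max Maximum packing fraction of the cell phase.
#' @param delta1 Maximum fractional growth inhibition by compression (< 1).
#' @param delta2 Compression scale of the inhibition law (MPa).
#' @param zeta Nutrient consumption rate (1/day); see
#'   [nutrient_consumption_rate()] for its derivation from the oxygen diffusion
#'   coefficient and uptake length.
#' @param S_n Vascular nutrient supply rate (1/day).
#' @param phi_sn Solid fraction in the natural state.
#' @return An object of class `gm_growth_params`.
#' @export
growth_params <- function(gamma = 0.5, c0 = 0.3, phi_max = 0.85,
                          delta1 = 0.8, delta2 = 1e-4,
                          zeta = 8640, S_n = 1e4, phi_sn = 0.3) {
  stopifnot(gamma >= 0, c0 > 0, c0 < 1, phi_max < 1, phi_sn < phi_max,
            delta1 >= 0, delta1 < 1, delta2 > 0, zeta >= 0, S_n >= 0,
            phi_sn > 0)
  structure(list(gamma = gamma, c0 = c0, phi_max = phi_max,
                 delta1 = delta1, delta2 = delta2,
                 zeta = zeta, S_n = S_n, phi_sn = phi_sn),
            class = "gm_growth_params")
}

#' Nutrient consumption rate from oxygen diffusivity and uptake length
#'
#' The consumption rate is estimated as \eqn{\zeta = D_n / l_n^2} from the
#' oxygen diffusion coefficient in brain tissue `D_n` and the distance `l_n`
#' an oxygen molecule travels before uptake by a tumour cell.
#'
#' @param D_n Oxygen diffusion coefficient (mm^2/day).
#' @param l_n Uptake length (mm).
#' @return Consumption rate (1/day); the defaults give 8640/day.
#' @export
nutrient_consumption_rate <- function(D_n = 86.4, l_n = 0.1) {
  stopifnot(D_n > 0, l_n > 0)
  D_n / l_n^2
}

#' Simulation configuration
#'
#' Collects the time discretization, parameter blocks, growth-law variant,
#' boundary-condition mode and Newton controls used by [run_simulation()].
#'
#' @param dt Time step (day). The coupled system is advanced by a semi-implicit
#'   Euler scheme; 0.1 day keeps the cellwise advective CFL numbers well below
#'   one on the phantom geometries.
#' @param t_end Final time (day).
#' @param material A [material_params()] object.
#' @param growth A [growth_params()] object.
#' @param permeability A [permeability_params()] object.
#' @param growth_law `"plain"` (nutrient-limited only) or `"stress_inhibited"`.
#' @param r Anisotropy enhancement factor for the preferential-direction
#'   tensor (`r = 1`: no enhancement).
#' @param bc_mode Boundary conditions for pressure and nutrients:
#'   `"dirichlet"` (p = 0, c = 1 on the outer boundary) or `"zero_flux"`.
#'   Displacement is always clamped (u = 0) at the skull boundary.
#' @param newton_rtol,newton_atol,newton_maxit Newton controls (blockwise
#'   scaled residual norms).
#' @param stabilize Add a pressure-gradient (Brezzi--Pitkaranta type)
#'   stabilization term to the mass balance; off by default, matching the
#'   plain equal-order P1--P1 pairing.
#' @param output_every Record a state checkpoint every this many steps.
#' @return An object of class `gm_config`.
#' @export
simulation_config <- function(dt = 0.1, t_end = 10,
                              material = material_params(),
                              growth = growth_params(),
                              permeability = permeability_params(),
                              growth_law = c("plain", "stress_inhibited"),
                              r = 1,
                              bc_mode = c("dirichlet", "zero_flux"),
                              newton_rtol = 1e-8, newton_atol = 1e-10,
                              newton_maxit = 25,
                              stabilize = FALSE,
                              output_every = 10L) {
  growth_law <- match.arg(growth_law)
  bc_mode <- match.arg(bc_mode)
  stopifnot(dt > 0, t_end >= dt, r >= 1,
            inherits(material, "gm_material_params"),
            inherits(growth, "gm_growth_params"),
            inherits(permeability, "gm_permeability_params"))
  structure(list(dt = dt, t_end = t_end, material = material, growth = growth,
                 permeability = permeability, growth_law = growth_law, r = r,
                 bc_mode = bc_mode, newton_rtol = newton_rtol,
                 newton_atol = newton_atol, newton_maxit = newton_maxit,
                 stabilize = stabilize,
                 output_every = as.integer(output_every)),
            class = "gm_config")
}
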