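# Pointwise finite-strain kinematics and the hyperelastic constitutive law.
# All quantities in mm / day / MPa.

.eye3 <- diag(3)

.check_mat3 <- function(A, name) {
  if (!is.matrix(A) || !all(dim(A) == c(3L, 3L)) || !all(is.finite(A)))
    stop(name, " must be a finite 3x3 matrix")
}

#' Multiplicative elastic/growth kinematics at a material point
#'
#' Builds the deformation gradient `F_s = I + grad_u`, splits it into an
#' isotropic growth part `F_g = g I` and an elastic part `F_e = F_s / g`, and
#' derives the volume ratios `J_s = det F_s`, `J_g = g^3`, `J_e = J_s / J_g`,
#' the elastic right Cauchy--Green tensor `C_e = F_e' F_e` and its isochoric
#' (unimodular) part `Cbar_e = J_e^(-2/3) C_e`.
#'
#' @param grad_u Material displacement gradient (3x3, dimensionless).
#' @param g Scalar growth stretch, `g >= 1`.
#' @return An object of class `gm_kinematics` with fields `F_s`, `F_g`, `F_e`,
#'   `g`, `J_s`, `J_g`, `J_e`, `C_e`, `Cbar_e`.
#' @examples
#' k <- compute_kinematics(matrix(0, 3, 3), g = 1)
#' k$J_e  # 1 in the undeformed state
#' @export
compute_kinematics <- function(grad_u, g = 1) {
  .check_mat3(grad_u, "grad_u")
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
  if (g < 1) stop("growth stretch g must be >= 1")
  F_s <- .eye3 + grad_u
  J_s <- det(F_s)
  if (J_s <= 0) stop("non-positive J_s: element inverted (det(I + grad_u) <= 0)")
  F_e <- F_s / g
  J_g <- g^3
  J_e <- J_s / J_g
  C_e <- crossprod(F_e)
  structure(list(F_s = F_s, F_g = g * .eye3, F_e = F_e, g = g,
                 J_s = J_s, J_g = J_g, J_e = J_e,
                 C_e = C_e, Cbar_e = J_e^(-2 / 3) * C_e),
            class = "gm_kinematics")
}

#' Isochoric Mooney--Rivlin strain energy density
#'
#' \eqn{W_i = \frac{1}{2}\mu_1 (I_{\bar C} - 3) + \frac{1}{2}\mu_2 (II_{\bar C} - 3)}
#' where \eqn{I, II} are the first and second principal invariants of the
#' unimodular elastic Cauchy--Green tensor. Zero in the undeformed state.
#'
#' @param Cbar_e Unimodular elastic Cauchy--Green tensor (3x3, symmetric,
#'   `det = 1` to tolerance).
#' @param mu1,mu2 Mooney--Rivlin moduli (MPa).
#' @return Energy density (MPa, i.e. per unit natural-state volume).
#' @export
isochoric_energy <- function(Cbar_e, mu1, mu2) {
  .check_mat3(Cbar_e, "Cbar_e")
  if (max(abs(Cbar_e - t(Cbar_e))) > 1e-8 * max(1, max(abs(Cbar_e))))
    stop("Cbar_e must be symmetric")
  if (abs(det(Cbar_e) - 1) > 1e-6)
    stop("Cbar_e must be unimodular (det = 1)")
  I1 <- sum(diag(Cbar_e))
  I2 <- 0.5 * (I1^2 - sum(diag(Cbar_e %*% Cbar_e)))
  0.5 * mu1 * (I1 - 3) + 0.5 * mu2 * (I2 - 3)
}

#' Logarithmic volumetric strain energy density
#'
#' \eqn{W_v = \frac{1}{2}\kappa (\ln J_e)^2}; even in `ln J_e`, so expansion
#' and the reciprocal compression store the same energy.
#'
#' @param J_e Elastic volume ratio (> 0).
#' @param kappa Volumetric modulus (MPa).
#' @return Energy density (MPa).
#' @export
volumetric_energy <- function(J_e, kappa) {
  stopifnot(is.numeric(J_e), all(is.finite(J_e)))
  if (any(J_e <= 0)) stop("J_e must be positive")
  0.5 * kappa * log(J_e)^2
}

# Deviatoric + spherical Cauchy stress of one tissue (single parameter set).
.cauchy_one <- function(kin, mu1, mu2, kappa) {
  Je <- kin$J_e
  Bbar <- Je^(-2 / 3) * tcrossprod(kin$F_e)   # unimodular left Cauchy-Green
  I1 <- sum(diag(Bbar))
  B2 <- Bbar %*% Bbar
  dev_raw <- 0.5 * mu1 * Bbar + 0.5 * mu2 * (I1 * Bbar - B2)
  T_dev <- (2 / Je) * (dev_raw - (sum(diag(dev_raw)) / 3) * .eye3)
  T_vol <- kappa * log(Je) / Je * .eye3
  list(dev = T_dev, vol = T_vol)
}

#' Cauchy stress of the solid phase
#'
#' Evaluates the constitutive Cauchy stress from the isochoric Mooney--Rivlin
#' plus logarithmic volumetric energy, blended pointwise across the diffuse
#' tumour interface: `T_s = chi * T_s(tumour params) + (1 - chi) * T_s(healthy
#' params)`. The deviatoric part is traceless; the spherical part is
#' `kappa * ln(J_e)/J_e * I`. Also returns the constitutive first
#' Piola--Kirchhoff stress `P_s = J_s T_s F_s^-T`, the total first
#' Piola--Kirchhoff stress `P = -J_s p F_s^-T + P_s` for a given fluid
#' pressure, and the compression measure `Sigma = -tr(T_s)/3`.
#'
#' @param kin A [compute_kinematics()] object.
#' @param params A [material_params()] object.
#' @param chi Tumour indicator value in `[0, 1]` at the point.
#' @param p Fluid pressure (MPa), used only for the total stress `P`.
#' @return An object of class `gm_stress` with fields `T_s`, `T_s_dev`,
#'   `T_s_vol`, `P_s`, `P`, `Sigma`.
#' @export
cauchy_stress <- function(kin, params, chi, p = 0) {
  stopifnot(inherits(kin, "gm_kinematics"),
            inherits(params, "gm_material_params"),
            is.numeric(chi), length(chi) == 1L, chi >= 0, chi <= 1)
  st_t <- .cauchy_one(kin, params$mu1_t, params$mu2_t, params$kappa_t)
  st_h <- .cauchy_one(kin, params$mu1_h, params$mu2_h, params$kappa_h)
  T_dev <- chi * st_t$dev + (1 - chi) * st_h$dev
  T_vol <- chi * st_t$vol + (1 - chi) * st_h$vol
  T_s <- T_dev + T_vol
  FinvT <- t(solve(kin$F_s))
  P_s <- kin$J_s * T_s %*% FinvT
  structure(list(T_s = T_s, T_s_dev = T_dev, T_s_vol = T_vol,
                 P_s = P_s, P = -kin$J_s * p * FinvT + P_s,
                 Sigma = compression_measure(T_s)),
            class = "gm_stress")
}

#' Compression measure from a Cauchy stress tensor
#'
#' `Sigma = -tr(T_s)/3`: positive under compression, zero for a traceless
#' (purely deviatoric) stress. This is the quantity entering the
#' stress-inhibited growth law.
#'
#' @param T_s Symmetric Cauchy stress tensor (3x3, MPa).
#' @return Scalar `Sigma` (MPa).
#' @export
compression_measure <- function(T_s) {
  .check_mat3(T_s, "T_s")
  if (max(abs(T_s - t(T_s))) > 1e-8 * max(1, max(abs(T_s))))
    stop("T_s must be symmetric")
  -sum(diag(T_s)) / 3
}

#' Holmes--Mow hydraulic mobility
#'
#' \eqn{k(J_e) = k_0 ((J_e - \phi_{sn})/(1 - \phi_{sn}))^{\alpha_0}
#'      e^{m(J_e^2 - 1)/2}}, equal to `k0` at `J_e = 1`, vanishing at pore
#' closure and strictly increasing in `J_e` for the default parameters.
#' Vectorized over `J_e`.
#'
#' @param J_e Elastic volume ratio(s), each `> phi_sn`.
#' @param params A [permeability_params()] object.
#' @return Mobility (mm^2 MPa^-1 day^-1).
#' @export
holmes_mow_k <- function(J_e, params = permeability_params()) {
  stopifnot(inherits(params, "gm_permeability_params"),
            is.numeric(J_e), all(is.finite(J_e)))
  if (any(J_e <= params$phi_sn))
    stop("compaction limit reached: J_e <= phi_sn (pores closed)")
  params$k0 * ((J_e - params$phi_sn) / (1 - params$phi_sn))^params$alpha0 *
    exp(params$m * (J_e^2 - 1) / 2)
}
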