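# Derived quantities: tumour volume series and growth metrics (VDT, SGR,
# VRE), ray profiles, and anisotropy-change maps.

#' Current tumour volume
#'
#' Integrates the deformed volume `J_s dV` over the reference cells whose
#' barycentric tumour indicator exceeds the 0.1 threshold, in cm^3. Because
#' the indicator is transported with the solid phase (Lagrangian frame), this
#' is also the current-frame volume of the tumour region.
#'
#' @param state A `gm_state` object.
#' @param prob A [prepare_problem()] object.
#' @param threshold Upper-level-set threshold defining the tumour region.
#' @return Volume in cm^3.
#' @export
tumour_volume <- function(state, prob, threshold = 0.1) {
  sel <- prob$chi_cell > threshold
  sum(prob$vol[sel] * state$cell$J_s[sel]) / 1e3
}

#' Volume doubling time, specific growth rate and radial expansion velocity
#'
#' * VDT: first time the volume reaches twice its initial value, by linear
#'   interpolation between outputs (`NA` if never reached);
#' * SGR: `100 * ln(2) / VDT` in percent per day;
#' * VRE: mean slope of the equivalent-sphere radius
#'   `r(t) = (3V / 4 pi)^(1/3)` over the full horizon, in mm/year
#'   (365 days).
#'
#' @param times Output times (day).
#' @param volumes Tumour volumes at those times (cm^3).
#' @return List with `VDT` (day), `SGR` (percent/day), `VRE` (mm/year).
#' @export
growth_metrics <- function(times, volumes) {
  stopifnot(length(times) == length(volumes), length(times) >= 2,
            all(volumes > 0))
  V0 <- volumes[1]
  target <- 2 * V0
  VDT <- NA_real_
  hit <- which(volumes >= target)
  if (length(hit)) {
    i <- hit[1]
    if (i == 1L) VDT <- times[1]
    else VDT <- times[i - 1] + (target - volumes[i - 1]) *
        (times[i] - times[i - 1]) / (volumes[i] - volumes[i - 1])
  }
  SGR <- if (is.na(VDT)) NA_real_ else 100 * log(2) / VDT
  r <- (3 * volumes * 1e3 / (4 * pi))^(1 / 3)  # mm (volumes in cm^3)
  VRE <- (r[length(r)] - r[1]) / (times[length(times)] - times[1]) * 365
  list(VDT = VDT, SGR = SGR, VRE = VRE)
}

#' Sample a nodal field along a ray
#'
#' P1-interpolates `field` at `n` equispaced points from `origin` along
#' `direction`, in the reference frame by default or in the deformed frame
#' (nodes displaced by `u`) when requested. Samples falling outside the mesh
#' are dropped with a warning (truncated profile).
#'
#' @param mesh A `gm_mesh` object.
#' @param field Nodal values.
#' @param origin Ray origin (mm).
#' @param direction Ray direction (normalized internally).
#' @param length_mm Ray length (mm).
#' @param n Number of samples.
#' @param frame `"reference"` or `"deformed"`.
#' @param u Nodal displacements (required for the deformed frame).
#' @return data.frame with arc length `s` (mm) and `value`.
#' @export
ray_profile <- function(mesh, field, origin, direction, length_mm, n = 50,
                        frame = c("reference", "deformed"), u = NULL) {
  frame <- match.arg(frame)
  d <- direction / sqrt(sum(direction^2))
  s <- seq(0, length_mm, length.out = n)
  pts <- outer(s, d) + matrix(origin, n, 3, byrow = TRUE)
  m <- mesh
  if (frame == "deformed") {
    if (is.null(u)) stop("deformed-frame sampling needs the displacement u")
    m <- mesh
    m$nodes <- mesh$nodes + u
  }
  val <- interpolate_p1(m, field, pts)
  if (anyNA(val)) {
    warning("ray leaves the mesh; profile truncated")
    keep <- !is.na(val)
    s <- s[keep]; val <- val[keep]
  }
  data.frame(s = s, value = val)
}

#' Cellwise anisotropy-change maps between two tensor fields
#'
#' Computes per cell the fractional-anisotropy change `FA_final - FA_initial`
#' and, in cells whose initial FA exceeds `fa_threshold` (anisotropic regions
#' where a leading eigenvector is meaningful), the leading-eigenvector change
#' metrics `s`, `|d theta|`, `|d phi|` of [eigenvector_change()]; elsewhere
#' those are `NA`.
#'
#' @param D0_field,D_final_field ne x 6 cell tensor fields (components
#'   xx, xy, xz, yy, yz, zz) on the same mesh.
#' @param fa_threshold FA mask threshold (default 0.1).
#' @return data.frame with `FA_initial`, `FA_final`, `dFA`, `s`,
#'   `d_theta_abs`, `d_phi_abs` (one row per cell).
#' @export
anisotropy_change_maps <- function(D0_field, D_final_field,
                                   fa_threshold = 0.1) {
  if (nrow(D0_field) != nrow(D_final_field))
    stop("mismatched cell counts between initial and final tensor fields")
  sp0 <- .cell_spectral(D0_field)
  spf <- .cell_spectral(D_final_field)
  fa0 <- fractional_anisotropy(sp0$lambda[, 1], sp0$lambda[, 2],
                               sp0$lambda[, 3])
  faf <- fractional_anisotropy(spf$lambda[, 1], spf$lambda[, 2],
                               spf$lambda[, 3])
  ne <- nrow(D0_field)
  s <- dth <- dph <- rep(NA_real_, ne)
  for (e in which(fa0 > fa_threshold)) {
    ch <- eigenvector_change(sp0$vectors[e, 1:3], spf$vectors[e, 1:3])
    s[e] <- ch$s; dth[e] <- ch$d_theta_abs; dph[e] <- ch$d_phi_abs
  }
  data.frame(FA_initial = fa0, FA_final = faf, dFA = faf - fa0,
             s = s, d_theta_abs = dth, d_phi_abs = dph)
}
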