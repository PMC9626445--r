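# Diffusion / preferential-direction tensor machinery: anisotropy indices,
# construction of the preferential-direction tensor, deformation-driven
# reorientation, Lagrangian pullbacks, and eigenvector-change metrics.
#
# Cell tensor fields are stored as ne x 6 matrices of the unique components in
# the fixed order xx, xy, xz, yy, yz, zz.

.TENSOR_COMP <- c("xx", "xy", "xz", "yy", "yz", "zz")

#' Pack / unpack symmetric 3x3 tensors
#'
#' `sym_to_vec` stores a symmetric tensor as its 6 unique components in the
#' order xx, xy, xz, yy, yz, zz; `vec_to_sym` is the inverse.
#'
#' @param S Symmetric 3x3 matrix.
#' @param v Numeric vector of length 6.
#' @return A length-6 vector, respectively a 3x3 symmetric matrix.
#' @export
sym_to_vec <- function(S) c(S[1, 1], S[1, 2], S[1, 3], S[2, 2], S[2, 3], S[3, 3])

#' @rdname sym_to_vec
#' @export
vec_to_sym <- function(v) {
  stopifnot(length(v) == 6L)
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

#' Linear, planar and spherical anisotropy indices
#'
#' For descending eigenvalues of a diffusion tensor,
#' \eqn{a_l = (\lambda_1-\lambda_2)/\sum\lambda},
#' \eqn{a_p = 2(\lambda_2-\lambda_3)/\sum\lambda},
#' \eqn{a_s = 3\lambda_3/\sum\lambda}; the three indices sum to one exactly.
#'
#' @param lambda1,lambda2,lambda3 Eigenvalues, `lambda1 >= lambda2 >=
#'   lambda3 > 0` (ties allowed).
#' @return Named list with `a_l`, `a_p`, `a_s`.
#' @export
anisotropy_indices <- function(lambda1, lambda2, lambda3) {
  if (any(lambda3 <= 0)) stop("eigenvalues must be positive")
  if (any(lambda1 < lambda2) || any(lambda2 < lambda3))
    stop("eigenvalues must be ordered descending")
  s <- lambda1 + lambda2 + lambda3
  list(a_l = (lambda1 - lambda2) / s,
       a_p = 2 * (lambda2 - lambda3) / s,
       a_s = 3 * lambda3 / s)
}

#' Anisotropy enhancement weights
#'
#' The preferential-direction tensor rescales the two leading eigenvalues by
#' `a1(r) = r a_l + r a_p + a_s` and `a2(r) = a_l + r a_p + a_s`; `r = 1`
#' gives `a1 = a2 = 1` (no enhancement).
#'
#' @param lambda1,lambda2,lambda3 Descending positive eigenvalues.
#' @param r Anisotropy enhancement factor, `>= 1`.
#' @return Named list with `a1`, `a2`.
#' @export
anisotropy_weights <- function(lambda1, lambda2, lambda3, r) {
  stopifnot(all(r >= 1))
  ai <- anisotropy_indices(lambda1, lambda2, lambda3)
  list(a1 = r * ai$a_l + r * ai$a_p + ai$a_s,
       a2 = ai$a_l + r * ai$a_p + ai$a_s)
}

# Spectral decomposition with descending eigenvalues (stable tie-break:
# eigen() returns descending order; eigenvectors orthonormal).
.spectral3 <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  list(lambda = e$values, vectors = e$vectors)
}

#' Build the preferential-direction tensor from a diffusion tensor
#'
#' Rescales the leading eigenvalues of `D0` by the anisotropy weights
#' `a1(r)`, `a2(r)` and normalizes the result so its trace equals 3
#' (mean value 1), yielding the dimensionless tensor steering the anisotropic
#' permeability.
#'
#' @param D0 Symmetric positive-definite 3x3 diffusion tensor, or a length-6
#'   component vector (xx, xy, xz, yy, yz, zz).
#' @param r Anisotropy enhancement factor, `>= 1`.
#' @return Symmetric 3x3 tensor `A0` with `tr(A0) = 3`.
#' @export
build_preferential_tensor <- function(D0, r = 1) {
  if (!is.matrix(D0)) D0 <- vec_to_sym(D0)
  sp <- .spectral3(D0)
  lam <- sp$lambda
  if (lam[3] <= 0) stop("D0 must be positive-definite")
  w <- anisotropy_weights(lam[1], lam[2], lam[3], r)
  V <- sp$vectors
  Ahat <- w$a1 * lam[1] * tcrossprod(V[, 1]) +
    w$a2 * lam[2] * tcrossprod(V[, 2]) +
    lam[3] * tcrossprod(V[, 3])
  3 * Ahat / sum(diag(Ahat))
}

#' Reorient a tensor by a deformation, preserving eigenvalue magnitudes
#'
#' Pushes each eigenvector through `F_s` and renormalizes it, so only the
#' fibre directions change:
#' \eqn{T = \sum_i w_i \lambda_i (F e_i \otimes F e_i)/|F e_i|^2}.
#' For a diffusion tensor (`weights = c(1,1,1)`, no trace target) the trace is
#' preserved unconditionally. For a preferential-direction tensor pass the
#' anisotropy weights and `normalize_trace_to = 3`.
#'
#' @param T0 Symmetric positive-definite 3x3 tensor (or length-6 components).
#' @param F_s Deformation gradient (3x3, `det > 0`).
#' @param normalize_trace_to Optional trace target applied after reorientation
#'   (used for the preferential-direction tensor); `NULL` for none.
#' @param weights Length-3 eigenvalue weights `(a1, a2, 1)`; defaults to no
#'   reweighting.
#' @return Reoriented symmetric 3x3 tensor.
#' @export
reorient_tensor <- function(T0, F_s, normalize_trace_to = NULL,
                            weights = c(1, 1, 1)) {
  if (!is.matrix(T0)) T0 <- vec_to_sym(T0)
  .check_mat3(F_s, "F_s")
  if (det(F_s) <= 0) stop("F_s must have positive determinant")
  sp <- .spectral3(T0)
  out <- matrix(0, 3, 3)
  for (i in 1:3) {
    fi <- F_s %*% sp$vectors[, i]
    out <- out + weights[i] * sp$lambda[i] * tcrossprod(fi) / sum(fi^2)
  }
  if (!is.null(normalize_trace_to))
    out <- normalize_trace_to * out / sum(diag(out))
  out
}

#' Lagrangian pullback of a spatial tensor
#'
#' \eqn{T^* = J F^{-1} T F^{-T}}: carries a spatial second-order tensor (e.g.
#' the reoriented diffusion tensor) to the reference configuration. Symmetry
#' and positive-definiteness are preserved (congruence transform).
#'
#' @param T Symmetric 3x3 tensor in the current configuration.
#' @param F_s Deformation gradient (`det > 0`).
#' @param J_s Volume ratio `det F_s` (passed separately so callers can reuse
#'   a cached value).
#' @return Pulled-back 3x3 tensor.
#' @export
pullback_tensor <- function(T, F_s, J_s = det(F_s)) {
  if (!is.matrix(T)) T <- vec_to_sym(T)
  .check_mat3(F_s, "F_s")
  if (det(F_s) <= 0) stop("F_s must have positive determinant")
  Fi <- solve(F_s)
  J_s * Fi %*% T %*% t(Fi)
}

#' Fractional anisotropy
#'
#' \deqn{FA = \sqrt{\frac{1}{2}\frac{(\lambda_1-\lambda_2)^2 +
#'  (\lambda_2-\lambda_3)^2 + (\lambda_1-\lambda_3)^2}
#'  {\lambda_1^2+\lambda_2^2+\lambda_3^2}} \in [0,1],}
#' zero for an isotropic tensor, approaching one for a single totally
#' preferred direction. Vectorized over eigenvalue triples.
#'
#' @param lambda1,lambda2,lambda3 Non-negative eigenvalues, not all zero.
#' @return Fractional anisotropy in `[0, 1]`.
#' @export
fractional_anisotropy <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 < 0 | lambda2 < 0 | lambda3 < 0))
    stop("eigenvalues must be non-negative")
  ss <- lambda1^2 + lambda2^2 + lambda3^2
  if (any(ss == 0)) stop("eigenvalues must not all be zero")
  sqrt(0.5 * ((lambda1 - lambda2)^2 + (lambda2 - lambda3)^2 +
                (lambda1 - lambda3)^2) / ss)
}

# Fold an angular difference onto [0, pi/2], identifying angles that differ
# by multiples of pi (axis, not orientation).
.fold_angle <- function(d) {
  d <- abs(d) %% pi
  ifelse(d > pi / 2, pi - d, d)
}

#' Change of the leading diffusion eigenvector
#'
#' Quantifies how much the preferential diffusion axis rotated between an
#' initial and a final state: `s = 1 - |e0 . ef|` (0 for an unchanged axis,
#' including a flipped sign; 1 for perpendicular axes), plus the absolute
#' changes of the azimuthal and polar spherical angles, with angles differing
#' by multiples of pi identified and variations folded into `[0, pi/2]`.
#'
#' @param e1_initial,e1_final Unit 3-vectors (leading eigenvectors).
#' @return Named list with `s`, `d_theta_abs`, `d_phi_abs`.
#' @export
eigenvector_change <- function(e1_initial, e1_final) {
  n0 <- sqrt(sum(e1_initial^2)); nf <- sqrt(sum(e1_final^2))
  if (n0 == 0 || nf == 0) stop("eigenvectors must be non-zero")
  e0 <- e1_initial / n0; ef <- e1_final / nf
  s <- 1 - abs(sum(e0 * ef))
  s <- min(max(s, 0), 1)
  theta0 <- atan2(e0[2], e0[1]); thetaf <- atan2(ef[2], ef[1])
  phi0 <- acos(min(max(e0[3], -1), 1)); phif <- acos(min(max(ef[3], -1), 1))
  list(s = s,
       d_theta_abs = .fold_angle(thetaf - theta0),
       d_phi_abs = .fold_angle(phif - phi0))
}

#' Sample a voxel tensor grid onto mesh cells
#'
#' Assigns to each tetrahedron the tensor of the voxel containing its
#' barycentre. Voxel ownership uses half-open intervals `[x_i, x_{i+1})` along
#' each axis, so barycentres on voxel faces are assigned deterministically.
#'
#' @param grid A voxel tensor grid as returned by [make_synthetic_dti()]:
#'   list with `origin` (corner of the first voxel, mm), `spacing` (mm),
#'   `dim` (3 integers) and `tensors` (nvox x 6 matrix, voxel index varying
#'   fastest in x, components xx, xy, xz, yy, yz, zz).
#' @param mesh A `gm_mesh` object.
#' @return A cell tensor field: ne x 6 matrix with attribute
#'   `provenance = "initial"`.
#' @export
voxel_to_cell <- function(grid, mesh) {
  stopifnot(inherits(mesh, "gm_mesh"))
  bary <- cell_barycentres(mesh)
  ijk <- sweep(sweep(bary, 2, grid$origin), 2, grid$spacing, "/")
  ijk <- floor(ijk)
  bad <- which(ijk[, 1] < 0 | ijk[, 1] >= grid$dim[1] |
                 ijk[, 2] < 0 | ijk[, 2] >= grid$dim[2] |
                 ijk[, 3] < 0 | ijk[, 3] >= grid$dim[3])
  if (length(bad))
    stop("cell barycentre outside the voxel grid for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  idx <- 1 + ijk[, 1] + grid$dim[1] * (ijk[, 2] + grid$dim[2] * ijk[, 3])
  out <- grid$tensors[idx, , drop = FALSE]
  colnames(out) <- .TENSOR_COMP
  attr(out, "provenance") <- "initial"
  out
}

# Spectral data of a cell tensor field: eigenvalues (ne x 3, descending) and
# eigenvectors (ne x 9, columns of V stored row-wise per cell).
.cell_spectral <- function(field) {
  ne <- nrow(field)
  lam <- matrix(0, ne, 3)
  vec <- matrix(0, ne, 9)
  for (e in seq_len(ne)) {
    sp <- .spectral3(vec_to_sym(field[e, ]))
    lam[e, ] <- sp$lambda
    vec[e, ] <- as.vector(sp$vectors)
  }
  list(lambda = lam, vectors = vec)
}
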