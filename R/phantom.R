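# Synthetic "brain phantom" inputs: ball meshes, smooth tumour indicators and
# voxel DTI grids with controllable anisotropy. These stand in for the
# patient MRI/DTI geometry so the whole pipeline runs on generated data.

#' Phantom specification
#'
#' @param brain_radius Radius of the ball-shaped "skull-bounded brain" (mm).
#'   40 mm keeps the outer boundary far from the default tumour.
#' @param h Target mesh spacing (mm).
#' @param refine Radial refinement factor near the tumour centre (1 = uniform;
#'   2 halves the spacing near the centre). Refinement grades radially about
#'   the tumour centre, so it is intended for centred tumours.
#' @param tumour_centre Length-3 tumour centre (mm).
#' @param tumour_radius Initial tumour radius r0 (mm).
#' @param interface_width Width w of the smooth tanh interface (mm).
#' @param dti_mode One of `"isotropic"`, `"uniform_axis"`, `"radial"`.
#' @param eigenvalues Descending positive diffusion eigenvalues (mm^2/day).
#'   The default mean is the oxygen diffusivity 86.4 mm^2/day.
#' @param voxel_spacing DTI voxel spacing (mm).
#' @param seed Integer seed (the generators are deterministic; the seed is
#'   recorded for provenance and reserved for randomized variants).
#' @return An object of class `gm_phantom_spec`.
#' @export
phantom_spec <- function(brain_radius = 40, h = 5, refine = 1,
                         tumour_centre = c(0, 0, 0), tumour_radius = 7,
                         interface_width = 1,
                         dti_mode = c("isotropic", "uniform_axis", "radial"),
                         eigenvalues = c(86.4, 86.4, 86.4),
                         voxel_spacing = 2, seed = 1L) {
  dti_mode <- match.arg(dti_mode)
  stopifnot(brain_radius > 0, h > 0, refine >= 1,
            length(tumour_centre) == 3L, tumour_radius > 0,
            interface_width > 0,
            length(eigenvalues) == 3L, all(eigenvalues > 0),
            !is.unsorted(rev(eigenvalues)),
            voxel_spacing > 0)
  if (tumour_radius + interface_width >=
      brain_radius - sqrt(sum(tumour_centre^2)) - 2 * interface_width)
    stop("tumour (radius + interface width) too close to the brain boundary")
  structure(list(brain_radius = brain_radius, h = h, refine = refine,
                 tumour_centre = tumour_centre, tumour_radius = tumour_radius,
                 interface_width = interface_width, dti_mode = dti_mode,
                 eigenvalues = eigenvalues, voxel_spacing = voxel_spacing,
                 seed = as.integer(seed)),
            class = "gm_phantom_spec")
}

# Freudenthal (Kuhn) decomposition of the unit cube into 6 conforming tets,
# as vertex index offsets into the (i,j,k) lattice.
.kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- vector("list", 6)
  for (p in seq_len(6)) {
    v <- matrix(0, 4, 3)
    for (s in 1:3) {
      v[s + 1, ] <- v[s, ]
      v[s + 1, perms[p, s]] <- 1
    }
    out[[p]] <- v
  }
  out
}

#' Tetrahedral mesh of a ball
#'
#' Builds a structured Freudenthal tetrahedralization of the cube
#' `[-R, R]^3`, maps it onto the ball of radius R with the smooth
#' cube-to-sphere mapping (boundary nodes land exactly on the sphere),
#' improves interior element shapes by damped Laplacian smoothing with the
#' boundary pinned, and optionally applies a radial grading about the tumour
#' centre that refines the spacing there by the factor `spec$refine` (the
#' relative spacing profile is flat at `1/refine` across the tumour and rises
#' smoothly outside it).
#'
#' @param spec A [phantom_spec()] object.
#' @return A `gm_mesh` object.
#' @export
make_ball_mesh <- function(spec) {
  stopifnot(inherits(spec, "gm_phantom_spec"))
  R <- spec$brain_radius
  n <- max(4L, as.integer(round(2 * R / spec$h)))
  # lattice of nodes in [-1, 1]^3
  g1 <- seq(-1, 1, length.out = n + 1)
  idx <- function(i, j, k) 1L + i + (n + 1L) * (j + (n + 1L) * k)
  gi <- rep(0:n, times = (n + 1)^2)
  gj <- rep(rep(0:n, each = n + 1), times = n + 1)
  gk <- rep(0:n, each = (n + 1)^2)
  xi <- cbind(g1[gi + 1], g1[gj + 1], g1[gk + 1])
  # smooth cube-to-ball mapping (exact on the boundary, mild distortion)
  x <- xi[, 1]; y <- xi[, 2]; z <- xi[, 3]
  nodes <- cbind(x * sqrt(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3),
                 y * sqrt(1 - x^2 / 2 - z^2 / 2 + x^2 * z^2 / 3),
                 z * sqrt(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)) * R
  # tets from the Kuhn decomposition of each lattice cube
  kt <- .kuhn_tets()
  ci <- rep(0:(n - 1), times = n^2)
  cj <- rep(rep(0:(n - 1), each = n), times = n)
  ck <- rep(0:(n - 1), each = n^2)
  tets <- matrix(0L, 6 * n^3, 4)
  row <- 1L
  for (p in 1:6) {
    v <- kt[[p]]
    block <- cbind(idx(ci + v[1, 1], cj + v[1, 2], ck + v[1, 3]),
                   idx(ci + v[2, 1], cj + v[2, 2], ck + v[2, 3]),
                   idx(ci + v[3, 1], cj + v[3, 2], ck + v[3, 3]),
                   idx(ci + v[4, 1], cj + v[4, 2], ck + v[4, 3]))
    tets[row:(row + n^3 - 1L), ] <- block
    row <- row + n^3
  }
  mesh <- gm_mesh(nodes, tets)
  mesh <- .laplace_smooth(mesh, iters = 30L, damp = 0.5)
  if (spec$refine > 1) {
    # calibrate the internal grading contrast so the delivered median-edge
    # ratio between tumour and far field actually reaches 1/refine (the
    # cube-to-ball mapping compresses the far field and dilutes the nominal
    # contrast otherwise)
    r_ref <- spec$tumour_radius + 2 * spec$interface_width
    ctr <- spec$tumour_centre
    base <- mesh$nodes
    eff <- spec$refine
    best <- NULL
    for (it in 1:6) {
      cand <- .radial_grade(base, ctr, R, r_ref, eff)
      if (any(.signed_volumes(cand, mesh$tets) <= 0)) break
      best <- cand
      med <- .edge_ratio(cand, mesh$tets, ctr, r_ref, R)
      if (med <= 1 / spec$refine) break
      eff <- min(eff * med * spec$refine, 6 * spec$refine)
    }
    if (!is.null(best)) mesh$nodes <- best
  }
  mesh
}

# median max-edge inside the refined zone over the far-field median
.edge_ratio <- function(nodes, tets, centre, r_ref, R) {
  m <- list(nodes = nodes, tets = tets)
  el <- .cell_edge_lengths(m)
  maxe <- apply(el, 1, max)
  bar <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
            nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  d <- sqrt(rowSums(sweep(bar, 2, centre)^2))
  median(maxe[d < r_ref]) / median(maxe[d > 0.5 * R])
}

# Damped Laplacian smoothing with the boundary pinned; any iteration that
# would invert an element is skipped and smoothing stops.
.laplace_smooth <- function(mesh, iters = 30L, damp = 0.5) {
  bn <- mesh$boundary_nodes
  ep <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)],
              mesh$tets[, c(1, 4)], mesh$tets[, c(2, 3)],
              mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  ep <- rbind(ep, ep[, 2:1])
  cnt <- tabulate(ep[, 1], nbins = nrow(mesh$nodes))
  for (it in seq_len(iters)) {
    avg <- rowsum(mesh$nodes[ep[, 2], , drop = FALSE], ep[, 1]) / cnt
    dimnames(avg) <- NULL
    avg[bn, ] <- mesh$nodes[bn, ]
    cand <- mesh$nodes + damp * (avg - mesh$nodes)
    if (any(.signed_volumes(cand, mesh$tets) <= 0)) break
    mesh$nodes <- cand
  }
  mesh
}

# Radial grading about `centre`: along each ray from the centre to the outer
# sphere the normalized radius t in [0, 1] is remapped by T(t) with
# T'(t) = a for t <= t0 (inside the tumour), rising by a smoothstep to b on
# [t0, t1], with a/b = 1/refine and the integral of T' equal to 1 so the
# boundary stays fixed.
.radial_grade <- function(nodes, centre, R, r_refined, refine) {
  d <- sweep(nodes, 2, centre)
  rho <- sqrt(rowSums(d^2))
  rmax <- rep(R, length(rho))
  pos <- rho > 0
  u <- d[pos, , drop = FALSE] / rho[pos]
  b0 <- as.vector(u %*% centre)
  rmax[pos] <- sqrt(pmax(b0^2 - (sum(centre^2) - R^2), 0)) - b0
  t_ <- ifelse(rmax > 0, pmin(rho / rmax, 1), 0)
  # choose t0 so that the *image* of the plateau covers the tumour radius:
  # a(t0) * t0 = r_refined / rmax, solved by fixed-point iteration
  rho0 <- pmin(pmax(r_refined / rmax, 0.02), 0.45)
  t0 <- rho0
  for (i in 1:30) {
    t1 <- pmin(2 * t0, 0.9)
    I1 <- (t1 - t0) / 2 + (1 - t1)
    b <- 1 / (I1 + (1 - I1) / refine)
    a <- b / refine
    t0 <- pmin(rho0 / a, 0.45)
  }
  t1 <- pmin(2 * t0, 0.9)
  I1 <- (t1 - t0) / 2 + (1 - t1)
  b <- 1 / (I1 + (1 - I1) / refine)
  a <- b / refine
  ss <- function(x) ifelse(x <= 0, 0, ifelse(x >= 1, 1, 3 * x^2 - 2 * x^3))
  ssint <- function(x) ifelse(x <= 0, 0, ifelse(x >= 1, x - 0.5, x^3 - x^4 / 2))
  # T(t) = a t + (b - a) (t1 - t0) * ssint((t - t0)/(t1 - t0))
  Tt <- a * t_ + (b - a) * (t1 - t0) * ssint((t_ - t0) / (t1 - t0))
  fac <- ifelse(rho > 0, Tt * rmax / rho, 1)
  sweep(d * fac, 2, centre, "+")
}

#' Smooth tumour indicator field
#'
#' \eqn{\chi(X) = \frac{1}{2}(1 - \tanh((|X - c| - r_0)/w))}: about 1 at the
#' tumour centre, 0.5 at radius r0, decaying to 0 over the interface width w.
#' The tumour region is its upper level set `{chi > 0.1}`, whose analytic
#' radius is `r0 + w * atanh(0.8)`.
#'
#' @param mesh A `gm_mesh` object.
#' @param centre Tumour centre (mm).
#' @param r0 Tumour radius (mm).
#' @param w Interface width (mm).
#' @return A nodal field (class `gm_indicator`) with attributes `centre`,
#'   `r0`, `w`, `threshold = 0.1`.
#' @export
make_indicator <- function(mesh, centre = c(0, 0, 0), r0 = 7, w = 1) {
  stopifnot(inherits(mesh, "gm_mesh"), w > 0, r0 > 0)
  d <- sqrt(rowSums(sweep(mesh$nodes, 2, centre)^2))
  chi <- 0.5 * (1 - tanh((d - r0) / w))
  structure(chi, class = "gm_indicator",
            centre = centre, r0 = r0, w = w, threshold = 0.1)
}

#' Synthetic voxel DTI grid
#'
#' Builds a voxel grid of symmetric positive-definite diffusion tensors
#' covering the phantom ball:
#' * `isotropic`: mean diffusivity times the identity in every voxel;
#' * `uniform_axis`: a fixed eigenframe (axes of the grid) everywhere with the
#'   prescribed descending eigenvalues;
#' * `radial`: leading eigenvector along the radial direction from the domain
#'   centre, eigenvalues constant.
#'
#' @param spec A [phantom_spec()] object.
#' @return A voxel grid list with `origin`, `spacing`, `dim`, `tensors`
#'   (nvox x 6, components xx, xy, xz, yy, yz, zz, x varying fastest) and
#'   `mode`.
#' @export
make_synthetic_dti <- function(spec) {
  stopifnot(inherits(spec, "gm_phantom_spec"))
  s <- spec$voxel_spacing
  R <- spec$brain_radius
  half <- ceiling((R + s) / s)
  nvx <- 2L * half
  origin <- rep(-half * s, 3)
  dimv <- rep(nvx, 3L)
  centres_1d <- origin[1] + (seq_len(nvx) - 0.5) * s
  cx <- rep(centres_1d, times = nvx^2)
  cy <- rep(rep(centres_1d, each = nvx), times = nvx)
  cz <- rep(centres_1d, each = nvx^2)
  lam <- spec$eigenvalues
  nvox <- nvx^3
  tensors <- matrix(0, nvox, 6)
  if (spec$dti_mode == "isotropic") {
    lbar <- mean(lam)
    tensors[, c(1, 4, 6)] <- lbar
  } else if (spec$dti_mode == "uniform_axis") {
    tensors[, 1] <- lam[1]; tensors[, 4] <- lam[2]; tensors[, 6] <- lam[3]
  } else { # radial
    r <- sqrt(cx^2 + cy^2 + cz^2)
    ex <- ifelse(r > 0, cx / r, 1)
    ey <- ifelse(r > 0, cy / r, 0)
    ez <- ifelse(r > 0, cz / r, 0)
    # D = lam3 I + (lam1 - lam3) e1 e1' + (lam2 - lam3) e2 e2', with e2 any
    # unit vector orthogonal to e1 (deterministic completion).
    e2 <- .orthonormal_completion(cbind(ex, ey, ez))
    l13 <- lam[1] - lam[3]; l23 <- lam[2] - lam[3]
    tensors[, 1] <- lam[3] + l13 * ex^2 + l23 * e2[, 1]^2
    tensors[, 2] <- l13 * ex * ey + l23 * e2[, 1] * e2[, 2]
    tensors[, 3] <- l13 * ex * ez + l23 * e2[, 1] * e2[, 3]
    tensors[, 4] <- lam[3] + l13 * ey^2 + l23 * e2[, 2]^2
    tensors[, 5] <- l13 * ey * ez + l23 * e2[, 2] * e2[, 3]
    tensors[, 6] <- lam[3] + l13 * ez^2 + l23 * e2[, 3]^2
  }
  colnames(tensors) <- .TENSOR_COMP
  list(origin = origin, spacing = rep(s, 3), dim = dimv,
       tensors = tensors, mode = spec$dti_mode)
}

# Deterministic unit vector orthogonal to each row of E (n x 3): cross with
# the global axis least aligned with the vector.
.orthonormal_completion <- function(E) {
  n <- nrow(E)
  aidx <- max.col(-abs(E), ties.method = "first")
  A <- matrix(0, n, 3)
  A[cbind(seq_len(n), aidx)] <- 1
  cr <- cbind(E[, 2] * A[, 3] - E[, 3] * A[, 2],
              E[, 3] * A[, 1] - E[, 1] * A[, 3],
              E[, 1] * A[, 2] - E[, 2] * A[, 1])
  cr / sqrt(rowSums(cr^2))
}

#' Generate the complete phantom input set
#'
#' Convenience wrapper producing the mesh, the tumour indicator, the voxel
#' DTI grid and its cell-sampled tensor field in one call.
#'
#' @param spec A [phantom_spec()] object.
#' @return List with `mesh`, `chi`, `dti_grid`, `D0` (cell tensor field) and
#'   the `spec` echo.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  mesh <- make_ball_mesh(spec)
  chi <- make_indicator(mesh, spec$tumour_centre, spec$tumour_radius,
                        spec$interface_width)
  grid <- make_synthetic_dti(spec)
  D0 <- voxel_to_cell(grid, mesh)
  list(mesh = mesh, chi = chi, dti_grid = grid, D0 = D0, spec = spec)
}
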