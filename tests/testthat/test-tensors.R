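test_that("anisotropy indices: canonical triples and exact closure", {
  ai <- anisotropy_indices(1, 1, 1)
  expect_equal(unlist(ai), c(a_l = 0, a_p = 0, a_s = 1))
  ai <- anisotropy_indices(2, 1, 1)
  expect_equal(unlist(ai), c(a_l = 0.25, a_p = 0, a_s = 0.75))
  set.seed(10)
  for (i in 1:100) {
    lam <- sort(rexp(3) + 0.01, decreasing = TRUE)
    ai <- anisotropy_indices(lam[1], lam[2], lam[3])
    expect_lt(abs(ai$a_l + ai$a_p + ai$a_s - 1), 1e-12)
    expect_true(all(unlist(ai) >= 0) && all(unlist(ai) <= 1))
  }
  expect_error(anisotropy_indices(1, 2, 0.5), "descending")
  expect_error(anisotropy_indices(1, 0.5, 0), "positive")
})

test_that("preferential-direction tensor: r = 1, isotropy, trace normalization", {
  set.seed(11)
  D0 <- random_spd()
  # r = 1: no anisotropy increase, A0 = 3 D0 / tr(D0)
  expect_equal(build_preferential_tensor(D0, r = 1), 3 * D0 / sum(diag(D0)),
               tolerance = 1e-12)
  # isotropic D0 -> identity for every r
  for (r in c(1, 5, 10))
    expect_equal(build_preferential_tensor(2.5 * diag(3), r), diag(3))
  # unit mean eigenvalue after normalization, any D0 and r
  for (r in c(1, 5, 10)) {
    A0 <- build_preferential_tensor(random_spd(), r)
    expect_equal(sum(diag(A0)), 3, tolerance = 1e-12)
  }
  expect_error(build_preferential_tensor(diag(c(1, 1, -1)), 2),
               "positive-definite")
})

test_that("reorientation moves fibre directions only", {
  set.seed(12)
  D0 <- random_spd()
  expect_equal(reorient_tensor(D0, diag(3)), D0, tolerance = 1e-12)
  # rigid rotation: eigenvalues unchanged, eigenvectors rotated
  Q <- random_rotation()
  D <- reorient_tensor(D0, Q)
  expect_equal(D, Q %*% D0 %*% t(Q), tolerance = 1e-10)
  expect_equal(eigen(D, symmetric = TRUE)$values,
               eigen(D0, symmetric = TRUE)$values, tolerance = 1e-10)
  # trace preservation under 50 random deformations
  for (i in 1:50) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
    if (det(F) <= 0) next
    D <- reorient_tensor(D0, F)
    expect_equal(sum(diag(D)), sum(diag(D0)), tolerance = 1e-10)
  }
  # trace target for the preferential-direction variant
  A <- reorient_tensor(D0, diag(3) + 0.2 * matrix(rnorm(9), 3, 3),
                       normalize_trace_to = 3, weights = c(2, 1.5, 1))
  expect_equal(sum(diag(A)), 3, tolerance = 1e-12)
  expect_error(reorient_tensor(D0, matrix(0, 3, 3)), "determinant")
})

test_that("pullback: identity, eigenvector restoration, SPD preservation", {
  set.seed(13)
  D0 <- random_spd()
  expect_equal(pullback_tensor(D0, diag(3)), D0)
  # the pullback of the reoriented tensor has the eigenvectors of D0
  sp0 <- eigen(D0, symmetric = TRUE)
  for (i in 1:10) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
    if (det(F) <= 0) next
    Dstar <- pullback_tensor(reorient_tensor(D0, F), F)
    spd <- eigen(Dstar, symmetric = TRUE)
    # same eigenvectors up to sign and ordering: cross-products of the frames
    M <- abs(t(spd$vectors) %*% sp0$vectors)
    expect_equal(sort(apply(M, 1, max)), c(1, 1, 1), tolerance = 1e-8)
  }
  # congruence preserves positive-definiteness
  for (i in 1:50) {
    T0 <- random_spd(0.1)
    F <- diag(3) + 0.5 * matrix(rnorm(9), 3, 3)
    if (abs(det(F)) < 0.05) next
    F <- F * sign(det(F))
    ev <- eigen(pullback_tensor(T0, F), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), 0)
  }
})

test_that("fractional anisotropy: limits and direct value", {
  expect_equal(fractional_anisotropy(3, 3, 3), 0)
  expect_equal(fractional_anisotropy(1, 0, 0), 1)
  expect_equal(fractional_anisotropy(2, 1, 1), sqrt(1 / 6))
  expect_error(fractional_anisotropy(0, 0, 0), "zero")
  # always in [0, 1]; monotone in lambda1/lambda3 with lambda2 the
  # geometric mean
  set.seed(14)
  ratios <- c(1, 2, 5, 10, 50)
  fa <- sapply(ratios, function(r)
    fractional_anisotropy(r, sqrt(r), 1))
  expect_true(all(fa >= 0 & fa <= 1))
  expect_true(all(diff(fa) > 0))
})

test_that("leading-eigenvector change treats directions as axes", {
  e <- c(1, 0, 0)
  ch <- eigenvector_change(e, e)
  expect_equal(unlist(ch), c(s = 0, d_theta_abs = 0, d_phi_abs = 0))
  ch <- eigenvector_change(e, -e)          # flipped axis: no change
  expect_equal(ch$s, 0)
  expect_equal(ch$d_theta_abs, 0)
  expect_equal(eigenvector_change(e, c(0, 1, 0))$s, 1)
  # folding into [0, pi/2]
  set.seed(15)
  for (i in 1:20) {
    v1 <- rnorm(3); v2 <- rnorm(3)
    ch <- eigenvector_change(v1, v2)
    expect_true(ch$s >= 0 && ch$s <= 1)
    expect_true(ch$d_theta_abs >= 0 && ch$d_theta_abs <= pi / 2 + 1e-12)
    expect_true(ch$d_phi_abs >= 0 && ch$d_phi_abs <= pi / 2 + 1e-12)
    # axis identification: flipping either vector changes nothing
    ch2 <- eigenvector_change(-v1, v2)
    expect_equal(ch$s, ch2$s, tolerance = 1e-12)
  }
  expect_error(eigenvector_change(c(0, 0, 0), e), "non-zero")
})

test_that("voxel sampling assigns the tensor of the owning voxel", {
  ph <- small_phantom()
  # spatially constant grid -> constant field
  grid <- ph$dti_grid
  expect_true(all(apply(ph$D0, 2, function(x) length(unique(x))) == 1))
  expect_equal(vec_to_sym(ph$D0[1, ]), 86.4 * diag(3))

  # two-valued grid split by the plane x = 0: cells partition by barycentre
  grid2 <- grid
  nv <- grid2$dim[1]
  cx <- grid2$origin[1] + (rep(seq_len(nv), times = nv^2) - 0.5) * grid2$spacing[1]
  grid2$tensors[, 1] <- ifelse(cx < 0, 1, 2)
  f2 <- voxel_to_cell(grid2, ph$mesh)
  bar <- cell_barycentres(ph$mesh)
  vox_x <- floor((bar[, 1] - grid2$origin[1]) / grid2$spacing[1])
  cx_cell <- grid2$origin[1] + (vox_x + 0.5) * grid2$spacing[1]
  expect_equal(f2[, 1], unname(ifelse(cx_cell < 0, 1, 2)))

  # refinement consistency: 1 mm vs 2 mm sampling of a smooth field agrees
  # within the field's modulus of continuity over one voxel diagonal
  smooth_grid <- function(s) {
    spec <- phantom_spec(brain_radius = 20, h = 7, tumour_radius = 5,
                         voxel_spacing = s)
    g <- make_synthetic_dti(spec)
    nv <- g$dim[1]
    ax <- g$origin[1] + (seq_len(nv) - 0.5) * g$spacing[1]
    cx <- rep(ax, times = nv^2)
    g$tensors[, 1] <- 1 + 0.01 * cx          # Lipschitz constant 0.01/mm
    g
  }
  f1 <- voxel_to_cell(smooth_grid(1), ph$mesh)
  f2 <- voxel_to_cell(smooth_grid(2), ph$mesh)
  expect_lt(max(abs(f1[, 1] - f2[, 1])), 0.01 * sqrt(3) * 2)

  # barycentre outside the grid is an error naming the cell
  gridsmall <- grid
  gridsmall$dim <- c(2L, 2L, 2L)
  gridsmall$tensors <- grid$tensors[1:8, ]
  expect_error(voxel_to_cell(gridsmall, ph$mesh), "cell")
})
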