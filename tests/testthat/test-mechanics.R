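test_that("kinematics split reproduces the defining identities", {
  # undeformed, no growth
  k <- compute_kinematics(matrix(0, 3, 3), g = 1)
  expect_equal(k$F_e, diag(3))
  expect_equal(k$J_e, 1)
  expect_equal(k$Cbar_e, diag(3))

  # pure growth F_s = 2I, g = 2: no elastic strain
  k <- compute_kinematics(diag(3), g = 2)   # grad_u = I -> F_s = 2I
  expect_equal(k$F_e, diag(3))
  expect_equal(k$J_s, 8)
  expect_equal(k$J_g, 8)
  expect_equal(k$J_e, 1)

  # uniaxial stretch without growth
  k <- compute_kinematics(diag(c(0.2, 0, 0)), g = 1)
  expect_equal(k$J_e, 1.2)
  expect_equal(k$Cbar_e, 1.2^(-2 / 3) * diag(c(1.44, 1, 1)))
  expect_equal(det(k$Cbar_e), 1, tolerance = 1e-12)

  # multiplicative consistency F_e F_g = F_s, J_e = J_s / g^3 for random states
  set.seed(1)
  for (i in 1:20) {
    H <- matrix(rnorm(9, sd = 0.1), 3, 3)
    g <- runif(1, 1, 1.5)
    k <- compute_kinematics(H, g)
    expect_equal(k$F_e %*% k$F_g, k$F_s, tolerance = 1e-14)
    expect_equal(k$J_e, det(k$F_s) / g^3, tolerance = 1e-12)
  }

  # inverted configuration is rejected
  expect_error(compute_kinematics(-2 * diag(3), g = 1), "inverted")
  expect_error(compute_kinematics(matrix(0, 3, 3), g = 0.5), ">= 1")
})

test_that("strain energy densities match their closed forms", {
  expect_equal(isochoric_energy(diag(3), 1.5e-3, 3e-3), 0)

  # isotropy: invariance under conjugation by rotations
  set.seed(2)
  F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
  Cbar <- det(crossprod(F))^(-1 / 3) * crossprod(F)
  w0 <- isochoric_energy(Cbar, 1.5e-3, 3e-3)
  for (i in 1:5) {
    Q <- random_rotation()
    expect_equal(isochoric_energy(Q %*% Cbar %*% t(Q), 1.5e-3, 3e-3), w0,
                 tolerance = 1e-12)
  }

  # simple shear gamma = 0.5: invariants from the eigenvalue oracle
  Fs <- diag(3); Fs[1, 2] <- 0.5
  Cb <- crossprod(Fs)                      # det = 1 already
  lam <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
  I1 <- sum(lam); I2 <- lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]
  mu1 <- 1.53e-3; mu2 <- 2.97e-3
  expect_equal(isochoric_energy(Cb, mu1, mu2),
               0.5 * mu1 * (I1 - 3) + 0.5 * mu2 * (I2 - 3))
  expect_equal(isochoric_energy(Cb, mu1, mu2), 0.125 * (mu1 + mu2),
               tolerance = 1e-12)

  expect_error(isochoric_energy(matrix(rnorm(9), 3, 3), mu1, mu2))

  # volumetric part: zero at J = 1, even in ln J, kappa/2 at J = e
  expect_equal(volumetric_energy(1, 1.4e-3), 0)
  for (J in c(0.5, 0.9, 2, 5))
    expect_equal(volumetric_energy(J, 1.4e-3), volumetric_energy(1 / J, 1.4e-3))
  expect_equal(volumetric_energy(exp(1), 1.4e-3), 1.4e-3 / 2)
  expect_error(volumetric_energy(-1, 1.4e-3), "positive")
})

test_that("Cauchy stress: natural state, dilation closed form, structure", {
  mp <- material_params()
  k <- compute_kinematics(matrix(0, 3, 3), g = 1)
  st <- cauchy_stress(k, mp, chi = 1)
  expect_lt(max(abs(st$T_s)), 1e-12)
  expect_lt(max(abs(st$P_s)), 1e-12)

  # pure dilation F_e = lambda I: deviatoric part vanishes,
  # T = kappa ln(lambda^3)/lambda^3 I
  lam <- 1.15
  k <- compute_kinematics((lam - 1) * diag(3), g = 1)
  for (chi in c(0, 0.4, 1)) {
    st <- cauchy_stress(k, mp, chi = chi)
    kap <- chi * mp$kappa_t + (1 - chi) * mp$kappa_h
    expect_lt(max(abs(st$T_s_dev)), 1e-15)
    expect_equal(st$T_s, kap * log(lam^3) / lam^3 * diag(3),
                 tolerance = 1e-12)
    expect_equal(st$Sigma, -kap * log(lam^3) / lam^3, tolerance = 1e-12)
  }

  # structure: symmetry, traceless deviator, dev + vol decomposition,
  # P = -J p F^-T + P_s
  set.seed(3)
  H <- matrix(rnorm(9, sd = 0.15), 3, 3)
  k <- compute_kinematics(H, g = 1.1)
  st <- cauchy_stress(k, mp, chi = 0.5, p = 2e-4)
  expect_equal(st$T_s, t(st$T_s), tolerance = 1e-15)
  expect_lt(abs(sum(diag(st$T_s_dev))), 1e-15)
  expect_equal(st$T_s, st$T_s_dev + st$T_s_vol)
  expect_equal(st$P, -k$J_s * 2e-4 * t(solve(k$F_s)) + st$P_s)
})

test_that("stress agrees with the finite-difference energy oracle", {
  mp <- material_params()
  set.seed(4)
  for (i in 1:20) {
    H <- matrix(rnorm(9, sd = 0.1), 3, 3)
    k <- compute_kinematics(H, g = 1)
    for (chi in c(0, 1)) {
      mu1 <- if (chi == 1) mp$mu1_t else mp$mu1_h
      mu2 <- if (chi == 1) mp$mu2_t else mp$mu2_h
      kap <- if (chi == 1) mp$kappa_t else mp$kappa_h
      T_fd <- fd_cauchy_stress(k$F_e, mu1, mu2, kap)
      T_cl <- cauchy_stress(k, mp, chi = chi)$T_s
      expect_lt(max(abs(T_cl - T_fd)) / max(abs(T_fd)), 1e-5)
    }
  }
})

test_that("stress is frame-indifferent", {
  mp <- material_params()
  set.seed(5)
  H <- matrix(rnorm(9, sd = 0.2), 3, 3)
  k <- compute_kinematics(H, g = 1)
  T0 <- cauchy_stress(k, mp, chi = 1)$T_s
  for (i in 1:5) {
    Q <- random_rotation()
    kq <- compute_kinematics(Q %*% k$F_s - diag(3), g = 1)
    Tq <- cauchy_stress(kq, mp, chi = 1)$T_s
    expect_equal(Tq, Q %*% T0 %*% t(Q), tolerance = 1e-10)
  }
})

test_that("small-strain deviatoric stress tends to 2(mu1+mu2) dev(sym(H))", {
  mp <- material_params()
  set.seed(6)
  H <- matrix(rnorm(9), 3, 3)
  mu <- mp$mu1_t + mp$mu2_t
  devsym <- function(A) {
    S <- (A + t(A)) / 2
    S - sum(diag(S)) / 3 * diag(3)
  }
  target <- 2 * mu * devsym(H)
  err <- function(eps) {
    k <- compute_kinematics(eps * H, g = 1)
    max(abs(cauchy_stress(k, mp, chi = 1)$T_s_dev / eps - target))
  }
  # Richardson: the error should shrink linearly in eps
  e1 <- err(1e-3); e2 <- err(5e-4)
  expect_lt(e2 / e1, 0.6)
  expect_lt(e2, 5e-3 * max(abs(target)))
})

test_that("compression measure and Holmes-Mow permeability", {
  expect_equal(compression_measure(-0.3 * diag(3)), 0.3)
  devT <- matrix(c(1, 2, 0, 2, -1, 1, 0, 1, 0), 3, 3)
  expect_equal(compression_measure(devT), 0)
  expect_error(compression_measure(matrix(rnorm(9), 3, 3)), "symmetric")

  pp <- permeability_params()
  expect_equal(holmes_mow_k(1, pp), 2.17e5)
  # vanishing at pore closure (a slow power law: alpha0 is small), error
  # beyond it; monotone decay towards the closure point
  eps <- 10^seq(-4, -16, by = -4)
  kseq <- holmes_mow_k(pp$phi_sn + eps, pp)
  expect_true(all(diff(kseq) < 0))
  expect_lt(kseq[length(kseq)], 0.01 * pp$k0)
  expect_error(holmes_mow_k(0.25, pp), "compaction")
  # direct scalar formula evaluation at J_e = 1.1
  ref <- 2.17e5 * ((1.1 - 0.3) / 0.7)^0.0848 * exp(4.638 * (1.1^2 - 1) / 2)
  expect_equal(holmes_mow_k(1.1, pp) / holmes_mow_k(1, pp), ref / 2.17e5,
               tolerance = 1e-14)
  # strictly increasing over a J_e sweep for the default parameters
  Je <- seq(0.35, 2, by = 0.01)
  expect_true(all(diff(holmes_mow_k(Je, pp)) > 0))
})
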