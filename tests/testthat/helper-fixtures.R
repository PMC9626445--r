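# Shared fixtures, built once per test run.

# random rotation matrix (Gram-Schmidt on a random 3x3)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random symmetric positive-definite 3x3
random_spd <- function(scale = 1) {
  A <- matrix(rnorm(9), 3, 3)
  crossprod(A) + scale * diag(3)
}

# energy-based Cauchy stress oracle: numerical differentiation of the total
# strain energy density W(C_e) (S = 2 dW/dC_e, T = F_e S F_e^T / J_e),
# independent of the closed-form stress path
fd_cauchy_stress <- function(F_e, mu1, mu2, kappa, h = 1e-6) {
  W_of_C <- function(C) {
    Je <- sqrt(det(C))
    Cbar <- det(C)^(-1 / 3) * C
    I1 <- sum(diag(Cbar))
    I2 <- 0.5 * (I1^2 - sum(diag(Cbar %*% Cbar)))
    0.5 * mu1 * (I1 - 3) + 0.5 * mu2 * (I2 - 3) + 0.5 * kappa * log(Je)^2
  }
  C <- crossprod(F_e)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[j, i] <- h
    dW <- (W_of_C(C + dC) - W_of_C(C - dC)) / (2 * h)
    # dW here is dW/dC_ij + dW/dC_ji for i != j; S_ij = 2 dW/dC_ij
    S[i, j] <- S[j, i] <- if (i == j) 2 * dW else dW
  }
  F_e %*% S %*% t(F_e) / det(F_e)
}

# small phantom + problem reused across solver-level tests
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(brain_radius = 20, h = 7, tumour_radius = 5,
                           interface_width = 1)
      cache <<- make_phantom(spec)
    }
    cache
  }
})

coarse_brain_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(brain_radius = 40, h = 10, refine = 2)
      cache <<- make_phantom(spec)
    }
    cache
  }
})
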