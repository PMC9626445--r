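# The coupled Lagrangian finite-element problem: mixture mass balance /
# Darcy, mixture momentum and nutrient transport, advanced by a semi-implicit
# Euler scheme with a monolithic Newton solve for (u, p, c) per step, followed
# by explicit pointwise updates of the growth stretch g and solid fraction.

#' Assemble the discrete problem structure
#'
#' Precomputes everything that is fixed over a simulation: shape-function
#' gradients, element volumes, the spectral decomposition of the initial
#' diffusion tensor per cell, the anisotropy weights, the degree-of-freedom
#' numbering and the sparse Jacobian skeleton.
#'
#' @param mesh A `gm_mesh` object.
#' @param chi Nodal tumour indicator ([make_indicator()]).
#' @param D0 Cell tensor field of initial diffusion tensors (ne x 6), e.g.
#'   from [voxel_to_cell()].
#' @param config A [simulation_config()] object.
#' @return An object of class `gm_problem`.
#' @export
prepare_problem <- function(mesh, chi, D0, config) {
  stopifnot(inherits(mesh, "gm_mesh"), inherits(config, "gm_config"),
            length(chi) == nrow(mesh$nodes),
            is.matrix(D0), nrow(D0) == nrow(mesh$tets), ncol(D0) == 6L)
  if (any(chi < 0 | chi > 1)) stop("chi must lie in [0, 1]")
  M <- nrow(mesh$nodes)
  ne <- nrow(mesh$tets)
  tets <- mesh$tets

  # P1 shape gradients (constant per tet) and volumes
  gradN <- matrix(0, ne, 12)
  for (e in seq_len(ne)) {
    a <- mesh$nodes[tets[e, 1], ]
    E <- cbind(mesh$nodes[tets[e, 2], ] - a,
               mesh$nodes[tets[e, 3], ] - a,
               mesh$nodes[tets[e, 4], ] - a)
    Einv <- solve(E)                       # rows = grad of barycentric 2..4
    gradN[e, 4:12] <- as.vector(t(Einv))   # node-major xyz
    gradN[e, 1:3] <- -colSums(Einv)
  }
  vol <- cell_volumes(mesh)

  chi_cell <- (chi[tets[, 1]] + chi[tets[, 2]] +
                 chi[tets[, 3]] + chi[tets[, 4]]) / 4
  sp <- .cell_spectral(D0)
  w <- anisotropy_weights(sp$lambda[, 1], sp$lambda[, 2], sp$lambda[, 3],
                          config$r)

  # dof numbering: u interleaved per node, then p block, then c block
  udof <- function(n, d) 3L * (n - 1L) + d
  dofmap <- cbind(udof(tets[, 1], 1), udof(tets[, 1], 2), udof(tets[, 1], 3),
                  udof(tets[, 2], 1), udof(tets[, 2], 2), udof(tets[, 2], 3),
                  udof(tets[, 3], 1), udof(tets[, 3], 2), udof(tets[, 3], 3),
                  udof(tets[, 4], 1), udof(tets[, 4], 2), udof(tets[, 4], 3),
                  3L * M + tets[, 1], 3L * M + tets[, 2],
                  3L * M + tets[, 3], 3L * M + tets[, 4],
                  4L * M + tets[, 1], 4L * M + tets[, 2],
                  4L * M + tets[, 3], 4L * M + tets[, 4])

  bn <- mesh$boundary_nodes
  is_free <- rep(TRUE, 5L * M)
  is_free[as.vector(vapply(1:3, function(d) udof(bn, d), integer(length(bn))))] <- FALSE
  if (config$bc_mode == "dirichlet") {
    is_free[3L * M + bn] <- FALSE
    is_free[4L * M + bn] <- FALSE
  }
  free <- which(is_free)
  free_index <- integer(5L * M)
  free_index[free] <- seq_along(free)

  # element-major triplet pattern matching the C++ jacobian layout
  i_loc <- rep(1:20, times = 20)
  j_loc <- rep(1:20, each = 20)
  ii_all <- as.vector(t(dofmap[, i_loc, drop = FALSE]))
  jj_all <- as.vector(t(dofmap[, j_loc, drop = FALSE]))
  keep <- is_free[ii_all] & is_free[jj_all]
  ii_f <- free_index[ii_all[keep]]
  jj_f <- free_index[jj_all[keep]]
  o <- order(jj_f, ii_f)
  io <- ii_f[o]; jo <- jj_f[o]
  new_entry <- c(TRUE, diff(io) != 0L | diff(jo) != 0L)
  uid <- cumsum(new_entry)
  map <- integer(length(o)); map[o] <- uid
  nf <- length(free)
  skel_i <- io[new_entry] - 1L
  skel_p <- c(0L, cumsum(tabulate(jo[new_entry], nbins = nf)))
  keep_idx <- which(keep)

  stab <- if (isTRUE(config$stabilize)) {
    h2 <- mesh_quality(mesh)$max_edge^2
    0.01 * config$permeability$k0 * h2 / mean(h2)
  } else rep(0, ne)

  hbar <- mean(vol)^(1 / 3)
  structure(list(mesh = mesh, chi = as.numeric(chi), chi_cell = chi_cell,
                 D0 = D0, gradN = gradN, vol = vol, M = M, ne = ne,
                 lambda = sp$lambda, evec = sp$vectors,
                 a1 = w$a1, a2 = w$a2, stab = stab,
                 is_free = is_free, free = free, keep_idx = keep_idx,
                 map = map, skel_i = skel_i, skel_p = skel_p, nf = nf,
                 nnz = length(skel_i),
                 min_edge = mesh_quality(mesh)$min_edge,
                 res_scale = c(u = config$material$kappa_t * hbar^2,
                               p = hbar^3, c = hbar^3),
                 indicator = chi),
            class = "gm_problem")
}

.par_vector <- function(config) {
  m <- config$material; g <- config$growth; k <- config$permeability
  c(mu1_t = m$mu1_t, mu2_t = m$mu2_t, kappa_t = m$kappa_t,
    mu1_h = m$mu1_h, mu2_h = m$mu2_h, kappa_h = m$kappa_h,
    k0 = k$k0, alpha0 = k$alpha0, m = k$m, phi_sn = k$phi_sn,
    zeta = g$zeta, S_n = g$S_n, dt = config$dt)
}

# Per-cell deformation gradient components and determinant (vectorized).
.cell_F <- function(prob, u) {
  tets <- prob$mesh$tets
  Fc <- matrix(0, prob$ne, 9)  # F11 F21 F31 F12 F22 F32 F13 F23 F33
  Fc[, c(1, 5, 9)] <- 1
  for (a in 1:4) {
    un <- u[tets[, a], , drop = FALSE]
    for (d in 1:3) {
      gN <- prob$gradN[, 3 * (a - 1) + d]
      Fc[, d * 3 - 2] <- Fc[, d * 3 - 2] + un[, 1] * gN
      Fc[, d * 3 - 1] <- Fc[, d * 3 - 1] + un[, 2] * gN
      Fc[, d * 3]     <- Fc[, d * 3]     + un[, 3] * gN
    }
  }
  J <- Fc[, 1] * (Fc[, 5] * Fc[, 9] - Fc[, 8] * Fc[, 6]) -
    Fc[, 4] * (Fc[, 2] * Fc[, 9] - Fc[, 8] * Fc[, 3]) +
    Fc[, 7] * (Fc[, 2] * Fc[, 6] - Fc[, 5] * Fc[, 3])
  list(F = Fc, J = J)
}

.cell_mean <- function(prob, nodal) {
  tets <- prob$mesh$tets
  (nodal[tets[, 1]] + nodal[tets[, 2]] + nodal[tets[, 3]] + nodal[tets[, 4]]) / 4
}

.scaled_norm <- function(prob, res_f) {
  # residual rows already restricted to free dofs, in global dof order
  dof_kind <- rep(c("u", "p", "c"), c(3L * prob$M, prob$M, prob$M))[prob$free]
  max(abs(res_f) / prob$res_scale[dof_kind])
}

.assemble <- function(prob, config, u, p, c_n, Jsk, ck, g, phis, jacobian) {
  .fem_assemble(prob$gradN, prob$vol, prob$mesh$tets, u, p, c_n,
                Jsk, ck, g, phis, prob$chi_cell,
                prob$lambda, prob$evec, prob$a1, prob$a2, prob$stab,
                .par_vector(config), jacobian)
}

.sparse_from_template <- function(prob, jacvals) {
  x <- .accumulate_triplets(jacvals, prob$keep_idx, prob$map, prob$nnz)
  methods::new("dgCMatrix", i = prob$skel_i, p = as.integer(prob$skel_p),
               x = x, Dim = c(prob$nf, prob$nf))
}

# Monolithic Newton solve for (u, p, c) with g, phi_s, chi, Sigma frozen.
.newton_solve <- function(prob, config, u, p, c_n, Jsk, ck, g, phis) {
  free <- prob$free
  norm0 <- NULL
  for (it in seq_len(config$newton_maxit)) {
    asm <- .assemble(prob, config, u, p, c_n, Jsk, ck, g, phis, TRUE)
    if (!asm$ok)
      stop("assembly failed (inverted element or pore closure) at cell ",
           asm$bad_cell)
    rf <- asm$res[free]
    nrm <- .scaled_norm(prob, rf)
    if (is.null(norm0)) norm0 <- max(nrm, .Machine$double.xmin)
    if (nrm <= config$newton_atol || nrm <= config$newton_rtol * norm0)
      return(list(u = u, p = p, c = c_n, iters = it - 1L, resid = nrm))
    A <- .sparse_from_template(prob, asm$jac)
    dx <- as.numeric(Matrix::solve(A, -rf))
    # damped update: back off on inverted elements or diverging residual
    step <- 1
    for (ls in 1:10) {
      xu <- u; xp <- p; xc <- c_n
      du <- step * dx
      xall <- numeric(5L * prob$M)
      xall[free] <- du
      xu <- u + matrix(xall[1:(3 * prob$M)], ncol = 3, byrow = TRUE)
      xp <- p + xall[3 * prob$M + seq_len(prob$M)]
      xc <- c_n + xall[4 * prob$M + seq_len(prob$M)]
      trial <- .assemble(prob, config, xu, xp, xc, Jsk, ck, g, phis, FALSE)
      if (trial$ok && .scaled_norm(prob, trial$res[free]) <= 2 * nrm) {
        u <- xu; p <- xp; c_n <- xc
        break
      }
      step <- step / 2
      if (ls == 10) stop("Newton line search failed (residual ", nrm, ")")
    }
  }
  stop("Newton did not converge within ", config$newton_maxit,
       " iterations (scaled residual ", signif(nrm, 3), ")")
}

#' Initial simulation state
#'
#' Undeformed, pressure-free, nutrient-saturated state with `g = 1` and
#' `phi_s = phi_sn` everywhere.
#'
#' @param prob A [prepare_problem()] object.
#' @param config A [simulation_config()] object.
#' @return An object of class `gm_state`.
#' @export
initial_state <- function(prob, config) {
  M <- prob$M
  u <- matrix(0, M, 3)
  cstate <- .fem_cell_state(prob$gradN, prob$mesh$tets, u,
                            rep(1, prob$ne), prob$chi_cell,
                            prob$lambda, prob$evec, prob$a1, prob$a2,
                            .par_vector(config))
  structure(list(t = 0, u = u, p = numeric(M), c = rep(1, M),
                 g = rep(1, prob$ne),
                 phi_s = rep(config$growth$phi_sn, prob$ne),
                 cell = cstate, prev_u = u,
                 newton = list(iters = 0L, resid = 0)),
            class = "gm_state")
}

#' Advance the coupled system by one time step
#'
#' Solves the fully discrete residuals of the mass balance, momentum balance
#' and nutrient transport for `(u, p, c)` with the growth stretch, solid
#' fraction, indicator and compression measure frozen at the current level,
#' then updates `g` by explicit Euler and `phi_s` from the growth/volume
#' constraint, and refreshes the reoriented tensors and stresses from the new
#' deformation.
#'
#' @param state A `gm_state` object.
#' @param prob A [prepare_problem()] object.
#' @param config A [simulation_config()] object.
#' @return The new `gm_state`.
#' @export
advance_step <- function(state, prob, config) {
  stopifnot(inherits(state, "gm_state"))
  gp <- config$growth
  Jsk <- .cell_F(prob, state$u)$J
  cbark <- .cell_mean(prob, state$c)
  Sigma_k <- if (config$growth_law == "stress_inhibited")
    state$cell$Sigma else NULL
  Gamma_k <- growth_rate(state$phi_s, cbark, gp, Sigma_k)

  sol <- .newton_solve(prob, config, state$u, state$p, state$c,
                       Jsk, state$c, state$g, state$phi_s)

  g_new <- update_g(state$g, Gamma_k, state$phi_s, prob$chi_cell, config$dt)
  J_new <- .cell_F(prob, sol$u)$J
  phis_new <- update_phi_s(J_new, g_new, gp$phi_sn)
  cstate <- .fem_cell_state(prob$gradN, prob$mesh$tets, sol$u, g_new,
                            prob$chi_cell, prob$lambda, prob$evec,
                            prob$a1, prob$a2, .par_vector(config))
  structure(list(t = state$t + config$dt, u = sol$u, p = sol$p, c = sol$c,
                 g = g_new, phi_s = phis_new, cell = cstate,
                 prev_u = state$u,
                 newton = list(iters = sol$iters, resid = sol$resid)),
            class = "gm_state")
}

#' Fluid (Darcy) velocity per cell
#'
#' Post-processes the converged step:
#' `v_l = v_s - (k A / phi_l) grad p` in the current frame, with the solid
#' velocity from the displacement increment `(u - u_prev)/dt` and the spatial
#' pressure gradient `F^-T Grad p`.
#'
#' @param state A converged `gm_state`.
#' @param prob A [prepare_problem()] object.
#' @param config A [simulation_config()] object.
#' @return ne x 3 matrix of cell fluid velocities (mm/day).
#' @export
darcy_velocity <- function(state, prob, config) {
  tets <- prob$mesh$tets
  vs <- (state$u - state$prev_u) / config$dt
  vs_cell <- (vs[tets[, 1], ] + vs[tets[, 2], ] +
                vs[tets[, 3], ] + vs[tets[, 4], ]) / 4
  # material pressure gradient
  gp <- matrix(0, prob$ne, 3)
  for (a in 1:4) for (d in 1:3)
    gp[, d] <- gp[, d] + state$p[tets[, a]] * prob$gradN[, 3 * (a - 1) + d]
  # spatial gradient F^-T Grad p = cof(F) Grad p / J (vectorized cofactors)
  cf <- .cell_F(prob, state$u)
  Fc <- cf$F; J <- cf$J
  cof <- matrix(0, prob$ne, 9)
  idx <- function(r, c_) (c_ - 1) * 3 + r
  for (r in 1:3) for (c_ in 1:3) {
    rr <- setdiff(1:3, r); cc <- setdiff(1:3, c_)
    cof[, idx(r, c_)] <- (Fc[, idx(rr[1], cc[1])] * Fc[, idx(rr[2], cc[2])] -
                            Fc[, idx(rr[1], cc[2])] * Fc[, idx(rr[2], cc[1])]) *
      (-1)^(r + c_)
  }
  gps <- cbind(cof[, idx(1, 1)] * gp[, 1] + cof[, idx(1, 2)] * gp[, 2] +
                 cof[, idx(1, 3)] * gp[, 3],
               cof[, idx(2, 1)] * gp[, 1] + cof[, idx(2, 2)] * gp[, 2] +
                 cof[, idx(2, 3)] * gp[, 3],
               cof[, idx(3, 1)] * gp[, 1] + cof[, idx(3, 2)] * gp[, 2] +
                 cof[, idx(3, 3)] * gp[, 3]) / J
  A <- state$cell$A
  Agp <- cbind(A[, 1] * gps[, 1] + A[, 2] * gps[, 2] + A[, 3] * gps[, 3],
               A[, 2] * gps[, 1] + A[, 4] * gps[, 2] + A[, 5] * gps[, 3],
               A[, 3] * gps[, 1] + A[, 5] * gps[, 2] + A[, 6] * gps[, 3])
  phl <- 1 - state$phi_s
  if (any(phl <= 1e-10)) stop("fluid fraction vanished (phi_l -> 0)")
  vs_cell - state$cell$k * Agp / phl
}

#' Cellwise advective CFL report
#'
#' `max |v_l| dt / h_cell` with `h_cell` the shortest cell edge; values above
#' one are flagged (warning level, not an error).
#'
#' @param state A converged `gm_state`.
#' @param prob A [prepare_problem()] object.
#' @param config A [simulation_config()] object.
#' @return List with `max_cfl`, `cfl` (per cell) and `flagged` cell indices.
#' @export
cfl_check <- function(state, prob, config) {
  vl <- darcy_velocity(state, prob, config)
  speed <- sqrt(rowSums(vl^2))
  cfl <- speed * config$dt / prob$min_edge
  list(max_cfl = max(cfl), cfl = cfl, flagged = which(cfl > 1))
}

#' Run a full simulation
#'
#' Advances the coupled system from `t = 0` (or a restart state) to
#' `config$t_end`, recording the tumour volume at every step, checkpoints at
#' the configured cadence and a per-step log of Newton iterations, residuals
#' and CFL numbers. Deterministic given fixed inputs.
#'
#' @param prob A [prepare_problem()] object.
#' @param config A [simulation_config()] object.
#' @param init Optional restart state (defaults to [initial_state()]).
#' @param verbose Print per-step progress.
#' @return An object of class `gm_sim` with `final` state, `checkpoints`,
#'   `volume` (data.frame `t`, `V_cm3`), `log`, `metrics`
#'   ([growth_metrics()]) and the `config` echo.
#' @export
run_simulation <- function(prob, config, init = NULL, verbose = FALSE) {
  stopifnot(inherits(prob, "gm_problem"), inherits(config, "gm_config"))
  state <- if (is.null(init)) initial_state(prob, config) else init
  nsteps <- as.integer(round((config$t_end - state$t) / config$dt))
  times <- state$t
  vols <- tumour_volume(state, prob)
  checkpoints <- list()
  log <- data.frame(step = integer(), t = numeric(), newton_iters = integer(),
                    resid = numeric(), max_cfl = numeric())
  for (k in seq_len(nsteps)) {
    state <- advance_step(state, prob, config)
    cfl <- cfl_check(state, prob, config)
    times <- c(times, state$t)
    vols <- c(vols, tumour_volume(state, prob))
    log <- rbind(log, data.frame(step = k, t = state$t,
                                 newton_iters = state$newton$iters,
                                 resid = state$newton$resid,
                                 max_cfl = cfl$max_cfl))
    if (k %% config$output_every == 0L || k == nsteps)
      checkpoints[[length(checkpoints) + 1L]] <- state
    if (verbose)
      message(sprintf("step %d t=%.2f d iters=%d V=%.4f cm^3 cfl=%.3g",
                      k, state$t, state$newton$iters, vols[length(vols)],
                      cfl$max_cfl))
  }
  volume <- data.frame(t = times, V_cm3 = vols)
  structure(list(final = state, checkpoints = checkpoints, volume = volume,
                 log = log, metrics = growth_metrics(times, vols),
                 config = config),
            class = "gm_sim")
}
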