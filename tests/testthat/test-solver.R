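# Solver-level behaviour on small phantoms. The heavier qualitative
# reproduction runs live in test-acceptance.R.

quiet_cfg <- function(...) simulation_config(...)

test_that("zero-source state is a fixed point of the full solver", {
  ph <- small_phantom()
  gp <- growth_params(gamma = 0, zeta = 0, S_n = 0)
  cfg <- quiet_cfg(dt = 0.1, t_end = 5, growth = gp)
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  st <- initial_state(prob, cfg)
  for (k in 1:50) st <- advance_step(st, prob, cfg)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_lt(max(abs(st$p)), 1e-12)
  expect_lt(max(abs(st$c - 1)), 1e-12)
  expect_equal(st$g, rep(1, prob$ne))
  expect_equal(st$phi_s, rep(0.3, prob$ne))
  expect_equal(st$t, 5, tolerance = 1e-12)
})

test_that("interior nutrient level approaches the 0D consumption/supply balance", {
  # uniformly cancerous ball (chi = 1 everywhere), growth switched off so
  # only transport acts; the interior must settle at S_n/(S_n + zeta phi_sn)
  ph <- small_phantom()
  gp <- growth_params(gamma = 0)
  cfg <- quiet_cfg(dt = 0.1, t_end = 0.5, growth = gp)
  chi1 <- rep(1, nrow(ph$mesh$nodes))
  prob <- prepare_problem(ph$mesh, chi1, ph$D0, cfg)
  st <- initial_state(prob, cfg)
  for (k in 1:5) st <- advance_step(st, prob, cfg)
  cstar <- gp$S_n / (gp$S_n + gp$zeta * gp$phi_sn)
  centre <- which.min(rowSums(ph$mesh$nodes^2))
  expect_equal(st$c[centre], cstar, tolerance = 0.02)
  # interior nodes generally (away from the c = 1 boundary layer)
  d <- sqrt(rowSums(ph$mesh$nodes^2))
  interior <- d < 0.5 * ph$spec$brain_radius
  expect_lt(max(abs(st$c[interior] - cstar)) / cstar, 0.02)
})

test_that("free growth of a single unconstrained tet is stress-free", {
  # one tetrahedron, prescribed uniform g, rigid modes pinned but dilation
  # free: the compatible solution is F = g I with vanishing stress and
  # J_s = g^3
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 5
  tets <- matrix(1:4, 1)
  mesh <- gm_mesh(nodes, tets)
  cfg <- quiet_cfg(dt = 0.1, t_end = 1)
  prob <- prepare_problem(mesh, rep(1, 4), matrix(c(86.4, 0, 0, 86.4, 0, 86.4),
                                                  1, 6), cfg)
  g <- 1.2
  # free dofs: node2 x, node3 (x, y), node4 (x, y, z); p = 0, c = 1 fixed
  free <- c(4L, 7L, 8L, 10L, 11L, 12L)
  u <- matrix(0, 4, 3); p <- numeric(4); cn <- rep(1, 4)
  par <- gliomech:::.par_vector(cfg)
  for (it in 1:50) {
    asm <- gliomech:::.fem_assemble(prob$gradN, prob$vol, mesh$tets, u, p, cn,
                                    1, rep(1, 4), g, 0.3, prob$chi_cell,
                                    prob$lambda, prob$evec, prob$a1, prob$a2,
                                    prob$stab, par, TRUE)
    stopifnot(asm$ok)
    rf <- asm$res[free]
    if (max(abs(rf)) < 1e-16) break
    J <- matrix(asm$jac, 20, 20)[free, free]  # element-local = global here
    du <- solve(J, -rf)
    uu <- t(u); uu[free] <- uu[free] + du; u <- t(uu)
  }
  kin <- compute_kinematics(t(u[2:4, ]) %*% matrix(prob$gradN[1, 4:12], 3, 3,
                                                   byrow = FALSE) +
                              u[1, ] %o% prob$gradN[1, 1:3], g = g)
  cs <- gliomech:::.fem_cell_state(prob$gradN, mesh$tets, u, g,
                                   prob$chi_cell, prob$lambda, prob$evec,
                                   prob$a1, prob$a2, par)
  expect_equal(cs$J_s, g^3, tolerance = 1e-8)
  expect_lt(max(abs(cs$T_s)), 1e-12)
})

test_that("Darcy post-processing matches hand computations", {
  ph <- small_phantom()
  cfg <- quiet_cfg(dt = 0.1, t_end = 1)
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  st <- initial_state(prob, cfg)

  # uniform pressure: fluid moves with the solid (here both at rest)
  st$p <- rep(0.5e-3, prob$M)
  vl <- darcy_velocity(st, prob, cfg)
  expect_lt(max(abs(vl)), 1e-10)

  # linear pressure ramp p = a x with the solid at rest, isotropic A = I:
  # v_l = -(k / phi_l) grad p everywhere
  a <- 1e-6  # MPa/mm
  st$p <- a * ph$mesh$nodes[, 1]
  vl <- darcy_velocity(st, prob, cfg)
  k0 <- cfg$permeability$k0
  expected <- -k0 * a / 0.7
  expect_equal(vl[, 1], rep(expected, prob$ne), tolerance = 1e-6)
  expect_lt(max(abs(vl[, 2:3])), 1e-8 * abs(expected))

  # anisotropic mobility deflects the flux away from -grad p
  spec_a <- phantom_spec(brain_radius = 20, h = 7, tumour_radius = 5,
                         dti_mode = "uniform_axis",
                         eigenvalues = c(10, 1, 1) * 8.64)
  pha <- make_phantom(spec_a)
  proba <- prepare_problem(pha$mesh, pha$chi, pha$D0, cfg)
  sta <- initial_state(proba, cfg)
  gdir <- c(1, 1, 0) / sqrt(2)
  sta$p <- a * (pha$mesh$nodes %*% gdir)[, 1]
  vla <- darcy_velocity(sta, proba, cfg)
  A <- vec_to_sym(sta$cell$A[1, ])
  vref <- -k0 * as.numeric(A %*% gdir) * a / 0.7
  expect_equal(vla[1, ], vref, tolerance = 1e-6)
  cosang <- sum(vla[1, ] * (-gdir)) / sqrt(sum(vla[1, ]^2))
  expect_lt(cosang, 0.999)  # genuinely deflected off the gradient direction
})

test_that("CFL report equals the brute-force cellwise maximum", {
  ph <- small_phantom()
  cfg <- quiet_cfg(dt = 0.1, t_end = 1)
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  st <- initial_state(prob, cfg)
  r <- cfl_check(st, prob, cfg)
  expect_equal(r$max_cfl, 0)
  expect_length(r$flagged, 0)

  # synthetic advecting field: |v| dt / h against an exhaustive scan
  st$p <- 1e-5 * ph$mesh$nodes[, 1]
  r <- cfl_check(st, prob, cfg)
  vl <- darcy_velocity(st, prob, cfg)
  brute <- max(sqrt(rowSums(vl^2)) * cfg$dt / prob$min_edge)
  expect_equal(r$max_cfl, brute)
  # definition spot check: |v| = 1 mm/day, h = 1 mm, dt = 0.1 -> 0.1
  expect_equal(1 * 0.1 / 1, 0.1)
})

test_that("runs are deterministic and restartable from checkpoints", {
  ph <- small_phantom()
  cfg <- quiet_cfg(dt = 0.1, t_end = 0.2, output_every = 1L)
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  sim <- run_simulation(prob, cfg)
  # restart from the first checkpoint reproduces the continuous run bitwise
  chk <- sim$checkpoints[[1]]
  expect_equal(chk$t, 0.1)
  sim2 <- run_simulation(prob, cfg, init = chk)
  expect_identical(sim2$final$u, sim$final$u)
  expect_identical(sim2$final$p, sim$final$p)
  expect_identical(sim2$final$c, sim$final$c)
  expect_identical(sim2$final$g, sim$final$g)
  # full rerun identical
  sim3 <- run_simulation(prob, cfg)
  expect_identical(sim3$final$u, sim$final$u)
  expect_identical(sim3$volume, sim$volume)
})

test_that("growth stretch is monotone and confined to the tumour region", {
  ph <- small_phantom()
  cfg <- quiet_cfg(dt = 0.1, t_end = 0.5)
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  st <- initial_state(prob, cfg)
  g_prev <- st$g
  for (k in 1:5) {
    st <- advance_step(st, prob, cfg)
    expect_true(all(st$g >= g_prev - 1e-15))
    g_prev <- st$g
    # saturation holds exactly
    expect_equal(st$phi_s + (1 - st$phi_s), rep(1, prob$ne))
  }
  outside <- prob$chi_cell < 1e-6
  expect_true(any(outside))
  expect_lt(max(abs(st$g[outside] - 1)), 1e-7)
  expect_gt(max(st$g), 1.001)   # and it did grow inside
})

test_that("halving the time step changes the day-10 tumour volume by < 1%", {
  ph <- small_phantom()
  vol_at <- function(dt) {
    cfg <- quiet_cfg(dt = dt, t_end = 10)
    prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
    sim <- run_simulation(prob, cfg)
    sim$volume$V_cm3[nrow(sim$volume)]
  }
  v1 <- vol_at(0.1)
  v2 <- vol_at(0.05)
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("zero-flux boundary mode for pressure and nutrients also solves", {
  ph <- small_phantom()
  cfg <- quiet_cfg(dt = 0.1, t_end = 0.2, bc_mode = "zero_flux")
  prob <- prepare_problem(ph$mesh, ph$chi, ph$D0, cfg)
  sim <- run_simulation(prob, cfg)
  expect_true(all(is.finite(sim$final$p)))
  expect_true(all(is.finite(sim$final$c)))
  # with no nutrient inflow the total nutrient content cannot exceed start
  expect_lt(min(sim$final$c), 1)
})
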