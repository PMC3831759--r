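# Element matrices, assembly, boundary conditions and the Newmark stepper.

test_that("rigid translations lie in the null space of the element k_uu", {
  em <- element_matrices(unit_square, material())
  expect_lt(max(abs(em$k_uu %*% rep(c(1, 0), 4))), 1e-9 * max(abs(em$k_uu)))
  expect_lt(max(abs(em$k_uu %*% rep(c(0, 1), 4))), 1e-9 * max(abs(em$k_uu)))
  ev <- eigen(em$k_uu, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 * max(ev)))     # positive semi-definite
  expect_equal(em$k_uu, t(em$k_uu), tolerance = 1e-13)
})

test_that("element blocks satisfy the structural coupling identities", {
  set.seed(101)
  for (i in 1:5) {
    q <- random_quad()
    mat <- material()
    em <- element_matrices(q, mat)
    # k_up and c_pu carry the same volumetric integral, opposite sign
    expect_equal(em$k_up, -t(em$c_pu), tolerance = 1e-14)
    # Darcy resistance scales as 1/k_perm
    mat2 <- material(k_perm = 2 * mat$k_perm)
    em2 <- element_matrices(q, mat2)
    expect_equal(em2$k_qq, em$k_qq / 2, tolerance = 1e-14)
    # the other blocks are untouched by permeability
    expect_equal(em2$k_uu, em$k_uu)
    expect_equal(em2$c_pp, em$c_pp)
  }
})

test_that("element blocks match the brute-force quadrature oracle", {
  set.seed(2024)
  blocks <- c("m_uu", "m_qu", "c_uq", "c_pu", "c_pp", "c_qq",
              "k_uu", "k_up", "k_pq", "k_qp", "k_qq", "k_pp_stab")
  for (i in 1:8) {
    q <- random_quad()
    em <- element_matrices(q, material(), n_gauss = 4)
    bf <- element_matrices_bruteforce(q, material(), n_gauss = 4)
    for (b in blocks)
      expect_lt(max(abs(em[[b]] - bf[[b]])) / max(abs(bf[[b]])), 1e-10)
    expect_equal(em$area, bf$area, tolerance = 1e-12)
  }
})

test_that("degenerate elements and invalid materials are rejected", {
  bowtie <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  expect_error(element_matrices(bowtie, material()), "degenerate")
  expect_error(material(E = -1), "E must be")
  expect_error(material(nu = 0.5), "nu must")
  expect_error(material(porosity = 1), "porosity")
})

test_that("global assembly of one element equals its element blocks", {
  mesh <- build_column_mesh(1, 1, width = 1)
  mat <- material()
  sys <- assemble_system(mesh, mat)
  em <- element_matrices(mesh$nodes[mesh$elements[1, ], ], mat)
  lay <- sys$layout
  en <- mesh$elements[1, ]
  du <- cervodil:::dof_u(en, lay$n_nodes)
  dp <- cervodil:::dof_p(en, lay$n_nodes)
  dq <- cervodil:::dof_q(en, lay$n_nodes)
  expect_equal(as.matrix(sys$K[du, du]), em$k_uu, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys$K[du, dp]), em$k_up, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys$C[dp, du]), em$c_pu, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys$M[dq, du]), em$m_qu, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(dim(sys$K), rep(5 * lay$n_nodes, 2))
})

test_that("assembly is additive over elements sharing nodes", {
  mesh <- build_column_mesh(2, 2, width = 1)
  mat <- material()
  sys <- assemble_system(mesh, mat)
  lay <- sys$layout
  e1 <- element_matrices(mesh$nodes[mesh$elements[1, ], ], mat)
  e2 <- element_matrices(mesh$nodes[mesh$elements[2, ], ], mat)
  acc <- matrix(0, lay$n_dof, lay$n_dof)
  for (ee in list(list(e = e1, n = mesh$elements[1, ]),
                  list(e = e2, n = mesh$elements[2, ]))) {
    du <- cervodil:::dof_u(ee$n, lay$n_nodes)
    acc[du, du] <- acc[du, du] + ee$e$k_uu
  }
  expect_equal(as.matrix(sys$K[lay$u, lay$u]), acc[lay$u, lay$u],
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("edge pressure becomes work-equivalent nodal forces", {
  mesh <- build_column_mesh(1, 4, width = 0.3)
  f <- cervodil:::unit_pressure_load(mesh, "drained_surface")
  expect_equal(sum(abs(f[f != 0])), 0.3, tolerance = 1e-14)  # P*L for P=1
  # the force points downwards (compressing the column)
  lay <- dof_layout(mesh)
  fy <- f[lay$u[seq(2, length(lay$u), 2)]]
  expect_true(all(fy <= 0))
  expect_error(cervodil:::get_bset(mesh, "no_such_set"), "unknown boundary")
})

test_that("zero-pressure protocols produce a zero load vector", {
  mesh <- tiny_annulus()
  sys <- assemble_system(mesh, material())
  csys <- apply_boundary_conditions(sys, default_bc(mesh),
                                    make_protocol("step", p_max = 0,
                                                  t_end = 1))
  expect_identical(max(abs(csys$load_fun(0.7))), 0)
})

test_that("solver configuration enforces the stability region", {
  expect_error(solver_config(newmark_gamma = 0.4), "gamma")
  expect_error(solver_config(newmark_beta = 0.2, newmark_gamma = 0.6),
               "beta")
  expect_error(solver_config(dt = 0), "dt")
  expect_silent(solver_config(newmark_beta = 0.5625, newmark_gamma = 1))
})

test_that("single-dof Newmark reference reproduces the harmonic oscillator", {
  ref0 <- sdof_newmark_reference(1, 4 * pi^2, dt = 0.01, n_steps = 100)
  expect_identical(max(abs(ref0$u)), 0)       # zero input stays zero

  # u(0) = 1: amplitude conserved to 0.1 % and period error < 0.2 %
  # over 10 cycles at dt = T/100 with the trapezoidal pair
  omega <- 2 * pi; T <- 1
  ref <- sdof_newmark_reference(1, omega^2, dt = T / 100,
                                n_steps = 1000, u0 = 1)
  expect_lt(max(abs(ref$u)) - 1, 1e-3)
  env <- sqrt(ref$u^2 + (ref$v / omega)^2)    # amplitude envelope
  expect_lt(max(abs(env - 1)), 1e-3)
  expect_lt(abs(measured_period(ref$time, ref$u) / T - 1), 2e-3)

  # gamma > 1/2 damps the peaks monotonically
  refd <- sdof_newmark_reference(1, omega^2, dt = T / 40, n_steps = 400,
                                 beta = 0.3025, gamma = 0.6, u0 = 1)
  pk <- refd$u[which(diff(sign(diff(refd$u))) == -2) + 1]
  expect_true(all(diff(pk[pk > 0.1]) < 0))
})

test_that("assembled stepper matches the single-dof reference dynamics", {
  # same scheme on the assembled system: constant load converges to the
  # static drained solution once transients are damped out
  mesh <- build_column_mesh(0.1, 4)
  mat <- material(E = 1e6, nu = 0.3, k_perm = 1e-6)   # freely draining
  pr <- make_protocol("step", p_max = 500, t_end = 10)
  cfg <- solver_config(dt = 0.05, t_end = 10, newmark_beta = 0.5625,
                       newmark_gamma = 1, startup_substeps = 5)
  res <- run_simulation(mesh, mat, pr, cfg, record_rates = FALSE)
  u_end <- result_field(res, "u", length(res$time))
  u_static <- static_drained_solve(mesh, mat, pressure = 500, config = cfg)
  expect_equal(u_end, u_static, tolerance = 1e-3)
})

test_that("unloaded system conserves/dissipates energy at 100x the step", {
  mesh <- tiny_annulus()
  cfg <- solver_config(dt = 10, t_end = 500)  # 100x the 0.1 s default
  sys <- assemble_system(mesh, material(), cfg)
  csys <- apply_boundary_conditions(sys, default_bc(mesh),
                                    make_protocol("step", p_max = 0,
                                                  t_end = 500))
  set.seed(5)
  st <- init_state(csys)
  lay <- csys$layout
  x0 <- numeric(lay$n_dof)
  x0[lay$u] <- rnorm(length(lay$u), sd = 1e-5)
  y <- as.numeric(csys$Tmat %*% x0); y[csys$fixed] <- 0
  st$x <- as.numeric(Matrix::t(csys$Tmat) %*% y)
  stepper <- prepare_stepper(csys, cfg)
  e0 <- system_energy(csys, st)
  emax <- 0
  for (i in 1:50) {
    st <- newmark_step(st, stepper, i * cfg$dt)
    emax <- max(emax, system_energy(csys, st))
  }
  expect_lte(emax, e0 * (1 + 1e-9))
  expect_lt(system_energy(csys, st), e0)
})

test_that("prescribed-displacement mode drives the bore to the target", {
  mesh <- tiny_annulus()
  bc <- bc_spec(pressure = "inner_surface", displacement_control = TRUE,
                impermeable = "inner_surface", drained = "outer_surface",
                symmetry = "symmetry_plane", pin_x = "y_axis")
  d_target <- 5e-5
  pr <- make_protocol("ramp", p_max = d_target, t_rise = 1, t_end = 2,
                      label = "opening ramp [m]")
  res <- run_simulation(mesh, material(), pr, quick_config(2), bc = bc,
                        record_rates = FALSE)
  op <- inner_opening(res)
  expect_equal(op[length(op)], d_target, tolerance = 1e-8)
})
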