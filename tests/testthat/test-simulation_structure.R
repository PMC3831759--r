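# Structural properties of the forward model: zero input, linearity,
# symmetry, and the drained/undrained limits.

test_that("zero pressure produces identically zero fields", {
  res <- run_simulation(tiny_annulus(), material(),
                        make_protocol("ramp", p_max = 0, t_rise = 1,
                                      t_end = 2),
                        quick_config(2))
  expect_identical(max(abs(res$X)), 0)
  expect_identical(max(abs(res$V)), 0)
})

test_that("the response is exactly linear in the applied pressure", {
  mesh <- tiny_annulus()
  pr <- make_protocol("ramp", p_max = 5e3, t_rise = 1.5, t_end = 2)
  r1 <- run_simulation(mesh, material(), pr, quick_config(2),
                       record_rates = FALSE)
  r2 <- run_simulation(mesh, material(), cervodil:::scale_protocol(pr, 2),
                       quick_config(2), record_rates = FALSE)
  expect_lt(max(abs(r2$X - 2 * r1$X)) / max(abs(r2$X)), 1e-10)
})

test_that("half model with symmetry conditions matches the full model", {
  mat <- material()
  pr <- make_protocol("ramp", p_max = 10e3, t_rise = 1.5, t_end = 2)
  cfg <- quick_config(2)
  half <- build_annulus_mesh(1.5e-3, 10e-3, 6, 12, half_model = TRUE)
  full <- build_annulus_mesh(1.5e-3, 10e-3, 6, 24, half_model = FALSE)
  rh <- run_simulation(half, mat, pr, cfg, record_rates = FALSE)
  rf <- run_simulation(full, mat, pr, cfg, record_rates = FALSE)
  map <- match_nodes(half, full)
  expect_false(anyNA(map))
  lh <- dof_layout(half); lf <- dof_layout(full)
  ns <- length(rh$time)
  uh <- matrix(rh$X[lh$u, ns], ncol = 2, byrow = TRUE)
  uf <- matrix(rf$X[lf$u, ns], ncol = 2, byrow = TRUE)
  expect_lt(max(abs(uh - uf[map, ])) / max(abs(uf)), 1e-8)
  expect_lt(max(abs(rh$X[lh$p, ns] - rf$X[lf$p, ns][map])) /
              max(abs(rf$X[lf$p, ns])), 1e-8)
})

test_that("undrained limit: instantaneous pore pressure is uniform", {
  mesh <- build_column_mesh(1, 20)
  mat <- material(E = 1e6, nu = 0.3, k_perm = 3e-15 * 1e-6)
  sig0 <- 1e4
  pr <- make_protocol("step", p_max = sig0, t_end = 1)
  # in the near-incompressible undrained limit the equal-order pair needs
  # the pressure stabilization term to suppress checkerboard modes
  cfg <- solver_config(dt = 0.05, t_end = 1, newmark_beta = 0.5625,
                       newmark_gamma = 1, startup_substeps = 10,
                       pressure_stabilization = 1)
  res <- run_simulation(mesh, mat, pr, cfg, record_rates = FALSE)
  lay <- res$csys$layout
  p1 <- res$X[lay$p, 2]                      # first recorded step
  interior <- mesh$nodes[, 2] < 0.72         # outside the drained face layer
  expect_lt((max(p1[interior]) - min(p1[interior])) / sig0, 0.02)
  expect_equal(mean(p1[interior]), sig0, tolerance = 0.02)

  # without stabilization the same run exhibits the spurious mode
  cfg0 <- solver_config(dt = 0.05, t_end = 1, newmark_beta = 0.5625,
                        newmark_gamma = 1, startup_substeps = 10)
  res0 <- run_simulation(mesh, mat, pr, cfg0, record_rates = FALSE)
  p0 <- res0$X[lay$p, 2]
  expect_gt((max(p0[interior]) - min(p0[interior])) / sig0, 0.02)
})

test_that("consolidation transient follows the Terzaghi series (coarse)", {
  bench <- terzaghi_benchmark(n_elements = 12, t_end = 4)
  out <- run_terzaghi_benchmark(bench)
  expect_lt(out$max_err_pct, 3)              # coarse column, loose band
})

test_that("discrete mass balance holds at every step", {
  bench <- terzaghi_benchmark(n_elements = 12, t_end = 4)
  out <- run_terzaghi_benchmark(bench)
  mb <- out$mass_balance
  scale <- max(abs(mb$boundary_flux))
  expect_gt(scale, 0)
  expect_lt(max(abs(mb$residual)) / scale, 1e-8)
})

test_that("solver failures identify the failing time step", {
  mesh <- tiny_annulus()
  # an impossible linear tolerance forces a solver error
  cfg <- solver_config(dt = 0.1, t_end = 1, linear_tolerance = 1e-30)
  err <- tryCatch(
    run_simulation(mesh, material(), make_protocol("step", p_max = 1e3,
                                                   t_end = 1), cfg),
    error = function(e) e)
  expect_s3_class(err, "cervodil_solver_error")
  expect_match(conditionMessage(err), "time step")
})
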