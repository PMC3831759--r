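# Forward observable, synthetic observations, and identifiability.
# The full parameter-recovery experiment (noise-free and noisy) lives in
# the acceptance suite; these tests cover the structural contracts.

fit_mesh <- function() build_annulus_mesh(1.5e-3, 10e-3, 4, 8)
fit_cfg <- function(dt = 0.5, t_end = 10)
  solver_config(dt = dt, t_end = t_end, newmark_beta = 0.390625,
                newmark_gamma = 0.75)

test_that("zero protocol gives a zero opening series", {
  pr <- make_protocol("ramp", p_max = 0, t_rise = 5, t_end = 10)
  op <- simulate_opening(0.15e6, 3e-15, pr, fit_mesh(), fit_cfg())
  expect_identical(max(abs(op$opening)), 0)
})

test_that("opening is non-negative and scales inversely with E when drained", {
  pr <- make_protocol("ramp", p_max = 5e3, t_rise = 5, t_end = 10)
  k_drained <- 3e-15 * 1e6
  o1 <- simulate_opening(0.15e6, k_drained, pr, fit_mesh(), fit_cfg())
  o2 <- simulate_opening(0.30e6, k_drained, pr, fit_mesh(), fit_cfg())
  expect_true(all(o1$opening >= 0))
  sel <- o1$opening > 1e-9
  expect_equal(o2$opening[sel], o1$opening[sel] / 2, tolerance = 1e-2)
})

test_that("synthetic observations are reproducible and correctly scaled", {
  pr <- make_protocol("ramp", p_max = 5e3, t_rise = 5, t_end = 60)
  mesh <- fit_mesh()
  cfg <- fit_cfg(dt = 0.12, t_end = 60)     # 501 points
  clean <- synthesize_observation(0.15e6, 3e-15, pr, mesh, cfg,
                                  noise_sd = 0, seed = 9)
  base <- simulate_opening(0.15e6, 3e-15, pr, mesh, cfg)
  expect_equal(clean$opening, base$opening)  # noise_sd = 0 is exact

  sd <- 2e-6
  n1 <- synthesize_observation(0.15e6, 3e-15, pr, mesh, cfg,
                               noise_sd = sd, seed = 42)
  n2 <- synthesize_observation(0.15e6, 3e-15, pr, mesh, cfg,
                               noise_sd = sd, seed = 42)
  expect_identical(n1$opening, n2$opening)   # same seed, same series
  n3 <- synthesize_observation(0.15e6, 3e-15, pr, mesh, cfg,
                               noise_sd = sd, seed = 43)
  expect_false(identical(n1$opening, n3$opening))
  # sample noise level within 10 % of the requested one (500+ points)
  expect_equal(sd(n1$opening - base$opening), sd, tolerance = 0.1)
  # pressure column echoes the protocol
  expect_equal(n1$pressure, protocol_value(pr, n1$time))
})

test_that("residual at the generating parameters is zero", {
  sc <- calibration_scenario(n_radial = 4, n_circumferential = 8,
                             dt = 1, t_end = 20)
  sc$protocol <- ccbd_protocol(10e3, t_end = 20, t_rise = 15)
  obs <- synthesize_observation(0.15e6, 3e-15, sc$protocol, sc$mesh,
                                sc$config, noise_sd = 0, seed = 1,
                                bc = sc$bc)
  sim <- simulate_opening(0.15e6, 3e-15, sc$protocol, sc$mesh, sc$config,
                          bc = sc$bc)
  expect_lt(max(abs(sim$opening - obs$opening)), 1e-18)
})

test_that("E and k are jointly identifiable from the transient ramp", {
  sc <- calibration_scenario()
  sens <- opening_sensitivity(0.15e6, 3e-15, sc$protocol, sc$mesh,
                              sc$config, bc = sc$bc)
  # two strictly positive, numerically separated eigenvalues
  expect_gt(sens$eigenvalues[2], 1e-8 * sens$eigenvalues[1])
  expect_gt(sens$eigenvalues[2], 0)
})

test_that("steady-state-only data cannot identify the permeability", {
  # fast-draining configuration: the observation window sits almost
  # entirely on the drained plateau, so the permeability column of the
  # Jacobian collapses relative to the transient scenario's
  mesh <- fit_mesh()
  cfg <- fit_cfg(dt = 1, t_end = 30)
  k_ratio <- function(k_perm, t_rise) {
    pr <- make_protocol("ramp", p_max = 5e3, t_rise = t_rise, t_end = 30)
    s <- opening_sensitivity(0.15e6, k_perm, pr, mesh, cfg,
                             bc = calibration_bc())
    list(ratio = sqrt(sum(s$J[, 2]^2) / sum(s$J[, 1]^2)),
         eig = s$eigenvalues)
  }
  steady <- k_ratio(3e-15 * 1e6, t_rise = 1)
  transient <- k_ratio(3e-15, t_rise = 22)
  expect_lt(steady$ratio, 1e-3)
  expect_lt(steady$ratio, transient$ratio / 10)
  expect_lt(steady$eig[2] / steady$eig[1],
            0.1 * transient$eig[2] / transient$eig[1])
})

test_that("invalid fitting inputs are rejected", {
  expect_error(simulate_opening(-1, 3e-15,
                                make_protocol("step", p_max = 1, t_end = 1),
                                fit_mesh(), fit_cfg()), "positive")
  expect_error(synthesize_observation(1e5, 1e-15,
                                      make_protocol("step", p_max = 1,
                                                    t_end = 1),
                                      fit_mesh(), fit_cfg(),
                                      noise_sd = -1), "noise_sd")
  expect_error(fit_parameters(data.frame(time = 0, opening = 0),
                              make_protocol("step", p_max = 1, t_end = 1),
                              fit_mesh(), fit_cfg(),
                              initial_guess = c(E = -1, k = 1e-15)),
               "positive")
})
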