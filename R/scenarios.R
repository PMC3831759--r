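# Canonical study and verification configurations.
#
# These functions freeze, in one place, the conditions under which the
# package's simulations and verification benchmarks are run: the default
# canal geometry, the dilation comparison setup, the consolidation-column
# and pressurised-cylinder benchmarks, and the calibration scenario.

#' Default cervical-canal cross-section mesh
#'
#' Canal bore radius 1.5 mm and outer tissue radius 10 mm (configurable
#' defaults: the published study states no radii; these are chosen so a
#' Hegar final radius of 4 mm stays within small-strain plausibility).
#'
#' @param n_radial,n_circumferential Resolution (default 16 x 32).
#' @param half_model Use the symmetric half model (default).
#' @return A `biot_mesh`.
#' @export
default_annulus <- function(n_radial = 16, n_circumferential = 32,
                            half_model = TRUE) {
  build_annulus_mesh(1.5e-3, 10e-3, n_radial, n_circumferential, half_model)
}

#' Solver settings for the dilation scenarios
#'
#' `dt = 0.1 s` over one minute, with a dissipative Newmark pair
#' (`gamma = 0.75`, `beta = (gamma + 1/2)^2/4`) that removes the
#' unresolved microsecond-scale poroelastic wave transients excited by
#' step-like dilator loads while leaving the second-scale consolidation
#' response intact, plus a substepped first increment.
#'
#' @param dt,t_end Time step and duration \[s\].
#' @return A [solver_config()].
#' @export
dilation_config <- function(dt = 0.1, t_end = 60) {
  solver_config(dt = dt, t_end = t_end, newmark_beta = 0.390625,
                newmark_gamma = 0.75, startup_substeps = 10)
}

#' Canal boundary conditions with a fixed or compliant outer wall
#'
#' Dilator pressure on the sealed inner surface, drainage at the outer
#' surface and mirror symmetry.  `outer_fixed = TRUE` clamps the outer
#' wall rigidly; `FALSE` (used by the scenario comparisons and the
#' calibration) leaves it traction-free --- the cervix is embedded in
#' compliant tissue --- and pins the x-displacement on the y axis to
#' remove the rigid translation of the traction-free half model.
#'
#' @param outer_fixed Clamp the outer wall.
#' @return A [bc_spec()].
#' @export
canal_bc <- function(outer_fixed = FALSE) {
  if (outer_fixed)
    bc_spec(pressure = "inner_surface", impermeable = "inner_surface",
            fixed = "outer_surface", drained = "outer_surface",
            symmetry = "symmetry_plane")
  else
    bc_spec(pressure = "inner_surface", impermeable = "inner_surface",
            drained = "outer_surface", symmetry = "symmetry_plane",
            pin_x = "y_axis")
}

#' Hegar versus CCBD dilation comparison
#'
#' Runs the step-like Hegar protocol against the 45-s CCBD ramp to the
#' same working pressure on the identical default half-annulus mesh and
#' tissue material, and reports peak von Mises effective stresses and
#' openings at the standard snapshot times.
#'
#' @param p_max Working pressure \[Pa\] (default 10 kPa).
#' @param mesh,mat,config Overrides for the defaults.
#' @param hegar_rise Hegar rise time \[s\]; 0 gives an ideal step.
#' @param snapshot_times Snapshot times \[s\].
#' @param bc Boundary conditions (default [canal_bc()] with the compliant
#'   outer wall, under which the late-time stresses of the two dilators
#'   converge once their pressures match).
#' @return A `dilator_comparison`.
#' @export
dilation_comparison <- function(p_max = 10e3, mesh = default_annulus(),
                                mat = material(),
                                config = dilation_config(),
                                hegar_rise = 0,
                                snapshot_times = c(5, 20, 35, 45),
                                bc = canal_bc()) {
  compare_dilators(mesh, mat,
                   hegar_protocol(p_max, t_end = config$t_end,
                                  t_rise = hegar_rise),
                   ccbd_protocol(p_max, t_end = config$t_end),
                   config, snapshot_times = snapshot_times, bc = bc)
}

#' Consolidation-column verification benchmark
#'
#' One-element-wide, 40-element column under a step load with a drained
#' top: the transient pore-pressure field must follow the closed-form
#' consolidation series.  The benchmark material is chosen so the
#' consolidation time factor reaches 0.5 within the run
#' (`cv = 0.0625 m^2/s` on a 1-m column) and the integrator uses the
#' fully damped Newmark member with a substepped first increment, which
#' suppresses the unresolved undrained wave transient of the sudden load.
#'
#' @param n_elements Elements along the column (default 40).
#' @param sigma0 Step load \[Pa\].
#' @param height Column height \[m\].
#' @param cv Target consolidation coefficient \[m^2/s\].
#' @param dt,t_end Time stepping \[s\].
#' @return List with `mesh`, `mat`, `protocol`, `config`, `setup` (the
#'   [consolidation_setup()]), and `depths` (node depths below the
#'   drained surface).
#' @export
terzaghi_benchmark <- function(n_elements = 40, sigma0 = 1e4, height = 1,
                               cv = 0.0625, dt = 0.1, t_end = 8) {
  E <- 1e6; nu <- 0.3
  M <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  mat <- material(E = E, nu = nu, k_perm = cv / M)
  mesh <- build_column_mesh(height, n_elements)
  list(mesh = mesh, mat = mat,
       protocol = make_protocol("step", p_max = sigma0, t_end = t_end,
                                label = "consolidation step"),
       config = solver_config(dt = dt, t_end = t_end,
                              newmark_beta = 0.5625, newmark_gamma = 1,
                              startup_substeps = 20),
       setup = consolidation_setup(sigma0, height, mat = mat),
       depths = height - mesh$nodes[, 2])
}

#' Run the consolidation benchmark and measure the oracle error
#'
#' @param bench From [terzaghi_benchmark()].
#' @param skip_steps Compare only beyond this many initial steps
#'   (default 5).
#' @return List with the `result`, per-step maximum absolute
#'   pressure error as a percentage of the applied load (`err_pct`), its
#'   maximum over the compared window (`max_err_pct`), and the
#'   [mass_balance()] audit table.
#' @export
run_terzaghi_benchmark <- function(bench, skip_steps = 5) {
  res <- run_simulation(bench$mesh, bench$mat, bench$protocol, bench$config)
  lay <- res$csys$layout
  steps <- which(seq_along(res$time) - 1L > skip_steps)
  err <- vapply(steps, function(s) {
    max(abs(res$X[lay$p, s] -
              terzaghi_pressure(bench$setup, bench$depths, res$time[s])))
  }, numeric(1))
  list(result = res, time = res$time[steps],
       err_pct = 100 * err / bench$setup$sigma0,
       max_err_pct = 100 * max(err) / bench$setup$sigma0,
       mass_balance = mass_balance(res))
}

#' Boundary conditions for the pressurised-cylinder benchmark
#'
#' Inner pressure on a sealed bore, drained traction-free outer surface,
#' mirror symmetry, x-displacement pinned on the y axis: identical to the
#' compliant [canal_bc()], matching the traction-free-outer Lame variant.
#'
#' @return A [bc_spec()].
#' @export
lame_bc <- function() canal_bc(outer_fixed = FALSE)

#' Drained-limit annulus inflation versus the Lame solution
#'
#' Scales the tissue permeability by `k_factor` (default 1e6) so the pore
#' fluid drains freely, ramps the bore pressure slowly, and compares the
#' final radial displacement and hoop stress fields with the closed-form
#' plane-strain solution for a traction-free outer wall.
#'
#' @param n_radial,n_circumferential Mesh resolution.
#' @param p_inner Bore pressure \[Pa\].
#' @param k_factor Permeability scaling into the drained limit.
#' @param mat Base tissue material.
#' @return List with the relative maximum displacement error (`u_err`),
#'   relative maximum hoop-stress error at element centroids
#'   (`hoop_err`), relative displacement L2 error (`u_l2`), and the
#'   `result`.
#' @export
lame_benchmark <- function(n_radial = 64, n_circumferential = 128,
                           p_inner = 1e3, k_factor = 1e6,
                           mat = material()) {
  r_i <- 1.5e-3; r_o <- 10e-3
  mesh <- build_annulus_mesh(r_i, r_o, n_radial, n_circumferential)
  matd <- material(E = mat$E, nu = mat$nu, k_perm = mat$k_perm * k_factor,
                   rho_solid = mat$rho_solid, rho_fluid = mat$rho_fluid,
                   porosity = mat$porosity,
                   fluid_compressibility = mat$fluid_compressibility)
  pr <- make_protocol("ramp", p_max = p_inner, t_rise = 5, t_end = 8,
                      label = "slow inflation")
  cfg <- solver_config(dt = 0.25, t_end = 8, newmark_beta = 0.390625,
                       newmark_gamma = 0.75)
  res <- run_simulation(mesh, matd, pr, cfg, bc = lame_bc(), stride = 8L,
                        record_rates = FALSE)
  ns <- length(res$time)
  u <- result_field(res, "u", ns)
  r <- sqrt(rowSums(mesh$nodes^2))
  ur <- rowSums(u * mesh$nodes) / r
  ex <- lame_thick_cylinder(p_inner, r_i, r_o, matd$E, matd$nu, r,
                            outer = "free")
  st <- effective_stress(res)
  rc <- sqrt(rowSums(st$centroids^2))
  th <- atan2(st$centroids[, 2], st$centroids[, 1])
  hoop <- st$sxx[, ns] * sin(th)^2 - 2 * st$sxy[, ns] * sin(th) * cos(th) +
    st$syy[, ns] * cos(th)^2
  exc <- lame_thick_cylinder(p_inner, r_i, r_o, matd$E, matd$nu, rc,
                             outer = "free")
  list(u_err = max(abs(ur - ex$u_r)) / max(abs(ex$u_r)),
       hoop_err = max(abs(hoop - exc$sigma_theta)) / max(abs(exc$sigma_theta)),
       u_l2 = sqrt(mean((ur - ex$u_r)^2)) / sqrt(mean(ex$u_r^2)),
       result = res)
}

#' Observed convergence order of the drained annulus solution
#'
#' Runs [lame_benchmark()] on a ladder of uniformly refined meshes and
#' fits the slope of the displacement L2 error.
#'
#' @param n_radial Radial resolutions of the ladder.
#' @return List with `errors` and the fitted `order`.
#' @export
lame_convergence <- function(n_radial = c(8, 16, 32)) {
  errs <- vapply(n_radial, function(nr)
    lame_benchmark(nr, 2 * nr)$u_l2, numeric(1))
  fit <- stats::lm(log(errs) ~ log(1 / n_radial))
  list(n_radial = n_radial, errors = errs,
       order = unname(stats::coef(fit)[2]))
}

#' Calibration scenario
#'
#' The synthetic stand-in for the published balloon calibration: 45-s
#' pressure ramp to 10 kPa held to 60 s on the default annulus
#' (coarsened to 8 x 16 with `dt = 0.5 s` inside the fitting loop for
#' speed), with the [calibration_bc()] boundary set.
#'
#' @param p_max Working pressure \[Pa\].
#' @param n_radial,n_circumferential Mesh resolution.
#' @param dt,t_end Time stepping \[s\].
#' @return List with `mesh`, `protocol`, `config`, `bc`.
#' @export
calibration_scenario <- function(p_max = 10e3, n_radial = 8,
                                 n_circumferential = 16, dt = 0.5,
                                 t_end = 60, t_rise = min(45, 0.75 * t_end)) {
  list(mesh = default_annulus(n_radial, n_circumferential),
       protocol = ccbd_protocol(p_max, t_end = t_end, t_rise = t_rise),
       config = solver_config(dt = dt, t_end = t_end,
                              newmark_beta = 0.390625, newmark_gamma = 0.75),
       bc = calibration_bc())
}
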