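# Material and solver-configuration containers.

#' Poroelastic material parameters
#'
#' Drained linear-elastic skeleton plus Darcy flow.  Defaults are the
#' calibrated cervical-tissue values `E = 0.15 MPa` and
#' `k = 3e-15 m^4/(N s)`; the remaining constants (Poisson ratio, densities,
#' porosity, fluid compressibility) are not tissue-specific measurements but
#' standard water-saturated soft-tissue values, all configurable.
#'
#' @param E Drained Young's modulus \[Pa\].
#' @param nu Drained Poisson ratio, `0 <= nu < 0.5`.
#' @param k_perm Darcy permeability coefficient \[m^2/(Pa s)\], i.e. the
#'   constant in `q = -k_perm * grad(p)` (equivalently m^4/(N s)).
#' @param rho_solid,rho_fluid Phase densities \[kg/m^3\].
#' @param porosity Fluid volume fraction, in (0, 1).  Cervical stroma is
#'   roughly 80--85 percent water-rich extracellular matrix, hence the
#'   0.8 default.
#' @param fluid_compressibility Pore-fluid compressibility \[1/Pa\]
#'   (water: 4.5e-10).
#' @return An object of class `biot_material`.
#' @export
material <- function(E = 0.15e6, nu = 0.3, k_perm = 3e-15,
                     rho_solid = 1000, rho_fluid = 1000,
                     porosity = 0.8, fluid_compressibility = 4.5e-10) {
  if (!is.numeric(E) || E <= 0) stop_config("material: E must be > 0")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop_config("material: nu must satisfy 0 <= nu < 0.5 (got %g)", nu)
  if (!is.numeric(k_perm) || k_perm <= 0)
    stop_config("material: k_perm must be > 0")
  if (rho_solid <= 0 || rho_fluid <= 0)
    stop_config("material: densities must be > 0")
  if (porosity <= 0 || porosity >= 1)
    stop_config("material: porosity must be in (0, 1)")
  if (fluid_compressibility < 0)
    stop_config("material: fluid_compressibility must be >= 0")
  structure(list(E = E, nu = nu, k_perm = k_perm,
                 rho_solid = rho_solid, rho_fluid = rho_fluid,
                 porosity = porosity,
                 fluid_compressibility = fluid_compressibility),
            class = "biot_material")
}

#' @export
print.biot_material <- function(x, ...) {
  cat(sprintf(paste0("biot_material: E = %g Pa, nu = %g, k = %g m^2/(Pa s)\n",
                     "  rho_s = %g, rho_f = %g kg/m^3, porosity = %g, ",
                     "c_f = %g 1/Pa\n"),
              x$E, x$nu, x$k_perm, x$rho_solid, x$rho_fluid,
              x$porosity, x$fluid_compressibility))
  invisible(x)
}

# Plane-strain drained elasticity matrix (Voigt order xx, yy, xy with
# engineering shear), and derived moduli.
elastic_constants <- function(mat) {
  E <- mat$E; nu <- mat$nu
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(c(lambda + 2 * mu, lambda, 0,
                lambda, lambda + 2 * mu, 0,
                0, 0, mu), 3, 3)
  list(mu = mu, lambda = lambda, D = D,
       M_confined = E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)),
       storage = mat$porosity * mat$fluid_compressibility,
       rho_mix = (1 - mat$porosity) * mat$rho_solid +
         mat$porosity * mat$rho_fluid)
}

#' Time-integration settings for the Newmark scheme
#'
#' The defaults mirror the dilation simulations: `dt = 0.1 s` over one
#' minute.  `beta = 1/4`, `gamma = 1/2` is the non-dissipative trapezoidal
#' member; `gamma > 1/2` (with `beta >= (gamma + 1/2)^2 / 4`) adds numerical
#' high-frequency dissipation, which the step-loaded benchmark
#' configurations use to remove unresolved wave transients.
#'
#' @param dt Time step \[s\].
#' @param t_end Simulated duration \[s\].
#' @param newmark_beta,newmark_gamma Newmark parameters; unconditional
#'   stability requires `2 * beta >= gamma >= 1/2`.
#' @param linear_tolerance Relative residual required of each linear solve.
#' @param n_gauss Quadrature order per direction for element integrals.
#' @param pressure_stabilization Coefficient of an optional
#'   Brezzi-Pitkaranta-type pressure Laplacian (scaled by h^2/mu) added to
#'   the continuity equation; 0 (default) disables it.
#' @param startup_substeps Subdivide the first time step into this many
#'   implicit substeps (default 1 = off).  Step loads applied at `t = 0+`
#'   are otherwise smeared over the first step, which shifts the early
#'   consolidation response by a fraction of `dt`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.1, t_end = 60,
                          newmark_beta = 0.25, newmark_gamma = 0.5,
                          linear_tolerance = 1e-9, n_gauss = 2,
                          pressure_stabilization = 0,
                          startup_substeps = 1L) {
  if (dt <= 0) stop_config("solver_config: dt must be > 0")
  if (t_end < dt) stop_config("solver_config: t_end must be >= dt")
  if (!(2 * newmark_beta >= newmark_gamma && newmark_gamma >= 0.5))
    stop_config(
      "solver_config: need 2*beta >= gamma >= 1/2 (got beta=%g, gamma=%g)",
      newmark_beta, newmark_gamma)
  if (linear_tolerance <= 0)
    stop_config("solver_config: linear_tolerance must be > 0")
  if (pressure_stabilization < 0)
    stop_config("solver_config: pressure_stabilization must be >= 0")
  if (startup_substeps < 1)
    stop_config("solver_config: startup_substeps must be >= 1")
  structure(list(dt = dt, t_end = t_end, newmark_beta = newmark_beta,
                 newmark_gamma = newmark_gamma,
                 linear_tolerance = linear_tolerance,
                 n_gauss = n_gauss,
                 pressure_stabilization = pressure_stabilization,
                 startup_substeps = as.integer(startup_substeps)),
            class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf(
    "solver_config: dt = %g s, t_end = %g s, beta = %g, gamma = %g\n",
    x$dt, x$t_end, x$newmark_beta, x$newmark_gamma))
  invisible(x)
}
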