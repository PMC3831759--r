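# Implicit Newmark time integration of the assembled system.
#
# The incremental unknowns are (Du, Dp, Dq).  Displacements follow the full
# Newmark relations; the first-order fields p and q follow the matching
# generalised trapezoidal rule with the same gamma.  With constant matrices
# the effective matrix is factorised once and reused at every step; each
# solve is polished by iterative refinement until the relative residual is
# below `linear_tolerance`.

newmark_coeffs <- function(config) {
  dt <- config$dt; beta <- config$newmark_beta; gamma <- config$newmark_gamma
  list(dt = dt,
       a0 = 1 / (beta * dt^2), a2 = 1 / (beta * dt), a3 = 1 / (2 * beta) - 1,
       gb = gamma / (beta * dt), c4 = 1 - gamma / beta,
       c5 = dt * (1 - gamma / (2 * beta)),
       ag = 1 / (gamma * dt), d1 = 1 / gamma - 1)
}

#' Zero initial state for a constrained system
#'
#' @param csys A `biot_csys`.
#' @return A list of class `biot_state` with full-length vectors `x`
#'   (displacements, pressures, Darcy velocities), `v` (their rates),
#'   `acc` (solid accelerations, u slots only) and `time`.
#' @export
init_state <- function(csys) {
  n <- csys$layout$n_dof
  structure(list(x = numeric(n), v = numeric(n), acc = numeric(n), time = 0),
            class = "biot_state")
}

# Extract per-field views of a state vector.
state_fields <- function(x, lay) {
  list(u = matrix(x[lay$u], ncol = 2, byrow = TRUE),
       p = x[lay$p],
       q = matrix(x[lay$q], ncol = 2, byrow = TRUE))
}

#' Prepare the reusable Newmark stepper
#'
#' Forms the effective matrix `a0*M + C*Ds + K` in the transformed frame,
#' eliminates constrained dofs, equilibrates and factorises it.
#'
#' @param csys A `biot_csys` from [apply_boundary_conditions()].
#' @param config A [solver_config()].
#' @return An environment used by [newmark_step()].
#' @export
prepare_stepper <- function(csys, config) {
  nm <- newmark_coeffs(config)
  lay <- csys$layout
  ds <- numeric(lay$n_dof)
  ds[lay$u] <- nm$gb
  ds[c(lay$p, lay$q)] <- nm$ag
  A <- nm$a0 * csys$M + csys$C %*% Matrix::Diagonal(x = ds) + csys$K
  Tm <- csys$Tmat
  At <- Tm %*% A %*% Matrix::t(Tm)
  free <- csys$free; fixed <- csys$fixed
  Aff <- At[free, free, drop = FALSE]
  Afc <- if (length(fixed)) At[free, fixed, drop = FALSE] else NULL

  # two-sided equilibration guards the factorisation against the very
  # different natural scales of the u, p and q equations
  rs <- 1 / sparse_margin_absmax(Aff, 1)
  As <- Matrix::Diagonal(x = rs) %*% Aff
  cs <- 1 / sparse_margin_absmax(As, 2)
  As <- As %*% Matrix::Diagonal(x = cs)
  fac <- tryCatch(Matrix::lu(As), error = function(e)
    stop_solver("singular effective matrix: %s", conditionMessage(e)))

  env <- new.env(parent = emptyenv())
  env$nm <- nm; env$csys <- csys; env$config <- config
  env$ds <- ds; env$Aff <- Aff; env$Afc <- Afc
  env$rs <- rs; env$cs <- cs; env$fac <- fac
  env$normA <- max(Matrix::rowSums(abs(Aff)))
  env
}

# Direct solve with iterative refinement; accepted when the normwise
# backward error ||r|| / (||A|| ||y|| + ||b||) reaches linear_tolerance.
solve_free <- function(st, rhs) {
  y <- st$cs * Matrix::solve(st$fac, st$rs * rhs)
  nb <- sqrt(sum(rhs^2))
  if (nb == 0) return(as.numeric(y))
  rel <- Inf
  for (it in 1:4) {
    res <- rhs - as.numeric(st$Aff %*% y)
    rel <- sqrt(sum(res^2)) / (st$normA * sqrt(sum(y^2)) + nb)
    if (!is.finite(rel))
      stop_solver("divergent linear residual (non-finite)")
    if (rel <= st$config$linear_tolerance) return(as.numeric(y))
    y <- y + st$cs * Matrix::solve(st$fac, st$rs * res)
  }
  if (rel > st$config$linear_tolerance)
    stop_solver(paste0("linear solve did not reach tolerance %g ",
                       "(backward error %g); ill-conditioned system"),
                st$config$linear_tolerance, rel)
  as.numeric(y)
}

#' Advance the state by one Newmark step
#'
#' Solves the incremental linear system for (Du, Dp, Dq) so that the
#' balance equations hold at `t + dt`, then updates the rates and solid
#' accelerations from the Newmark relations.
#'
#' @param state A `biot_state`.
#' @param stepper From [prepare_stepper()].
#' @param t1 Target time `t + dt`.
#' @return The state at `t1`.
#' @export
newmark_step <- function(state, stepper, t1) {
  st <- stepper; nm <- st$nm; csys <- st$csys; lay <- csys$layout
  x <- state$x; v <- state$v; acc <- state$acc

  g <- numeric(lay$n_dof)
  g[lay$u] <- nm$c4 * v[lay$u] + nm$c5 * acc[lay$u]
  pq <- c(lay$p, lay$q)
  g[pq] <- -nm$d1 * v[pq]
  h <- numeric(lay$n_dof)
  h[lay$u] <- nm$a2 * v[lay$u] + nm$a3 * acc[lay$u]

  b <- csys$load_fun(t1) - as.numeric(csys$K %*% x) +
    as.numeric(csys$M %*% h) - as.numeric(csys$C %*% g)
  bt <- as.numeric(csys$Tmat %*% b)

  dy <- numeric(lay$n_dof)
  if (length(csys$fixed)) {
    ycur <- as.numeric(csys$Tmat %*% x)[csys$fixed]
    dyc <- csys$fixed_value_fun(t1) - ycur
    rhs <- bt[csys$free] -
      (if (is.null(st$Afc)) 0 else as.numeric(st$Afc %*% dyc))
    dy[csys$fixed] <- dyc
  } else {
    rhs <- bt[csys$free]
  }
  dy[csys$free] <- solve_free(st, rhs)
  dx <- as.numeric(Matrix::t(csys$Tmat) %*% dy)

  x1 <- x + dx
  v1 <- st$ds * dx + g
  acc1 <- numeric(lay$n_dof)
  acc1[lay$u] <- nm$a0 * dx[lay$u] - nm$a2 * v[lay$u] - nm$a3 * acc[lay$u]
  structure(list(x = x1, v = v1, acc = acc1, time = t1),
            class = "biot_state")
}

#' Run a full poroelastic simulation
#'
#' Assembles the system, applies boundary conditions, and time-marches from
#' (by default) an undeformed, unpressurised initial state, recording the
#' nodal fields at every `stride`-th step.  Deterministic given its inputs.
#'
#' @param mesh A `biot_mesh`.
#' @param mat A [material()].
#' @param protocol A `loading_protocol` defined on `[0, t_end]`.
#' @param config A [solver_config()].
#' @param bc A [bc_spec()]; defaults to [default_bc()] for the mesh type.
#' @param initial_state Optional starting `biot_state`.
#' @param stride Record every `stride`-th step (the final step is always
#'   recorded).  1 records all 601 steps of the default one-minute run.
#' @param record_rates Also record the rate vectors (needed for the
#'   discrete mass-balance audit).
#' @return A `biot_result`: recorded times, field matrices `X` (and `V`),
#'   and the constrained system for post-processing.
#' @export
run_simulation <- function(mesh, mat, protocol, config = solver_config(),
                           bc = NULL, initial_state = NULL, stride = 1L,
                           record_rates = TRUE) {
  if (is.null(bc)) bc <- default_bc(mesh)
  sys <- assemble_system(mesh, mat, config)
  csys <- apply_boundary_conditions(sys, bc, protocol)
  stepper <- prepare_stepper(csys, config)

  n_steps <- max(1L, as.integer(round(config$t_end / config$dt)))
  rec <- sort(unique(c(0L, seq(0L, n_steps, by = as.integer(stride)), n_steps)))
  n_rec <- length(rec)
  X <- matrix(0, csys$layout$n_dof, n_rec)
  V <- if (record_rates) matrix(0, csys$layout$n_dof, n_rec) else NULL
  times <- rec * config$dt

  state <- initial_state %||% init_state(csys)
  ri <- 1L
  if (rec[1L] == 0L) {
    X[, 1L] <- state$x
    if (record_rates) V[, 1L] <- state$v
    ri <- 2L
  }
  sub_stepper <- NULL
  if ((config$startup_substeps %||% 1L) > 1L) {
    sub_cfg <- config
    sub_cfg$dt <- config$dt / config$startup_substeps
    sub_stepper <- prepare_stepper(csys, sub_cfg)
  }
  for (s in seq_len(n_steps)) {
    t1 <- s * config$dt
    state <- tryCatch({
      if (s == 1L && !is.null(sub_stepper)) {
        for (ss in seq_len(config$startup_substeps))
          state <- newmark_step(state, sub_stepper,
                                ss * config$dt / config$startup_substeps)
        state
      } else newmark_step(state, stepper, t1)
    }, error = function(e)
      stop_solver("failure at time step %d (t = %g s): %s",
                  s, t1, conditionMessage(e)))
    if (ri <= n_rec && rec[ri] == s) {
      X[, ri] <- state$x
      if (record_rates) V[, ri] <- state$v
      ri <- ri + 1L
    }
  }

  meta <- list(protocol_label = protocol$label %||% protocol$kind,
               config_digest = config_digest(unclass(config)))
  structure(list(mesh = mesh, material = mat, protocol = protocol,
                 config = config, bc = bc, time = times, X = X, V = V,
                 csys = csys, meta = meta),
            class = "biot_result")
}

#' @export
print.biot_result <- function(x, ...) {
  cat(sprintf(
    "biot_result: '%s', %d recorded steps over %g s, %d nodes\n",
    x$meta$protocol_label, length(x$time), max(x$time), x$csys$layout$n_nodes))
  invisible(x)
}

#' Extract a nodal field at a recorded step
#'
#' @param result A `biot_result`.
#' @param field One of `"u"`, `"p"`, `"q"` (or `"u_rate"`, `"p_rate"`).
#' @param step Recorded step index (1-based).
#' @return A vector (`p`) or an N x 2 matrix (`u`, `q`).
#' @export
result_field <- function(result, field = c("u", "p", "q", "u_rate", "p_rate"),
                         step) {
  field <- match.arg(field)
  lay <- result$csys$layout
  src <- if (field %in% c("u_rate", "p_rate")) {
    if (is.null(result$V)) stop("rates were not recorded", call. = FALSE)
    result$V
  } else result$X
  col <- src[, step]
  switch(sub("_rate", "", field),
         u = matrix(col[lay$u], ncol = 2, byrow = TRUE),
         p = col[lay$p],
         q = matrix(col[lay$q], ncol = 2, byrow = TRUE))
}

#' Mean radial opening of the inner surface over time
#'
#' The calibration observable: mean outward radial displacement of the
#' inner-surface nodes (a proxy for balloon volume) at each recorded step.
#'
#' @param result A `biot_result` on an annulus mesh.
#' @return Numeric vector, one entry per recorded step \[m\].
#' @export
inner_opening <- function(result) {
  b <- result$mesh$boundary$inner_surface
  if (is.null(b)) stop("mesh has no inner_surface set", call. = FALSE)
  lay <- result$csys$layout
  outward <- -b$normals               # stored normals point out of the domain
  ux <- result$X[2L * b$nodes - 1L, , drop = FALSE]
  uy <- result$X[2L * b$nodes, , drop = FALSE]
  as.numeric(colMeans(ux * outward[, 1] + uy * outward[, 2]))
}

#' Discrete fluid mass-balance audit
#'
#' At every recorded step, integrates the continuity density
#' `div(u_rate) + storage * p_rate + div(q)` over the domain by the same
#' quadrature used in assembly, and compares it with the consistent
#' drainage flux recovered from the constrained pressure rows (the
#' discrete analogue of the net boundary flux).  For a converged implicit
#' step the two agree to the linear-solver accuracy.
#'
#' @param result A `biot_result` recorded with `record_rates = TRUE`.
#' @return A data frame with columns `time`, `volume_integral`,
#'   `boundary_flux` and `residual` (their difference).
#' @export
mass_balance <- function(result) {
  if (is.null(result$V))
    stop("mass_balance needs a result recorded with record_rates = TRUE",
         call. = FALSE)
  csys <- result$csys; lay <- csys$layout
  pd <- lay$p
  fixed_p <- csys$fixed_p
  out <- data.frame(time = result$time, volume_integral = NA_real_,
                    boundary_flux = NA_real_, residual = NA_real_)
  Cp <- csys$C[pd, , drop = FALSE]
  Kp <- csys$K[pd, , drop = FALSE]
  con <- match(fixed_p, pd)
  for (i in seq_along(result$time)) {
    rp <- as.numeric(Cp %*% result$V[, i]) + as.numeric(Kp %*% result$X[, i])
    A <- sum(rp)
    B <- if (length(con)) sum(rp[con]) else 0
    out$volume_integral[i] <- A
    out$boundary_flux[i] <- B
    out$residual[i] <- A - B
  }
  out
}

#' Static drained elasticity solution
#'
#' Direct solve of the drained stiffness block `K_uu u = f` under the
#' displacement constraints of the boundary specification; the long-time
#' limit the transient solver must approach under a constant load when the
#' pore fluid has fully drained.
#'
#' @param mesh,mat,bc,config As in [run_simulation()].
#' @param pressure Applied surface pressure \[Pa\] on the `bc$pressure` set.
#' @return N x 2 matrix of nodal displacements.
#' @export
static_drained_solve <- function(mesh, mat, bc = default_bc(mesh),
                                 pressure = 1, config = solver_config()) {
  sys <- assemble_system(mesh, mat, config)
  csys <- apply_boundary_conditions(sys, bc,
                                    make_protocol("step", p_max = pressure,
                                                  t_end = 1))
  lay <- csys$layout
  Tm <- csys$Tmat
  Kt <- Tm %*% csys$K %*% Matrix::t(Tm)
  ufree <- setdiff(lay$u, csys$fixed)
  Kuu <- Kt[ufree, ufree, drop = FALSE]
  b <- as.numeric(Tm %*% (pressure * csys$f_unit))[ufree]
  y <- numeric(lay$n_dof)
  y[ufree] <- as.numeric(Matrix::solve(Kuu, b))
  x <- as.numeric(Matrix::t(Tm) %*% y)
  matrix(x[lay$u], ncol = 2, byrow = TRUE)
}
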