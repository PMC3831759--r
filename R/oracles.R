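# Closed-form reference solutions used as independent verification oracles
# for the finite-element core.  None of these call the element or assembly
# code.

#' Terzaghi consolidation setup
#'
#' Single-drained column under a step load: consolidation coefficient
#' `cv = k_perm * M` with confined modulus
#' `M = E (1 - nu) / ((1 + nu)(1 - 2 nu))`.
#'
#' @param sigma0 Applied step load \[Pa\].
#' @param height Drainage path length \[m\].
#' @param mat Optional [material()] from which `cv` is derived.
#' @param cv Consolidation coefficient \[m^2/s\]; overrides `mat`.
#' @param series_terms Number of Fourier terms (default 200).
#' @return An object of class `consolidation_setup`.
#' @export
consolidation_setup <- function(sigma0, height, mat = NULL, cv = NULL,
                                series_terms = 200) {
  if (height <= 0) stop_config("consolidation_setup: height must be > 0")
  if (series_terms < 1) stop_config("series_terms must be >= 1")
  if (is.null(cv)) {
    if (is.null(mat)) stop_config("supply either cv or a material")
    cv <- mat$k_perm * elastic_constants(mat)$M_confined
  }
  if (cv <= 0) stop_config("consolidation_setup: cv must be > 0")
  structure(list(sigma0 = sigma0, height = height, cv = cv,
                 series_terms = as.integer(series_terms)),
            class = "consolidation_setup")
}

#' Terzaghi pore-pressure series
#'
#' Classical single-drained consolidation solution
#' `p(z, t) = sigma0 * sum 2/M_m sin(M_m z/H) exp(-M_m^2 T)` with
#' `M_m = pi (2m + 1)/2` and `T = cv t / H^2`.  `z` is the depth below the
#' drained surface; the base `z = H` is impermeable.
#'
#' @param setup A [consolidation_setup()].
#' @param z Depths \[m\], `0 <= z <= height`.
#' @param t Time \[s\] (scalar), `t >= 0`.
#' @return Pore pressures \[Pa\] at the depths `z`.
#' @export
terzaghi_pressure <- function(setup, z, t) {
  stopifnot(inherits(setup, "consolidation_setup"))
  if (any(t < 0)) stop("terzaghi_pressure: t must be >= 0", call. = FALSE)
  if (any(z < 0 | z > setup$height))
    stop("terzaghi_pressure: z outside [0, height]", call. = FALSE)
  if (length(t) != 1L) stop("t must be a scalar", call. = FALSE)
  Tv <- setup$cv * t / setup$height^2
  m <- 0:(setup$series_terms - 1L)
  Mm <- pi / 2 * (2 * m + 1)
  # outer(z-term, mode): sum over modes
  S <- sin(outer(z / setup$height, Mm)) %*% (2 / Mm * exp(-Mm^2 * Tv))
  as.numeric(setup$sigma0 * S)
}

#' Average degree of consolidation
#'
#' `U(T) = 1 - sum 2/M_m^2 exp(-M_m^2 T)`; `U = 0.5` at the classical
#' dimensionless time `T ~ 0.197`.
#'
#' @param setup A [consolidation_setup()].
#' @param Tv Dimensionless time factor(s) `cv t / H^2`.
#' @return Average consolidation degree in `[0, 1]`.
#' @export
terzaghi_degree <- function(setup, Tv) {
  m <- 0:(setup$series_terms - 1L)
  Mm <- pi / 2 * (2 * m + 1)
  vapply(Tv, function(tv) 1 - sum(2 / Mm^2 * exp(-Mm^2 * tv)), numeric(1))
}

#' Plane-strain Lame solution for a pressurised thick-walled cylinder
#'
#' Displacement and stress field `u = A r + B/r` for internal pressure
#' `p_inner`, with either a traction-free (`outer = "free"`) or a fixed
#' (`outer = "fixed"`, `u(r_outer) = 0`) outer surface.
#'
#' @param p_inner Internal pressure \[Pa\].
#' @param r_inner,r_outer Wall radii \[m\].
#' @param E,nu Drained elastic constants.
#' @param r Radii at which to evaluate (must lie inside the wall).
#' @param outer `"free"` or `"fixed"`.
#' @return Data frame with `r`, `u_r` \[m\], `sigma_r`, `sigma_theta` \[Pa\]
#'   (tension positive).
#' @export
lame_thick_cylinder <- function(p_inner, r_inner, r_outer, E, nu, r,
                                outer = c("free", "fixed")) {
  outer <- match.arg(outer)
  if (r_inner <= 0 || r_outer <= r_inner)
    stop_config("lame: need 0 < r_inner < r_outer")
  if (any(r < r_inner - 1e-12 * r_outer | r > r_outer + 1e-12 * r_outer))
    stop("lame: r outside the cylinder wall", call. = FALSE)
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  # sigma_r = 2(lam + mu) A - 2 mu B / r^2 ; sigma_th = 2(lam + mu) A + 2 mu B / r^2
  if (outer == "free") {
    # sigma_r(r_i) = -p, sigma_r(r_o) = 0
    lhs <- rbind(c(2 * (lam + mu), -2 * mu / r_inner^2),
                 c(2 * (lam + mu), -2 * mu / r_outer^2))
    rhs <- c(-p_inner, 0)
  } else {
    # sigma_r(r_i) = -p, u(r_o) = 0
    lhs <- rbind(c(2 * (lam + mu), -2 * mu / r_inner^2),
                 c(r_outer, 1 / r_outer))
    rhs <- c(-p_inner, 0)
  }
  AB <- solve(lhs, rhs)
  data.frame(r = r,
             u_r = AB[1] * r + AB[2] / r,
             sigma_r = 2 * (lam + mu) * AB[1] - 2 * mu * AB[2] / r^2,
             sigma_theta = 2 * (lam + mu) * AB[1] + 2 * mu * AB[2] / r^2)
}

#' Single-degree-of-freedom Newmark reference recursion
#'
#' Exact Newmark update for `m u'' + k u = f(t)`, used to cross-check the
#' assembled integrator and to document the scheme's dispersion and
#' algorithmic-damping behaviour.
#'
#' @param mass,stiffness Positive scalars.
#' @param dt Time step \[s\].
#' @param n_steps Number of steps (>= 1).
#' @param beta,gamma Newmark parameters.
#' @param u0,v0 Initial displacement and velocity.
#' @param load_fun Optional `function(t)` giving the load (default 0).
#' @return Data frame with `time`, `u`, `v`, `a`.
#' @export
sdof_newmark_reference <- function(mass, stiffness, dt, n_steps,
                                   beta = 0.25, gamma = 0.5,
                                   u0 = 0, v0 = 0, load_fun = NULL) {
  if (mass <= 0 || stiffness <= 0)
    stop_config("sdof: mass and stiffness must be > 0")
  if (n_steps < 1) stop_config("sdof: n_steps must be >= 1")
  f <- load_fun %||% function(t) 0
  u <- numeric(n_steps + 1L); v <- numeric(n_steps + 1L)
  a <- numeric(n_steps + 1L)
  u[1] <- u0; v[1] <- v0; a[1] <- (f(0) - stiffness * u0) / mass
  for (i in seq_len(n_steps)) {
    t1 <- i * dt
    # predictors
    us <- u[i] + dt * v[i] + dt^2 / 2 * (1 - 2 * beta) * a[i]
    vs <- v[i] + dt * (1 - gamma) * a[i]
    a1 <- (f(t1) - stiffness * us) / (mass + stiffness * beta * dt^2)
    u[i + 1] <- us + beta * dt^2 * a1
    v[i + 1] <- vs + gamma * dt * a1
    a[i + 1] <- a1
  }
  data.frame(time = dt * (0:n_steps), u = u, v = v, a = a)
}

#' Brute-force element-matrix oracle
#'
#' Independent re-computation of every block of [element_matrices()] by
#' explicit scalar loops over shape-function pairs, with Gauss-Legendre
#' points from `pracma::gaussLegendre` (4 x 4 by default).  Shares no code
#' with the production implementation.
#'
#' @param coords 4 x 2 matrix of node coordinates.
#' @param mat A [material()].
#' @param n_gauss Quadrature order per direction.
#' @return A list with the same block names as [element_matrices()].
#' @export
element_matrices_bruteforce <- function(coords, mat, n_gauss = 4) {
  gl <- pracma::gaussLegendre(n_gauss, -1, 1)
  xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
  Nfun <- function(i, xi, eta) 0.25 * (1 + xi * xs[i]) * (1 + eta * es[i])
  dNfun <- function(i, xi, eta)
    c(0.25 * xs[i] * (1 + eta * es[i]), 0.25 * es[i] * (1 + xi * xs[i]))

  E <- mat$E; nu <- mat$nu
  mu <- E / (2 * (1 + nu)); lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  rho_mix <- (1 - mat$porosity) * mat$rho_solid + mat$porosity * mat$rho_fluid
  s_stor <- mat$porosity * mat$fluid_compressibility

  zero8 <- matrix(0, 8, 8)
  out <- list(m_uu = zero8, m_qu = zero8, c_uq = zero8, c_pu = matrix(0, 4, 8),
              c_pp = matrix(0, 4, 4), c_qq = zero8, k_uu = zero8,
              k_up = matrix(0, 8, 4), k_pq = matrix(0, 4, 8),
              k_qp = matrix(0, 8, 4), k_qq = zero8,
              k_pp_stab = matrix(0, 4, 4), area = 0)

  for (a in seq_len(n_gauss)) for (b in seq_len(n_gauss)) {
    xi <- gl$x[a]; eta <- gl$x[b]; wq <- gl$w[a] * gl$w[b]
    J <- matrix(0, 2, 2)
    for (i in 1:4) {
      d <- dNfun(i, xi, eta)
      J[1, ] <- J[1, ] + d[1] * coords[i, ]
      J[2, ] <- J[2, ] + d[2] * coords[i, ]
    }
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (detJ <= 0) stop_config("bruteforce oracle: degenerate element")
    # maps (dN/dxi, dN/deta) to (dN/dx, dN/dy): inverse-transpose of J
    JinvT <- matrix(c(J[2, 2], -J[1, 2], -J[2, 1], J[1, 1]), 2, 2) / detJ
    w <- wq * detJ
    out$area <- out$area + w
    Nv <- vapply(1:4, Nfun, numeric(1), xi = xi, eta = eta)
    dX <- t(vapply(1:4, function(i) as.numeric(dNfun(i, xi, eta) %*% JinvT),
                   numeric(2)))      # 4 x 2: dN_i/dx, dN_i/dy

    for (i in 1:4) for (j in 1:4) {
      nn <- Nv[i] * Nv[j]
      for (d in 1:2) {
        r <- 2 * (i - 1) + d; cdof <- 2 * (j - 1) + d
        out$m_uu[r, cdof] <- out$m_uu[r, cdof] + w * rho_mix * nn
        out$m_qu[r, cdof] <- out$m_qu[r, cdof] + w * mat$rho_fluid * nn
        out$c_uq[r, cdof] <- out$c_uq[r, cdof] + w * mat$rho_fluid * nn
        out$c_qq[r, cdof] <- out$c_qq[r, cdof] +
          w * mat$rho_fluid / mat$porosity * nn
        out$k_qq[r, cdof] <- out$k_qq[r, cdof] + w / mat$k_perm * nn
      }
      # drained stiffness: k_uu[(i,d),(j,e)] = int B_i' D B_j
      dxi <- dX[i, 1]; dyi <- dX[i, 2]; dxj <- dX[j, 1]; dyj <- dX[j, 2]
      kij <- matrix(c(
        (lam + 2 * mu) * dxi * dxj + mu * dyi * dyj,
        lam * dxi * dyj + mu * dyi * dxj,
        lam * dyi * dxj + mu * dxi * dyj,
        (lam + 2 * mu) * dyi * dyj + mu * dxi * dxj), 2, 2, byrow = TRUE)
      out$k_uu[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <-
        out$k_uu[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] + w * kij
      # volumetric coupling and divergence/gradient blocks
      for (d in 1:2) {
        out$c_pu[i, 2 * (j - 1) + d] <- out$c_pu[i, 2 * (j - 1) + d] +
          w * Nv[i] * dX[j, d]
        out$k_up[2 * (j - 1) + d, i] <- out$k_up[2 * (j - 1) + d, i] -
          w * Nv[i] * dX[j, d]
        out$k_pq[i, 2 * (j - 1) + d] <- out$k_pq[i, 2 * (j - 1) + d] +
          w * Nv[i] * dX[j, d]
        out$k_qp[2 * (i - 1) + d, j] <- out$k_qp[2 * (i - 1) + d, j] +
          w * Nv[i] * dX[j, d]
      }
      out$c_pp[i, j] <- out$c_pp[i, j] + w * s_stor * nn
      out$k_pp_stab[i, j] <- out$k_pp_stab[i, j] +
        w * (dX[i, 1] * dX[j, 1] + dX[i, 2] * dX[j, 2])
    }
  }
  out
}
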