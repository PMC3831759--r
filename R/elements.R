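# Element-level construction of the coupled dynamic poroelastic system.
#
# Unknowns per node: solid displacement u (2), pore pressure p (1), Darcy
# velocity q (2).  The three coupled balance equations, discretised with
# equal-order bilinear interpolation on quadrilaterals, produce the block
# system (per element)
#
#   [ m_uu  0  0 ] [u..]   [ 0    0    c_uq ] [u.]   [ k_uu k_up  0   ] [Du]
#   [ 0     0  0 ] [p..] + [ c_pu c_pp 0    ] [p.] + [ 0    0    k_pq ] [Dp]
#   [ m_qu  0  0 ] [q..]   [ 0    0    c_qq ] [q.]   [ 0    k_qp k_qq ] [Dq]
#        = [f_u; f_p; f_q]
#
# Row u: momentum of the mixture (total stress = effective - p*I, pore
#        pressure positive in compression), with relative-fluid inertia c_uq.
# Row p: fluid mass balance  div(u.) + n*c_f*p. + div(q) = 0, kept in
#        divergence form (no integration by parts), so flux boundary
#        conditions are essential conditions on q.
# Row q: generalised Darcy law  rho_f*u.. + (rho_f/n)*q. + grad(p)
#        + (1/k)*q = 0, again pointwise-weighted, so pressure boundary
#        conditions are essential conditions on p.

# Bilinear shape functions on the reference square [-1,1]^2.
# Returns N (length 4) and dN (4 x 2, derivatives wrt xi and eta).
shape_q4 <- function(xi, eta) {
  xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
  N <- 0.25 * (1 + xi * xs) * (1 + eta * es)
  dN <- cbind(0.25 * xs * (1 + eta * es),
              0.25 * es * (1 + xi * xs))
  list(N = N, dN = dN)
}

#' Element matrices of the dynamic poroelastic system
#'
#' Evaluates every mass, damping and stiffness block of the coupled
#' u--p--q system on one bilinear quadrilateral by Gauss quadrature,
#' together with the (element-local) raw pressure-stabilization matrix.
#'
#' Sign conventions: pore pressure is positive in compression and the total
#' stress is the effective stress minus the pressure times identity, so
#' `k_up = -t(c_pu)` and the Darcy-resistance part of `k_qq` scales as
#' `1/k_perm`.
#'
#' @param coords 4 x 2 matrix of node coordinates, counter-clockwise.
#' @param mat A [material()].
#' @param n_gauss Quadrature order per direction (default 2).
#' @return A list of class `element_matrices` with dense blocks `m_uu`,
#'   `m_qu`, `c_uq`, `c_pu`, `c_pp`, `c_qq`, `k_uu`, `k_up`, `k_pq`,
#'   `k_qp`, `k_qq`, the unscaled stabilization block `k_pp_stab`
#'   (`integral of grad(Np) . grad(Np)`), and the element area.
#' @export
element_matrices <- function(coords, mat, n_gauss = 2) {
  if (!is.matrix(coords) || nrow(coords) != 4L || ncol(coords) != 2L)
    stop_config("element_matrices: coords must be a 4 x 2 matrix")
  if (!inherits(mat, "biot_material")) stop_config("invalid material object")
  ec <- elastic_constants(mat)
  g <- gauss_rule(n_gauss)

  m_uu <- matrix(0, 8, 8); c_uq <- matrix(0, 8, 8); m_qu <- matrix(0, 8, 8)
  c_qq <- matrix(0, 8, 8); k_qq <- matrix(0, 8, 8); k_uu <- matrix(0, 8, 8)
  k_up <- matrix(0, 8, 4); c_pu <- matrix(0, 4, 8); c_pp <- matrix(0, 4, 4)
  k_pq <- matrix(0, 4, 8); k_qp <- matrix(0, 8, 4); k_pp <- matrix(0, 4, 4)
  area <- 0
  mvec <- c(1, 1, 0)                       # volumetric operator (Voigt)

  for (a in seq_along(g$x)) for (b in seq_along(g$x)) {
    sh <- shape_q4(g$x[a], g$x[b])
    J <- t(sh$dN) %*% coords               # 2 x 2
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (detJ <= 0)
      stop_config("degenerate element: non-positive Jacobian (det = %g)", detJ)
    w <- g$w[a] * g$w[b] * detJ
    dNdx <- sh$dN %*% t(solve(J))          # 4 x 2, derivatives wrt x, y
    area <- area + w

    # 2 x 8 vector interpolation matrix, and 3 x 8 strain matrix
    Nmat <- matrix(0, 2, 8)
    Nmat[1, seq(1, 8, 2)] <- sh$N
    Nmat[2, seq(2, 8, 2)] <- sh$N
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx[, 1]
    B[2, seq(2, 8, 2)] <- dNdx[, 2]
    B[3, seq(1, 8, 2)] <- dNdx[, 2]
    B[3, seq(2, 8, 2)] <- dNdx[, 1]
    NN <- crossprod(Nmat)                  # t(Nmat) %*% Nmat, 8 x 8
    m_uu <- m_uu + w * ec$rho_mix * NN
    c_uq <- c_uq + w * mat$rho_fluid * NN
    m_qu <- m_qu + w * mat$rho_fluid * NN
    c_qq <- c_qq + w * (mat$rho_fluid / mat$porosity) * NN
    k_qq <- k_qq + w * (1 / mat$k_perm) * NN
    k_uu <- k_uu + w * crossprod(B, ec$D %*% B)

    vol_row <- as.vector(mvec %*% B)       # length 8: div of u-interp
    # c_pu[a, j] = int N_a * (div N)_j ; k_up = -t(c_pu)
    c_pu <- c_pu + w * (sh$N %o% vol_row)
    k_up <- k_up - w * (vol_row %o% sh$N)
    c_pp <- c_pp + w * ec$storage * (sh$N %o% sh$N)
    # divergence of the q interpolation (same vector structure as vol_row)
    k_pq <- k_pq + w * (sh$N %o% vol_row)
    # gradient of p interpolation: k_qp[(i,d), a] = int N_i dN_a/dx_d
    gradP <- matrix(0, 8, 4)
    gradP[seq(1, 8, 2), ] <- sh$N %o% dNdx[, 1]
    gradP[seq(2, 8, 2), ] <- sh$N %o% dNdx[, 2]
    k_qp <- k_qp + w * gradP
    k_pp <- k_pp + w * tcrossprod(dNdx)    # grad(Np).grad(Np)
  }

  structure(list(m_uu = m_uu, m_qu = m_qu, c_uq = c_uq, c_pu = c_pu,
                 c_pp = c_pp, c_qq = c_qq, k_uu = k_uu, k_up = k_up,
                 k_pq = k_pq, k_qp = k_qp, k_qq = k_qq, k_pp_stab = k_pp,
                 area = area),
            class = "element_matrices")
}
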