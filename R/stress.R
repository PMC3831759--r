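# Effective stress recovery and scalar invariants.

#' Von Mises invariant of a plane-strain stress state
#'
#' @param sxx,syy,szz,sxy Stress components \[Pa\] (vectors recycle).
#' @return `sqrt(((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2)/2 + 3 sxy^2)`.
#' @export
von_mises <- function(sxx, syy, szz = 0, sxy = 0) {
  sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) + 3 * sxy^2)
}

# Sparse operator evaluating centroid strains (Voigt xx, yy, xy rows per
# element) from the global u vector, plus centroid radii/pressure weights.
strain_operator <- function(mesh) {
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cent <- matrix(0, ne, 2)
  sh <- shape_q4(0, 0)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    xy <- mesh$nodes[en, , drop = FALSE]
    cent[e, ] <- colMeans(xy)
    J <- t(sh$dN) %*% xy
    dNdx <- sh$dN %*% t(solve(J))
    du <- dof_u(en, nn)
    base <- 3L * (e - 1L)
    # rows: exx (du_x/dx), eyy (du_y/dy), gamma_xy
    ii <- c(ii, rep(base + 1L, 4), rep(base + 2L, 4), rep(base + 3L, 8))
    jj <- c(jj, du[seq(1, 8, 2)], du[seq(2, 8, 2)], du)
    xx <- c(xx, dNdx[, 1], dNdx[, 2],
            as.vector(rbind(dNdx[, 2], dNdx[, 1])))
  }
  list(G = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(3L * ne, 5L * nn)),
       centroids = cent)
}

#' Effective stress and von Mises fields
#'
#' Computes element-centroid strains from the recorded displacement
#' history, the drained constitutive (effective) stress including the
#' plane-strain out-of-plane component, the centroid pore pressure, and
#' the von Mises invariant of the effective tensor.  Total stress follows
#' as `effective - p * I` under the compression-positive pressure
#' convention.
#'
#' @param result A `biot_result`.
#' @param mat A [material()] (defaults to the one stored in the result).
#' @return A list of class `biot_stress`: `time`, element `centroids`,
#'   arrays `sxx`, `syy`, `szz`, `sxy` and `von_mises`
#'   (elements x recorded steps), and centroid pressures `p`.
#' @export
effective_stress <- function(result, mat = result$material) {
  if (is.null(result$X)) stop("result carries no recorded fields",
                              call. = FALSE)
  ec <- elastic_constants(mat)
  op <- strain_operator(result$mesh)
  ne <- nrow(result$mesh$elements)
  Ue <- as.matrix(op$G %*% result$X)      # 3*ne x n_steps
  exx <- Ue[seq(1, 3 * ne, 3), , drop = FALSE]
  eyy <- Ue[seq(2, 3 * ne, 3), , drop = FALSE]
  gxy <- Ue[seq(3, 3 * ne, 3), , drop = FALSE]
  lam <- ec$lambda; mu <- ec$mu
  sxx <- (lam + 2 * mu) * exx + lam * eyy
  syy <- lam * exx + (lam + 2 * mu) * eyy
  szz <- lam * (exx + eyy)
  sxy <- mu * gxy
  vm <- von_mises(sxx, syy, szz, sxy)
  # centroid pore pressure: average of the four nodal values
  lay <- dof_layout(result$mesh)
  Pn <- result$X[lay$p, , drop = FALSE]
  pc <- matrix(0, ne, ncol(result$X))
  for (e in seq_len(ne))
    pc[e, ] <- colMeans(Pn[result$mesh$elements[e, ], , drop = FALSE])
  structure(list(time = result$time, centroids = op$centroids,
                 sxx = sxx, syy = syy, szz = szz, sxy = sxy,
                 von_mises = vm, p = pc),
            class = "biot_stress")
}

#' @export
print.biot_stress <- function(x, ...) {
  cat(sprintf("biot_stress: %d elements x %d steps, peak von Mises %g Pa\n",
              nrow(x$von_mises), ncol(x$von_mises), max(x$von_mises)))
  invisible(x)
}
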