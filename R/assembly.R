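# Global assembly of the coupled system.
#
# Global degree-of-freedom layout for a mesh with N nodes (5 dof/node):
#   u dofs : 1 .. 2N          (node i -> 2i-1, 2i)
#   p dofs : 2N+1 .. 3N       (node i -> 2N + i)
#   q dofs : 3N+1 .. 5N       (node i -> 3N + 2i-1, 3N + 2i)

dof_u <- function(nodes, n_nodes) as.vector(rbind(2L * nodes - 1L, 2L * nodes))
dof_p <- function(nodes, n_nodes) 2L * n_nodes + nodes
dof_q <- function(nodes, n_nodes)
  3L * n_nodes + as.vector(rbind(2L * nodes - 1L, 2L * nodes))

dof_layout <- function(mesh) {
  n <- nrow(mesh$nodes)
  list(n_nodes = n, n_dof = 5L * n,
       u = seq_len(2L * n), p = 2L * n + seq_len(n),
       q = 3L * n + seq_len(2L * n))
}

#' Assemble the global poroelastic system
#'
#' Sums the element blocks of [element_matrices()] into three global sparse
#' matrices over all 5N degrees of freedom: `M` (mass, acting on
#' accelerations), `C` (damping/coupling, acting on rates) and `K`
#' (stiffness, acting on increments).  The optional pressure-stabilization
#' term of the [solver_config()] is added to `K` in the (p, p) block with
#' coefficient `alpha * h_e^2 / mu` per element.
#'
#' @param mesh A `biot_mesh`.
#' @param mat A [material()].
#' @param config A [solver_config()] (quadrature order and stabilization).
#' @return A list of class `biot_system` with `M`, `C`, `K` (dgCMatrix),
#'   the dof layout, and references to mesh/material/config.
#' @export
assemble_system <- function(mesh, mat, config = solver_config()) {
  check_mesh(mesh)
  if (!inherits(mat, "biot_material")) stop_config("invalid material object")
  lay <- dof_layout(mesh)
  nn <- lay$n_nodes
  ne <- nrow(mesh$elements)
  mu <- elastic_constants(mat)$mu
  alpha <- config$pressure_stabilization

  # triplet accumulators
  ti <- list(); tj <- list(); tm <- list(); tc <- list(); tk <- list()
  push <- function(rows, cols, Mblk, Cblk, Kblk) {
    idx <- length(ti) + 1L
    ij <- expand.grid(r = rows, c = cols)
    ti[[idx]] <<- ij$r; tj[[idx]] <<- ij$c
    tm[[idx]] <<- if (is.null(Mblk)) numeric(length(ij$r)) else as.vector(Mblk)
    tc[[idx]] <<- if (is.null(Cblk)) numeric(length(ij$r)) else as.vector(Cblk)
    tk[[idx]] <<- if (is.null(Kblk)) numeric(length(ij$r)) else as.vector(Kblk)
  }

  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    em <- element_matrices(mesh$nodes[en, , drop = FALSE], mat,
                           n_gauss = config$n_gauss)
    du <- dof_u(en, nn); dp <- dof_p(en, nn); dq <- dof_q(en, nn)
    push(du, du, em$m_uu, NULL, em$k_uu)
    push(du, dq, NULL, em$c_uq, NULL)
    push(du, dp, NULL, NULL, em$k_up)
    push(dp, du, NULL, em$c_pu, NULL)
    push(dp, dp, NULL, em$c_pp,
         if (alpha > 0) alpha * em$area / mu * em$k_pp_stab else NULL)
    push(dp, dq, NULL, NULL, em$k_pq)
    push(dq, du, em$m_qu, NULL, NULL)
    push(dq, dq, NULL, em$c_qq, em$k_qq)
    push(dq, dp, NULL, NULL, em$k_qp)
  }

  i <- unlist(ti); j <- unlist(tj)
  dims <- c(lay$n_dof, lay$n_dof)
  M <- Matrix::sparseMatrix(i = i, j = j, x = unlist(tm), dims = dims)
  C <- Matrix::sparseMatrix(i = i, j = j, x = unlist(tc), dims = dims)
  K <- Matrix::sparseMatrix(i = i, j = j, x = unlist(tk), dims = dims)

  structure(list(M = M, C = C, K = K, layout = lay, mesh = mesh,
                 material = mat, config = config),
            class = "biot_system")
}

#' @export
print.biot_system <- function(x, ...) {
  cat(sprintf("biot_system: %d dofs (%d nodes x 5), %d elements\n",
              x$layout$n_dof, x$layout$n_nodes, nrow(x$mesh$elements)))
  invisible(x)
}
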