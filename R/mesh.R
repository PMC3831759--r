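# Structured finite-element meshes: half/full annulus cross-sections of the
# cervical canal, and a quad-strip consolidation column used for
# verification against the Terzaghi closed form.
#
# A mesh is a plain list of class "biot_mesh":
#   nodes     : N x 2 matrix of coordinates [m]
#   elements  : E x 4 integer matrix, counter-clockwise bilinear quads
#   boundary  : named list of boundary sets; each set has
#               $nodes   integer vector,
#               $edges   M x 2 integer matrix oriented with the domain on
#                        the LEFT of n1 -> n2 (so the outward unit normal
#                        of a straight edge is (t_y, -t_x)),
#               $normals N_set x 2 matrix of outward unit normals per node
#                        (analytic for circular surfaces).
# Node indices are 1-based and contiguous.

new_mesh <- function(nodes, elements, boundary, type, meta = list()) {
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 type = type, meta = meta),
            class = "biot_mesh")
}

#' Build a structured annulus (cervical-canal cross-section) mesh
#'
#' Meshes the tissue cross-section as a thick-walled tube in 2-D plane
#' strain.  With `half_model = TRUE` (the default, exploiting the mirror
#' symmetry of an axisymmetric dilation load) the mesh spans angles
#' `[0, pi]` measured from the symmetry plane (the x-axis); otherwise the
#' full closed annulus is built.
#'
#' Boundary sets `inner_surface`, `outer_surface` and (for the half model)
#' `symmetry_plane` are populated, with exact radial outward normals stored
#' for the two curved surfaces.
#'
#' @param r_inner,r_outer Inner/outer radii in metres, `0 < r_inner < r_outer`.
#' @param n_radial Number of element layers through the wall (>= 1).
#' @param n_circumferential Number of element layers around the arc (>= 2).
#' @param half_model Mesh only the upper half (default) or the full annulus.
#' @return A `biot_mesh`.
#' @examples
#' m <- build_annulus_mesh(1.5e-3, 10e-3, 4, 8)
#' nrow(m$nodes)     # 45
#' nrow(m$elements)  # 32
#' @export
build_annulus_mesh <- function(r_inner, r_outer, n_radial, n_circumferential,
                               half_model = TRUE) {
  if (!is.numeric(r_inner) || !is.numeric(r_outer) ||
      r_inner <= 0 || r_outer <= r_inner)
    stop_config("invalid geometry: need 0 < r_inner < r_outer (got %g, %g)",
                r_inner, r_outer)
  if (n_radial < 1)
    stop_config("invalid resolution: n_radial must be >= 1")
  if (n_circumferential < 2)
    stop_config("invalid resolution: n_circumferential must be >= 2")

  nr <- as.integer(n_radial); nc <- as.integer(n_circumferential)
  theta_max <- if (half_model) pi else 2 * pi
  n_th <- if (half_model) nc + 1L else nc       # node columns
  radii <- seq(r_inner, r_outer, length.out = nr + 1L)
  thetas <- (seq_len(n_th) - 1L) * theta_max / nc

  # radial index varies fastest
  idx <- function(i, j) j * (nr + 1L) + i + 1L  # i in 0..nr, j in 0..n_th-1
  nodes <- cbind(
    x = rep(radii, times = n_th) * rep(cos(thetas), each = nr + 1L),
    y = rep(radii, times = n_th) * rep(sin(thetas), each = nr + 1L))

  elems <- matrix(0L, nrow = nr * nc, ncol = 4L)
  e <- 0L
  for (j in 0:(nc - 1L)) {
    jp <- if (!half_model && j == nc - 1L) 0L else j + 1L
    for (i in 0:(nr - 1L)) {
      e <- e + 1L
      elems[e, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jp), idx(i, jp))
    }
  }

  jcols <- 0:(n_th - 1L)
  inner_nodes <- idx(0L, jcols)
  outer_nodes <- idx(nr, jcols)
  th_of <- function(nid) atan2(nodes[nid, 2], nodes[nid, 1])

  edge_seq <- function(node_col_fun, reverse) {
    jj <- jcols
    a <- node_col_fun(jj)
    b <- if (half_model) c(a[-1L], NA) else c(a[-1L], a[1L])
    ed <- cbind(a, b)[!is.na(b), , drop = FALSE]
    if (reverse) ed[, 2:1, drop = FALSE] else ed
  }
  # The tissue lies outside the inner circle: traversing the inner surface
  # clockwise (decreasing theta) keeps the domain on the left; the outer
  # surface is traversed counter-clockwise for the same convention.
  inner_edges <- edge_seq(function(j) idx(0L, j), reverse = TRUE)
  outer_edges <- edge_seq(function(j) idx(nr, j), reverse = FALSE)

  boundary <- list(
    inner_surface = list(
      nodes = inner_nodes, edges = inner_edges,
      normals = cbind(-cos(th_of(inner_nodes)), -sin(th_of(inner_nodes)))),
    outer_surface = list(
      nodes = outer_nodes, edges = outer_edges,
      normals = cbind(cos(th_of(outer_nodes)), sin(th_of(outer_nodes)))))

  if (half_model) {
    sym_lo <- idx(0:nr, 0L)            # theta = 0 edge, normal (0, -1)
    sym_hi <- idx(0:nr, nc)            # theta = pi edge, normal (0, +1)
    sym_nodes <- c(sym_lo, sym_hi)
    boundary$symmetry_plane <- list(
      nodes = sym_nodes,
      edges = rbind(cbind(sym_lo[-length(sym_lo)], sym_lo[-1L]),
                    cbind(sym_hi[-1L], sym_hi[-length(sym_hi)])),
      normals = rbind(matrix(rep(c(0, -1), each = nr + 1L), ncol = 2),
                      matrix(rep(c(0, 1), each = nr + 1L), ncol = 2)))
  }

  new_mesh(nodes, elems, boundary, type = "annulus",
           meta = list(r_inner = r_inner, r_outer = r_outer,
                       n_radial = nr, n_circumferential = nc,
                       half_model = half_model))
}

#' Build a consolidation-column mesh (quad strip)
#'
#' One-element-wide strip of height `height` along the y axis, used for the
#' Terzaghi consolidation benchmark: the top surface (`drained_surface`)
#' carries the step load and drains; the `base` is fixed and impermeable;
#' the lateral `sides` are laterally confined and impermeable.
#'
#' @param height Column height in metres (> 0).
#' @param n_elements Number of elements along the column (>= 1).
#' @param width Strip width in metres; defaults to one element's height.
#' @return A `biot_mesh`.
#' @export
build_column_mesh <- function(height, n_elements, width = height / n_elements) {
  if (!is.numeric(height) || height <= 0)
    stop_config("invalid geometry: column height must be > 0 (got %g)", height)
  if (n_elements < 1)
    stop_config("invalid resolution: n_elements must be >= 1")
  ne <- as.integer(n_elements)
  ys <- seq(0, height, length.out = ne + 1L)
  # node index: left column first (x = 0), then right column (x = width)
  nodes <- rbind(cbind(0, ys), cbind(width, ys))
  left <- seq_len(ne + 1L)
  right <- left + ne + 1L
  elems <- cbind(left[-(ne + 1L)], right[-(ne + 1L)],
                 right[-1L], left[-1L])      # CCW
  storage.mode(elems) <- "integer"

  topL <- left[ne + 1L]; topR <- right[ne + 1L]
  boundary <- list(
    drained_surface = list(
      nodes = c(topL, topR),
      edges = matrix(c(topR, topL), ncol = 2),   # domain below on the left
      normals = rbind(c(0, 1), c(0, 1))),
    base = list(
      nodes = c(left[1L], right[1L]),
      edges = matrix(c(left[1L], right[1L]), ncol = 2),
      normals = rbind(c(0, -1), c(0, -1))),
    sides = list(
      nodes = c(left, right),
      edges = rbind(cbind(left[-1L], left[-(ne + 1L)]),
                    cbind(right[-(ne + 1L)], right[-1L])),
      normals = rbind(matrix(rep(c(-1, 0), each = ne + 1L), ncol = 2),
                      matrix(rep(c(1, 0), each = ne + 1L), ncol = 2))))

  new_mesh(nodes, elems, boundary, type = "column",
           meta = list(height = height, n_elements = ne, width = width))
}

#' @export
print.biot_mesh <- function(x, ...) {
  cat(sprintf("biot_mesh (%s): %d nodes, %d quad elements\n",
              x$type, nrow(x$nodes), nrow(x$elements)))
  cat("boundary sets:", paste(names(x$boundary), collapse = ", "), "\n")
  invisible(x)
}

# Jacobian determinants of every element at every quadrature point
# (n_elem x n_gp^2 matrix).  All entries must be strictly positive.
element_jacobians <- function(mesh, n_gauss = 2) {
  g <- gauss_rule(n_gauss)
  pts <- expand.grid(xi = g$x, eta = g$x)
  out <- matrix(NA_real_, nrow(mesh$elements), nrow(pts))
  for (e in seq_len(nrow(mesh$elements))) {
    xy <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    for (k in seq_len(nrow(pts))) {
      dN <- shape_q4(pts$xi[k], pts$eta[k])$dN
      J <- t(dN) %*% xy
      out[e, k] <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    }
  }
  out
}

#' Total mesh area by Gauss quadrature
#'
#' @param mesh A `biot_mesh`.
#' @param n_gauss Quadrature order per direction.
#' @return Total area in square metres.
#' @export
mesh_area <- function(mesh, n_gauss = 2) {
  g <- gauss_rule(n_gauss)
  w2 <- outer(g$w, g$w)
  pts <- expand.grid(xi = g$x, eta = g$x)
  total <- 0
  for (e in seq_len(nrow(mesh$elements))) {
    xy <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    for (k in seq_len(nrow(pts))) {
      dN <- shape_q4(pts$xi[k], pts$eta[k])$dN
      J <- t(dN) %*% xy
      total <- total + as.vector(w2)[k] * (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
    }
  }
  total
}

# Validate mesh invariants; used by tests and by assemble_system.
check_mesh <- function(mesh, n_gauss = 2) {
  dets <- element_jacobians(mesh, n_gauss)
  if (any(dets <= 0))
    stop_config("mesh has non-positive element Jacobians")
  nn <- nrow(mesh$nodes)
  for (nm in names(mesh$boundary)) {
    b <- mesh$boundary[[nm]]
    if (any(b$nodes < 1L | b$nodes > nn) ||
        (length(b$edges) && any(b$edges < 1L | b$edges > nn)))
      stop_config("boundary set '%s' references nonexistent nodes", nm)
  }
  invisible(TRUE)
}

# Reflect a half mesh across the symmetry plane (the x-axis) and merge
# duplicate nodes, yielding a conforming full mesh.  Used to test the
# half-model construction.
reflect_merge <- function(mesh, tol = 1e-12) {
  nodes <- mesh$nodes
  n <- nrow(nodes)
  scale <- max(abs(nodes)) + tol
  refl <- cbind(nodes[, 1], -nodes[, 2])
  on_plane <- abs(nodes[, 2]) < tol * scale
  map <- integer(n)           # original node -> reflected copy's new index
  new_nodes <- nodes
  for (i in seq_len(n)) {
    if (on_plane[i]) {
      map[i] <- i
    } else {
      new_nodes <- rbind(new_nodes, refl[i, ])
      map[i] <- nrow(new_nodes)
    }
  }
  # reflected elements reverse orientation; flip node order to restore CCW
  refl_elems <- t(apply(mesh$elements, 1, function(en) rev(map[en])))
  storage.mode(refl_elems) <- "integer"
  new_mesh(new_nodes, rbind(mesh$elements, refl_elems),
           boundary = list(), type = paste0(mesh$type, "_reflected"),
           meta = mesh$meta)
}

#' Export a mesh as plain CSV listings
#'
#' Writes `<prefix>_nodes.csv` (node id, x, y) and `<prefix>_elements.csv`
#' (element id and its four node ids).
#'
#' @param mesh A `biot_mesh`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
mesh_to_csv <- function(mesh, prefix) {
  fn <- paste0(prefix, "_nodes.csv")
  fe <- paste0(prefix, "_elements.csv")
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$nodes)),
                              x = mesh$nodes[, 1], y = mesh$nodes[, 2]),
                   fn, row.names = FALSE)
  utils::write.csv(data.frame(element = seq_len(nrow(mesh$elements)),
                              n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                              n3 = mesh$elements[, 3], n4 = mesh$elements[, 4]),
                   fe, row.names = FALSE)
  invisible(c(fn, fe))
}
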