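# Boundary conditions.
#
# Essential conditions (displacement, pore pressure, normal Darcy flux) are
# imposed by row/column elimination after an orthogonal change of variables
# that aligns the affected u/q node pairs with the local boundary normal,
# so that u.n = 0 or q.n = 0 on curved surfaces is a single-dof constraint.
# Natural conditions (surface pressure from the dilator) become
# work-equivalent nodal forces on the loaded edges.

#' Boundary-condition specification
#'
#' Names of mesh boundary sets play the following roles:
#' * `pressure`: edges receiving the loading-protocol pressure as an inward
#'   normal traction (or, with `displacement_control = TRUE`, nodes whose
#'   outward normal displacement is prescribed by the protocol, in metres).
#' * `fixed`: nodes with both displacement components fixed to zero.
#' * `symmetry`: nodes with zero normal displacement and zero normal Darcy
#'   flux (mirror plane, or laterally confined impermeable walls).
#' * `drained`: nodes with pore pressure prescribed to zero.
#' * `impermeable`: nodes with zero normal Darcy flux.
#' * `pin_x`: `"y_axis"` fixes the x-displacement of nodes lying on the
#'   y axis (removes the rigid translation of a traction-free half model
#'   under an axisymmetric load), or an integer vector of node ids.
#'
#' @param pressure Single set name or `NULL`.
#' @param fixed,symmetry,drained,impermeable Character vectors of set names
#'   (possibly empty).
#' @param pin_x `NULL`, `"y_axis"`, or node ids whose u_x is fixed.
#' @param displacement_control Drive the `pressure` set by prescribed
#'   outward normal displacement instead of traction.
#' @return An object of class `bc_spec`.
#' @export
bc_spec <- function(pressure = NULL, fixed = character(),
                    symmetry = character(), drained = character(),
                    impermeable = character(), pin_x = NULL,
                    displacement_control = FALSE) {
  structure(list(pressure = pressure, fixed = fixed, symmetry = symmetry,
                 drained = drained, impermeable = impermeable,
                 pin_x = pin_x,
                 displacement_control = isTRUE(displacement_control)),
            class = "bc_spec")
}

#' Default boundary conditions for the built-in geometries
#'
#' Annulus: dilator pressure on the inner surface, which is impermeable
#' (the balloon seals the canal); outer surface fixed and drained; symmetry
#' plane where present.  Column: load and drainage on the top surface,
#' fixed impermeable base, laterally confined impermeable sides.
#'
#' @param mesh A `biot_mesh`.
#' @return A [bc_spec()].
#' @export
default_bc <- function(mesh) {
  if (mesh$type == "column") {
    bc_spec(pressure = "drained_surface", fixed = "base",
            symmetry = "sides", drained = "drained_surface",
            impermeable = "base")
  } else {
    bc_spec(pressure = "inner_surface", fixed = "outer_surface",
            symmetry = intersect("symmetry_plane", names(mesh$boundary)),
            drained = "outer_surface", impermeable = "inner_surface")
  }
}

# Resolve a set name, failing loudly on unknown names.
get_bset <- function(mesh, name) {
  if (!name %in% names(mesh$boundary))
    stop_config("unknown boundary set '%s' (available: %s)", name,
                paste(names(mesh$boundary), collapse = ", "))
  mesh$boundary[[name]]
}

# Work-equivalent nodal forces for a unit pressure on the edges of a set.
# Edges are oriented with the domain on the left, so the outward normal of
# edge t = (t1, t2)/L is (t2, -t1); pressure acts opposite the outward
# normal.  Each node of a straight 2-node edge receives P*L/2.
unit_pressure_load <- function(mesh, set_name) {
  b <- get_bset(mesh, set_name)
  lay <- dof_layout(mesh)
  f <- numeric(lay$n_dof)
  for (r in seq_len(nrow(b$edges))) {
    n1 <- b$edges[r, 1]; n2 <- b$edges[r, 2]
    dvec <- mesh$nodes[n2, ] - mesh$nodes[n1, ]
    L <- sqrt(sum(dvec^2))
    nrm <- c(dvec[2], -dvec[1]) / L
    fn <- -nrm * L / 2
    f[dof_u(n1, lay$n_nodes)] <- f[dof_u(n1, lay$n_nodes)] + fn
    f[dof_u(n2, lay$n_nodes)] <- f[dof_u(n2, lay$n_nodes)] + fn
  }
  f
}

# Internal: accumulate a directional constraint on the 2-dof pair of
# (node, field).  `env$dir[[key]]` collects unit direction vectors.
add_dir_constraint <- function(env, node, field, n) {
  key <- paste0(field, node)
  env$dirs[[key]] <- c(env$dirs[[key]], list(n / sqrt(sum(n^2))))
  env$meta[[key]] <- list(node = node, field = field)
}

#' Apply boundary conditions to an assembled system
#'
#' Builds the orthogonal nodal transformation, the list of constrained
#' (transformed) dofs with their value histories, and the external load
#' vector as a function of time.
#'
#' @param system A `biot_system` from [assemble_system()].
#' @param bc A [bc_spec()].
#' @param protocol A `loading_protocol` driving the pressure (or prescribed
#'   displacement) boundary; may be `NULL` for an unloaded system.
#' @return A list of class `biot_csys` extending the system with `Tmat`,
#'   `fixed` (transformed dof indices), `fixed_value_fun(t)`, `free`,
#'   `load_fun(t)` and the bc echo.
#' @export
apply_boundary_conditions <- function(system, bc, protocol = NULL) {
  if (!inherits(system, "biot_system")) stop_config("invalid system object")
  if (!inherits(bc, "bc_spec")) stop_config("invalid bc_spec object")
  mesh <- system$mesh
  lay <- system$layout
  nn <- lay$n_nodes

  env <- new.env()
  env$dirs <- list(); env$meta <- list()
  fixed_p <- integer()      # p dofs (drained)
  fixed_full_u <- integer() # nodes with u fully fixed
  disp_nodes <- integer()   # displacement-control nodes (normal dof driven)
  disp_dirs <- NULL

  for (s in bc$fixed) {
    b <- get_bset(mesh, s)
    fixed_full_u <- union(fixed_full_u, b$nodes)
  }
  for (s in bc$drained) {
    b <- get_bset(mesh, s)
    fixed_p <- union(fixed_p, dof_p(b$nodes, nn))
  }
  for (s in bc$symmetry) {
    b <- get_bset(mesh, s)
    for (i in seq_along(b$nodes)) {
      add_dir_constraint(env, b$nodes[i], "u", b$normals[i, ])
      add_dir_constraint(env, b$nodes[i], "q", b$normals[i, ])
    }
  }
  for (s in bc$impermeable) {
    b <- get_bset(mesh, s)
    for (i in seq_along(b$nodes))
      add_dir_constraint(env, b$nodes[i], "q", b$normals[i, ])
  }
  if (!is.null(bc$pin_x)) {
    pin_nodes <- if (identical(bc$pin_x, "y_axis")) {
      scale <- max(abs(mesh$nodes))
      which(abs(mesh$nodes[, 1]) < 1e-9 * scale)
    } else as.integer(bc$pin_x)
    if (any(pin_nodes < 1L | pin_nodes > nn))
      stop_config("pin_x references nonexistent nodes")
    for (nd in pin_nodes) add_dir_constraint(env, nd, "u", c(1, 0))
  }
  if (!is.null(bc$pressure) && bc$displacement_control) {
    b <- get_bset(mesh, bc$pressure)
    disp_nodes <- b$nodes
    disp_dirs <- b$normals       # prescribed value acts along -normal (outward)
    for (i in seq_along(b$nodes))
      add_dir_constraint(env, b$nodes[i], "u", b$normals[i, ])
  }

  # Resolve directional constraints into rotations + transformed dof lists.
  rot_i <- integer(); rot_j <- integer(); rot_x <- numeric()
  fixed_dirdofs <- integer()
  driven_dof <- integer()       # transformed dofs driven by the protocol
  rotated <- character()
  for (key in names(env$dirs)) {
    info <- env$meta[[key]]
    pair <- if (info$field == "u") dof_u(info$node, nn) else dof_q(info$node, nn)
    dirs <- unique(do.call(rbind, env$dirs[[key]]))
    # collapse near-duplicate directions (up to sign)
    keep <- rep(TRUE, nrow(dirs))
    if (nrow(dirs) > 1) {
      for (a in 2:nrow(dirs)) for (bb in 1:(a - 1)) {
        if (keep[bb] && abs(abs(sum(dirs[a, ] * dirs[bb, ])) - 1) < 1e-9)
          keep[a] <- FALSE
      }
    }
    dirs <- dirs[keep, , drop = FALSE]
    is_driven <- info$field == "u" && info$node %in% disp_nodes
    if (nrow(dirs) >= 2L) {
      if (is_driven) {
        # prescribed normal motion can coexist with one orthogonal zero
        # constraint (e.g. the symmetry plane at the seam node): rotate to
        # the driven normal, drive the first dof, fix the second
        idx <- which(info$node == disp_nodes)[1]
        n <- disp_dirs[idx, ]
        others <- dirs[apply(dirs, 1, function(d)
          abs(abs(sum(d * n)) - 1) > 1e-9), , drop = FALSE]
        if (nrow(dirs) > 2L ||
            any(abs(others %*% n) > 1e-9))
          stop_config("conflicting constraints on node %d: %s", info$node,
                      "prescribed motion combined with a non-orthogonal constraint")
        # always rotate driven pairs so the first transformed dof is u.n
        # with the correct sign, whatever the normal's orientation
        rot_i <- c(rot_i, pair[1], pair[1], pair[2], pair[2])
        rot_j <- c(rot_j, pair[1], pair[2], pair[1], pair[2])
        rot_x <- c(rot_x, n[1], n[2], -n[2], n[1])
        rotated <- c(rotated, key)
        driven_dof <- c(driven_dof, pair[1])
        fixed_dirdofs <- c(fixed_dirdofs, pair[2])
        next
      }
      fixed_dirdofs <- c(fixed_dirdofs, pair)       # fully constrained
    } else {
      n <- dirs[1, ]
      if (!is_driven && abs(n[1]) > 1 - 1e-9) {
        cdof <- pair[1]
      } else if (!is_driven && abs(n[2]) > 1 - 1e-9) {
        cdof <- pair[2]
      } else {
        # rotate the pair so the first transformed dof is u.n (driven
        # nodes always rotate, preserving the normal's sign)
        rot_i <- c(rot_i, pair[1], pair[1], pair[2], pair[2])
        rot_j <- c(rot_j, pair[1], pair[2], pair[1], pair[2])
        rot_x <- c(rot_x, n[1], n[2], -n[2], n[1])
        rotated <- c(rotated, key)
        cdof <- pair[1]
      }
      if (is_driven) driven_dof <- c(driven_dof, cdof)
      else fixed_dirdofs <- c(fixed_dirdofs, cdof)
    }
  }

  udofs_fixed <- if (length(fixed_full_u)) dof_u(fixed_full_u, nn) else integer()
  # a fully fixed node may also carry a (redundant) directional constraint
  fixed_dirdofs <- setdiff(fixed_dirdofs, udofs_fixed)

  n_dof <- lay$n_dof
  ident <- setdiff(seq_len(n_dof), unique(rot_i))
  Tmat <- Matrix::sparseMatrix(i = c(ident, rot_i), j = c(ident, rot_j),
                               x = c(rep(1, length(ident)), rot_x),
                               dims = c(n_dof, n_dof))

  fixed <- sort(unique(c(udofs_fixed, fixed_dirdofs, fixed_p, driven_dof)))
  free <- setdiff(seq_len(n_dof), fixed)

  # prescribed values in the transformed frame (all zero except the
  # displacement-driven dofs, which follow -protocol since surface normals
  # point out of the domain and openings are measured outward)
  driven_mask <- fixed %in% driven_dof
  fixed_value_fun <- function(t) {
    v <- numeric(length(fixed))
    if (any(driven_mask) && !is.null(protocol))
      v[driven_mask] <- -protocol_value(protocol, t)
    v
  }

  f_unit <- if (!is.null(bc$pressure) && !bc$displacement_control)
    unit_pressure_load(mesh, bc$pressure) else numeric(n_dof)
  load_fun <- function(t) {
    if (is.null(protocol)) return(numeric(n_dof))
    if (bc$displacement_control) return(numeric(n_dof))
    protocol_value(protocol, t) * f_unit
  }

  out <- system
  out$Tmat <- Tmat
  out$fixed <- fixed
  out$free <- free
  out$fixed_p <- intersect(fixed, dof_p(seq_len(nn), nn))
  out$fixed_value_fun <- fixed_value_fun
  out$load_fun <- load_fun
  out$f_unit <- f_unit
  out$bc <- bc
  out$protocol <- protocol
  class(out) <- c("biot_csys", "biot_system")
  out
}
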