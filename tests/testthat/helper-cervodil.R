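# Shared fixtures for the test suite.  Everything is generated in code.

unit_square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)

# Random convex-ish distorted quad with a strictly positive Jacobian.
random_quad <- function() {
  repeat {
    q <- unit_square + matrix(stats::runif(8, -0.2, 0.2), 4, 2)
    ok <- tryCatch({
      element_matrices(q, material())
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(q)
  }
}

# Small annulus and short run used by several tests.
tiny_annulus <- function() build_annulus_mesh(1.5e-3, 10e-3, 6, 12)
quick_config <- function(t_end = 2, dt = 0.1)
  solver_config(dt = dt, t_end = t_end)

# Energy-like seminorm of a state (elastic + kinetic + fluid storage +
# fluid kinetic), used by the unconditional-stability test.
system_energy <- function(csys, state) {
  lay <- csys$layout
  u <- state$x[lay$u]; v <- state$v[lay$u]
  p <- state$x[lay$p]; q <- state$x[lay$q]
  0.5 * (sum(u * as.numeric(csys$K[lay$u, lay$u] %*% u)) +
           sum(v * as.numeric(csys$M[lay$u, lay$u] %*% v)) +
           sum(p * as.numeric(csys$C[lay$p, lay$p] %*% p)) +
           sum(q * as.numeric(csys$C[lay$q, lay$q] %*% q)))
}

# Oscillation period from linearly interpolated downward zero crossings.
measured_period <- function(time, u) {
  i <- which(u[-length(u)] > 0 & u[-1] <= 0)
  tc <- time[i] + (time[i + 1] - time[i]) * u[i] / (u[i] - u[i + 1])
  (tc[length(tc)] - tc[1]) / (length(tc) - 1)
}

# Map each node of mesh a onto the identically placed node of mesh b.
match_nodes <- function(a, b, tol = 1e-12) {
  key <- function(m) paste(round(m[, 1] / tol), round(m[, 2] / tol))
  match(key(a$nodes), key(b$nodes))
}
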