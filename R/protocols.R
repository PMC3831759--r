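# Dilator loading histories and their comparison.
#
# The measured in-vitro/in-vivo balloon traces exist only as published
# plots, so the package ships parametric emulations: a CCBD-style linear
# ramp reaching the working pressure at 45 s, and a Hegar-style near-step
# rise over about one second.  Digitised traces can be supplied as tables.

#' Construct a loading protocol
#'
#' * `ramp`: linear from 0 to `p_max` over `t_rise`, then constant.
#' * `step`: `p_max` for every `t > 0` (0 at `t = 0`).
#' * `table`: piecewise-linear through `(time, pressure)` breakpoints with
#'   constant extrapolation past the last time; a leading `(0, 0)` point is
#'   added when the table starts after time zero.
#'
#' @param kind `"ramp"`, `"step"` or `"table"`.
#' @param p_max Peak pressure \[Pa\] (ramp/step).
#' @param t_rise Ramp duration \[s\], `0 <= t_rise <= t_end`.
#' @param t_end Duration over which the protocol is meant to be used \[s\].
#' @param table Two-column data frame or matrix `(time [s], pressure [Pa])`
#'   with strictly increasing times (table kind).
#' @param label Optional display label.
#' @return An object of class `loading_protocol`.
#' @examples
#' pr <- make_protocol("ramp", p_max = 10e3, t_rise = 45, t_end = 60)
#' protocol_value(pr, 22.5)  # half the peak
#' @export
make_protocol <- function(kind = c("ramp", "step", "table"), p_max = NULL,
                          t_rise = NULL, t_end = NULL, table = NULL,
                          label = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("ramp", "step")) {
    if (is.null(p_max) || p_max < 0)
      stop_config("protocol: p_max must be >= 0")
    if (kind == "ramp") {
      if (is.null(t_rise) || is.null(t_end) || t_rise < 0 || t_rise > t_end)
        stop_config("protocol: need 0 <= t_rise <= t_end")
    } else {
      t_rise <- 0
      if (is.null(t_end)) t_end <- Inf
    }
    tab <- NULL
  } else {
    tab <- as.matrix(table)
    if (is.null(tab) || nrow(tab) < 1L || ncol(tab) != 2L)
      stop_config("protocol: table must have columns (time, pressure)")
    if (nrow(tab) > 1L && any(diff(tab[, 1]) <= 0))
      stop_config("protocol: table times must be strictly increasing")
    if (any(!is.finite(tab)))
      stop_config("protocol: table entries must be finite")
    if (tab[1, 1] > 0) tab <- rbind(c(0, 0), tab)
    t_end <- t_end %||% max(tab[, 1])
    p_max <- max(abs(tab[, 2]))
    t_rise <- NA_real_
  }
  structure(list(kind = kind, p_max = p_max, t_rise = t_rise, t_end = t_end,
                 table = tab, label = label %||% kind),
            class = "loading_protocol")
}

#' Evaluate a protocol's pressure at given times
#'
#' @param protocol A `loading_protocol`.
#' @param t Numeric vector of times \[s\].
#' @return Pressures \[Pa\], exact at table breakpoints and piecewise
#'   linear between them.
#' @export
protocol_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  switch(protocol$kind,
    step = ifelse(t > 0, protocol$p_max, 0),
    ramp = {
      if (protocol$t_rise == 0) ifelse(t > 0, protocol$p_max, 0)
      else protocol$p_max * pmin(pmax(t, 0) / protocol$t_rise, 1)
    },
    table = {
      tab <- protocol$table
      if (nrow(tab) == 1L) rep(tab[1, 2], length(t))
      else stats::approx(tab[, 1], tab[, 2], xout = pmin(t, tab[nrow(tab), 1]),
                         rule = 2)$y
    })
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf("loading_protocol '%s' (%s): p_max = %g Pa, t_end = %g s\n",
              x$label, x$kind, x$p_max, x$t_end))
  invisible(x)
}

# Scale a protocol's pressures by a constant (linearity checks).
scale_protocol <- function(protocol, factor) {
  out <- protocol
  if (protocol$kind == "table") out$table[, 2] <- out$table[, 2] * factor
  out$p_max <- out$p_max * factor
  out$label <- paste0(protocol$label, " x", factor)
  out
}

#' CCBD-style and Hegar-style parametric protocols
#'
#' The hydraulic balloon (CCBD) opens the canal continuously until its
#' final position at 45 s: a linear ramp.  The rigid Hegar dilator loads
#' the tissue almost immediately: a near-step rise over `t_rise` (1 s by
#' default; set `t_rise = 0` for an ideal step).
#'
#' @param p_max Working pressure on the tissue \[Pa\].
#' @param t_end Protocol duration \[s\].
#' @param t_rise Rise time \[s\].
#' @return A `loading_protocol`.
#' @export
ccbd_protocol <- function(p_max = 10e3, t_end = 60, t_rise = 45) {
  make_protocol("ramp", p_max = p_max, t_rise = t_rise, t_end = t_end,
                label = "CCBD ramp")
}

#' @rdname ccbd_protocol
#' @export
hegar_protocol <- function(p_max = 10e3, t_end = 60, t_rise = 1) {
  if (t_rise <= 0)
    make_protocol("step", p_max = p_max, t_end = t_end, label = "Hegar step")
  else
    make_protocol("ramp", p_max = p_max, t_rise = t_rise, t_end = t_end,
                  label = "Hegar near-step")
}

#' Net tissue pressure from paired dilation traces
#'
#' Subtracts the in-vivo from the in-vitro balloon pressure trace on the
#' union of their time grids (linear interpolation, constant extrapolation
#' at the ends), giving the net pressure transmitted to the canal wall.
#' Negative values are retained; their count is attached as attribute
#' `negative_count` and reported with a warning.
#'
#' @param pa_trace,pb_trace Two-column data frames/matrices
#'   `(time [s], pressure [Pa])` with increasing times.
#' @param swap Subtract in the opposite order (Pb - Pa).
#' @return A table-kind `loading_protocol` labelled `"Pa-Pb"` (or
#'   `"Pb-Pa"`).
#' @export
net_pressure <- function(pa_trace, pb_trace, swap = FALSE) {
  pa <- as.matrix(pa_trace); pb <- as.matrix(pb_trace)
  for (nm in list(list(pa, "pa"), list(pb, "pb"))) {
    m <- nm[[1]]
    if (is.null(m) || nrow(m) < 1L || ncol(m) < 2L)
      stop_config("net_pressure: %s_trace must be a non-empty 2-column table",
                  nm[[2]])
    if (nrow(m) > 1L && any(diff(m[, 1]) <= 0))
      stop_config("net_pressure: %s_trace times must be increasing", nm[[2]])
  }
  if (min(pa[, 1]) > max(pb[, 1]) || min(pb[, 1]) > max(pa[, 1]))
    stop_config("net_pressure: traces have disjoint time supports")
  grid <- sort(unique(c(pa[, 1], pb[, 1])))
  interp <- function(m) {
    if (nrow(m) == 1L) rep(m[1, 2], length(grid))
    else stats::approx(m[, 1], m[, 2], xout = grid, rule = 2)$y
  }
  diff_p <- if (swap) interp(pb) - interp(pa) else interp(pa) - interp(pb)
  neg <- sum(diff_p < 0)
  if (neg > 0)
    warning(sprintf("net_pressure: %d negative net-pressure values retained",
                    neg), call. = FALSE)
  out <- make_protocol("table", table = cbind(grid, diff_p),
                       label = if (swap) "Pb-Pa" else "Pa-Pb")
  attr(out, "negative_count") <- neg
  out
}

#' Side-by-side dilator comparison on identical mesh and material
#'
#' Runs the forward model once per protocol, then extracts the peak von
#' Mises effective stress over the domain and the mean inner-surface
#' radial opening at every recorded step, the a/b stress-ratio time
#' series, and a snapshot table at the requested times.
#'
#' @param mesh,mat,config,bc As in [run_simulation()].
#' @param protocol_a,protocol_b The two loading protocols.
#' @param snapshot_times Times \[s\] for the snapshot table
#'   (default `c(5, 20, 35, 45)`).
#' @param ratio_floor Denominator floor below which the ratio is reported
#'   as `NA`; defaults to `1e-9` times the overall peak stress.
#' @param stride Recording stride passed to [run_simulation()].
#' @return An object of class `dilator_comparison`.
#' @export
compare_dilators <- function(mesh, mat, protocol_a, protocol_b,
                             config = solver_config(),
                             snapshot_times = c(5, 20, 35, 45),
                             bc = NULL, ratio_floor = NULL, stride = 1L) {
  run1 <- function(pr, tag) {
    tryCatch(run_simulation(mesh, mat, pr, config, bc = bc, stride = stride,
                            record_rates = FALSE),
             error = function(e)
               stop_solver("protocol '%s' (%s): %s", pr$label, tag,
                           conditionMessage(e)))
  }
  ra <- run1(protocol_a, "a")
  rb <- run1(protocol_b, "b")
  sa <- effective_stress(ra, mat)
  sb <- effective_stress(rb, mat)
  peak_a <- apply(sa$von_mises, 2, max)
  peak_b <- apply(sb$von_mises, 2, max)
  open_a <- inner_opening(ra)
  open_b <- inner_opening(rb)
  if (any(snapshot_times < min(ra$time) | snapshot_times > max(ra$time)))
    stop_config("snapshot times must lie within [%g, %g] s",
                min(ra$time), max(ra$time))
  floor_val <- ratio_floor %||% (1e-9 * max(peak_a, peak_b, 0))
  ratio <- ifelse(peak_b > floor_val, peak_a / peak_b, NA_real_)
  snap_idx <- vapply(snapshot_times,
                     function(t) which.min(abs(ra$time - t)), integer(1))
  snapshots <- data.frame(
    time_requested = snapshot_times, time = ra$time[snap_idx],
    peak_vm_a = peak_a[snap_idx], peak_vm_b = peak_b[snap_idx],
    opening_a = open_a[snap_idx], opening_b = open_b[snap_idx],
    stress_ratio = ratio[snap_idx])
  structure(list(time = ra$time, peak_vm_a = peak_a, peak_vm_b = peak_b,
                 opening_a = open_a, opening_b = open_b, ratio = ratio,
                 snapshots = snapshots, ratio_floor = floor_val,
                 labels = c(a = protocol_a$label, b = protocol_b$label),
                 result_a = ra, result_b = rb),
            class = "dilator_comparison")
}

#' @export
print.dilator_comparison <- function(x, ...) {
  cat(sprintf("dilator_comparison: a = '%s' vs b = '%s'\n",
              x$labels["a"], x$labels["b"]))
  print(x$snapshots, row.names = FALSE)
  invisible(x)
}
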