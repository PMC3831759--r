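# Snapshot extraction and export to VTK / CSV / JSON.
#
# All exports are plain ASCII with fixed numeric formatting and no
# timestamps, so repeated exports of the same result are byte-identical.

#' Extract fields at requested times
#'
#' Returns, for every requested time, the nearest recorded step's fields
#' together with the actual step time and the offset.  The default set
#' mirrors the published comparison times of 5, 20, 35 and 45 s.
#'
#' @param result A `biot_result`.
#' @param times Numeric vector of times \[s\] inside the recorded range.
#' @return A list (one entry per time) with `time_requested`, `time`,
#'   `offset`, `step`, and fields `u`, `p`, `q`.
#' @export
snapshot <- function(result, times = c(5, 20, 35, 45)) {
  lo <- min(result$time); hi <- max(result$time)
  bad <- times < lo | times > hi
  if (any(bad))
    stop(sprintf(
      "snapshot: requested time %g outside the recorded interval [%g, %g] s",
      times[which(bad)[1]], lo, hi), call. = FALSE)
  lapply(times, function(tt) {
    i <- which.min(abs(result$time - tt))
    list(time_requested = tt, time = result$time[i],
         offset = tt - result$time[i], step = i,
         u = result_field(result, "u", i),
         p = result_field(result, "p", i),
         q = result_field(result, "q", i))
  })
}

fmt_num <- function(x) sprintf("%.9e", x)

#' Export a result to legacy VTK unstructured-grid files
#'
#' One ASCII file per selected recorded step, named
#' `<prefix>_NNNN.vtk`, carrying displacement and Darcy velocity as point
#' vectors, pore pressure as point scalars and (when a material is
#' available) the von Mises effective stress as a cell scalar.
#'
#' @param result A `biot_result`.
#' @param path_prefix Output path prefix.
#' @param steps Recorded step indices to export (default: all).  An empty
#'   selection writes nothing and succeeds.
#' @param stress Optional precomputed [effective_stress()] object.
#' @return Invisibly, the written file paths.
#' @export
export_vtk <- function(result, path_prefix, steps = NULL, stress = NULL) {
  if (is.null(steps)) steps <- seq_along(result$time)
  if (length(steps) == 0L) return(invisible(character(0)))
  if (is.null(stress)) stress <- effective_stress(result)
  mesh <- result$mesh
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  files <- character(0)
  for (s in steps) {
    u <- result_field(result, "u", s)
    p <- result_field(result, "p", s)
    q <- result_field(result, "q", s)
    path <- sprintf("%s_%04d.vtk", path_prefix, s)
    con <- file(path, "w")
    wl <- function(...) writeLines(c(...), con)
    wl("# vtk DataFile Version 2.0",
       sprintf("poroelastic fields t=%s", fmt_num(result$time[s])),
       "ASCII", "DATASET UNSTRUCTURED_GRID",
       sprintf("POINTS %d double", nn))
    wl(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
             fmt_num(0)))
    wl(sprintf("CELLS %d %d", ne, 5L * ne))
    wl(paste(4L, mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
             mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L))
    wl(sprintf("CELL_TYPES %d", ne))
    wl(rep("9", ne))
    wl(sprintf("POINT_DATA %d", nn),
       "VECTORS displacement double")
    wl(paste(fmt_num(u[, 1]), fmt_num(u[, 2]), fmt_num(0)))
    wl("SCALARS pressure double 1", "LOOKUP_TABLE default")
    wl(fmt_num(p))
    wl("VECTORS darcy_velocity double")
    wl(paste(fmt_num(q[, 1]), fmt_num(q[, 2]), fmt_num(0)))
    wl(sprintf("CELL_DATA %d", ne),
       "SCALARS von_mises double 1", "LOOKUP_TABLE default")
    wl(fmt_num(stress$von_mises[, s]))
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}

#' Minimal reader for the legacy VTK files written by [export_vtk()]
#'
#' @param path File path.
#' @return List with `points`, `cells` (1-based), `point_data` and
#'   `cell_data` (named lists).
#' @export
read_vtk_legacy <- function(path) {
  ln <- readLines(path)
  i <- grep("^POINTS", ln)[1]
  nn <- as.integer(strsplit(ln[i], " ")[[1]][2])
  pts <- matrix(scan(text = ln[(i + 1):(i + nn)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  i <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[i], " ")[[1]][2])
  cl <- matrix(scan(text = ln[(i + 1):(i + ne)], quiet = TRUE),
               ncol = 5, byrow = TRUE)[, -1, drop = FALSE] + 1L
  read_fields <- function(start, count) {
    out <- list(); j <- start
    while (j <= length(ln)) {
      if (grepl("^(POINT_DATA|CELL_DATA)", ln[j])) break
      if (grepl("^VECTORS", ln[j])) {
        nm <- strsplit(ln[j], " ")[[1]][2]
        out[[nm]] <- matrix(scan(text = ln[(j + 1):(j + count)],
                                 quiet = TRUE), ncol = 3, byrow = TRUE)
        j <- j + count + 1L
      } else if (grepl("^SCALARS", ln[j])) {
        nm <- strsplit(ln[j], " ")[[1]][2]
        out[[nm]] <- scan(text = ln[(j + 2):(j + 1 + count)], quiet = TRUE)
        j <- j + count + 2L
      } else j <- j + 1L
    }
    out
  }
  ipd <- grep("^POINT_DATA", ln)[1]
  icd <- grep("^CELL_DATA", ln)[1]
  list(points = pts, cells = cl,
       point_data = if (is.na(ipd)) list() else read_fields(ipd + 1L, nn),
       cell_data = if (is.na(icd)) list() else read_fields(icd + 1L, ne))
}

#' Export probe time series to CSV
#'
#' One row per recorded step; columns for each probed node (displacement,
#' pressure, Darcy velocity) and element (von Mises), plus the
#' peak-over-domain von Mises stress.
#'
#' @param result A `biot_result`.
#' @param path Output CSV path.
#' @param nodes Integer node ids to probe (may be empty).
#' @param elements Integer element ids to probe (may be empty).
#' @param stress Optional precomputed [effective_stress()] object.
#' @return Invisibly, the exported data frame.
#' @export
export_timeseries <- function(result, path, nodes = integer(),
                              elements = integer(), stress = NULL) {
  nn <- nrow(result$mesh$nodes); ne <- nrow(result$mesh$elements)
  if (any(nodes < 1L | nodes > nn))
    stop("export_timeseries: invalid node probe id", call. = FALSE)
  if (any(elements < 1L | elements > ne))
    stop("export_timeseries: invalid element probe id", call. = FALSE)
  if (is.null(stress)) stress <- effective_stress(result)
  df <- data.frame(time = result$time)
  lay <- result$csys$layout
  for (nd in nodes) {
    df[[sprintf("u_x_n%d", nd)]] <- result$X[2L * nd - 1L, ]
    df[[sprintf("u_y_n%d", nd)]] <- result$X[2L * nd, ]
    df[[sprintf("p_n%d", nd)]] <- result$X[lay$p[nd], ]
    df[[sprintf("q_x_n%d", nd)]] <- result$X[lay$q[2L * nd - 1L], ]
    df[[sprintf("q_y_n%d", nd)]] <- result$X[lay$q[2L * nd], ]
  }
  for (el in elements)
    df[[sprintf("vm_e%d", el)]] <- stress$von_mises[el, ]
  df$peak_von_mises <- apply(stress$von_mises, 2, max)
  utils::write.csv(format(df, digits = 12, scientific = TRUE,
                          trim = TRUE), path, row.names = FALSE,
                   quote = FALSE)
  invisible(df)
}

#' Read / write two-column pressure traces
#'
#' CSV with the header `time_s,pressure_pa`, as accepted by table-kind
#' protocols and [net_pressure()].
#'
#' @param path CSV path.
#' @return Data frame with columns `time_s`, `pressure_pa`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_config("trace file not found: %s", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop_config("malformed trace CSV %s: %s", path, conditionMessage(e)))
  if (!all(c("time_s", "pressure_pa") %in% names(df)))
    stop_config("trace CSV %s must have header time_s,pressure_pa", path)
  tm <- suppressWarnings(as.numeric(df$time_s))
  pp <- suppressWarnings(as.numeric(df$pressure_pa))
  bad <- which(!is.finite(tm) | !is.finite(pp))
  if (length(bad))
    stop_config("malformed trace CSV %s: non-numeric entry at line %d",
                path, bad[1] + 1L)
  if (length(tm) > 1L && any(diff(tm) <= 0)) {
    ln <- which(diff(tm) <= 0)[1] + 2L
    stop_config("trace CSV %s: times not increasing at line %d", path, ln)
  }
  data.frame(time_s = tm, pressure_pa = pp)
}

#' @rdname read_trace
#' @param trace Data frame with `time_s` and `pressure_pa` (or two
#'   columns).
#' @export
write_trace <- function(trace, path) {
  m <- as.matrix(trace)
  utils::write.csv(data.frame(time_s = m[, 1], pressure_pa = m[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON run summary
#'
#' Peak von Mises effective stress at the snapshot times, the opening at
#' the end of the run, and the reproducibility metadata (package version,
#' configuration digest).
#'
#' @param result A `biot_result`.
#' @param snapshot_times Times \[s\] for the stress summary.
#' @param path Optional path; when given, the JSON is written there.
#' @return The summary list, invisibly when `path` is given.
#' @export
run_summary <- function(result, snapshot_times = c(5, 20, 35, 45),
                        path = NULL) {
  snapshot_times <- snapshot_times[snapshot_times <= max(result$time) &
                                     snapshot_times >= min(result$time)]
  stress <- effective_stress(result)
  peak <- apply(stress$von_mises, 2, max)
  idx <- vapply(snapshot_times, function(t) which.min(abs(result$time - t)),
                integer(1))
  opening <- if (!is.null(result$mesh$boundary$inner_surface))
    inner_opening(result) else rep(NA_real_, length(result$time))
  out <- list(
    package = "cervodil",
    version = as.character(utils::packageVersion("cervodil")),
    protocol = result$meta$protocol_label,
    config_digest = result$meta$config_digest,
    snapshots = data.frame(time = result$time[idx],
                           peak_von_mises_pa = peak[idx],
                           opening_m = opening[idx]),
    final_opening_m = opening[length(opening)],
    peak_von_mises_overall_pa = max(peak))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    return(invisible(out))
  }
  out
}
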