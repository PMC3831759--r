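# Snapshots, VTK and CSV exports, trace IO.

quick_run <- function() {
  run_simulation(tiny_annulus(), material(),
                 make_protocol("ramp", p_max = 5e3, t_rise = 1, t_end = 2),
                 quick_config(2), bc = canal_bc(), record_rates = FALSE)
}

test_that("snapshots use the nearest recorded step and report offsets", {
  res <- quick_run()
  s <- snapshot(res, c(1.0, 1.04))
  expect_equal(s[[1]]$time, 1.0)
  expect_equal(s[[1]]$offset, 0)
  expect_equal(s[[2]]$time, 1.0)
  expect_equal(s[[2]]$offset, 0.04)
  expect_equal(dim(s[[1]]$u), c(nrow(res$mesh$nodes), 2))
  err <- tryCatch(snapshot(res, 999), error = function(e) e)
  expect_match(conditionMessage(err), "\\[0, 2\\]")
})

test_that("VTK export round-trips fields and is byte-stable", {
  res <- quick_run()
  st <- effective_stress(res)
  pre <- file.path(tempdir(), "vtkout")
  files <- export_vtk(res, pre, steps = c(11, 21), stress = st)
  expect_length(files, 2)
  v <- read_vtk_legacy(files[1])
  expect_equal(nrow(v$points), nrow(res$mesh$nodes))
  expect_setequal(names(v$point_data),
                  c("displacement", "pressure", "darcy_velocity"))
  expect_named(v$cell_data, "von_mises")
  # ASCII values round-trip exactly at the written precision
  p_mem <- result_field(res, "p", 11)
  expect_identical(v$point_data$pressure,
                   as.numeric(sprintf("%.9e", p_mem)))
  # repeated export is byte-identical
  pre2 <- file.path(tempdir(), "vtkout2")
  files2 <- export_vtk(res, pre2, steps = c(11, 21), stress = st)
  expect_identical(readLines(files[1]), readLines(files2[1]))
  # empty selection: nothing written, success
  expect_identical(export_vtk(res, pre, steps = integer()), character(0))
})

test_that("time-series export is consistent and re-readable", {
  res <- quick_run()
  path <- file.path(tempdir(), "ts.csv")
  ne <- nrow(res$mesh$elements)
  df <- export_timeseries(res, path, nodes = c(1, 5),
                          elements = seq_len(ne))
  back <- read.csv(path)
  expect_equal(nrow(back), length(res$time))
  # re-read values match to printed precision
  expect_equal(back$peak_von_mises, df$peak_von_mises, tolerance = 1e-10)
  # peak column equals the max over all element probes
  vm_cols <- as.matrix(back[, grep("^vm_e", names(back))])
  expect_equal(apply(vm_cols, 1, max), back$peak_von_mises,
               tolerance = 1e-9)
  expect_error(export_timeseries(res, path, nodes = 10^6), "invalid node")
  expect_error(export_timeseries(res, path, elements = 10^6),
               "invalid element")
})

test_that("a zero-load run exports all-zero series", {
  res <- run_simulation(tiny_annulus(), material(),
                        make_protocol("ramp", p_max = 0, t_rise = 1,
                                      t_end = 2),
                        quick_config(2), record_rates = FALSE)
  path <- file.path(tempdir(), "ts0.csv")
  df <- export_timeseries(res, path, nodes = 1, elements = 1)
  expect_identical(max(abs(as.matrix(df[, -1]))), 0)
})

test_that("pressure traces round-trip and malformed files are located", {
  tr <- data.frame(time_s = c(0, 1, 2), pressure_pa = c(0, 5e3, 4e3))
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back, tr)

  writeLines(c("time_s,pressure_pa", "0,0", "1,oops"), path)
  err <- tryCatch(read_trace(path), error = function(e) e)
  expect_s3_class(err, "cervodil_config_error")
  expect_match(conditionMessage(err), "line 3")

  writeLines(c("time_s,pressure_pa", "1,0", "0.5,1"), path)
  expect_error(read_trace(path), "not increasing at line 3")
})

test_that("run summaries are deterministic and carry the peak stresses", {
  res <- quick_run()
  p1 <- file.path(tempdir(), "s1.json"); p2 <- file.path(tempdir(), "s2.json")
  run_summary(res, snapshot_times = c(1, 2), path = p1)
  run_summary(res, snapshot_times = c(1, 2), path = p2)
  expect_identical(readLines(p1), readLines(p2))
  s <- jsonlite::read_json(p1, simplifyVector = TRUE)
  expect_equal(length(s$snapshots$time), 2)
  st <- effective_stress(res)
  expect_equal(s$peak_von_mises_overall_pa, max(st$von_mises),
               tolerance = 1e-12)
})
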