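# Protocol construction, evaluation and the net-pressure subtraction.

test_that("ramp, step and table protocols evaluate as specified", {
  P <- 7e3
  ramp <- make_protocol("ramp", p_max = P, t_rise = 45, t_end = 60)
  expect_equal(protocol_value(ramp, 22.5), P / 2)
  expect_equal(protocol_value(ramp, c(0, 45, 60)), c(0, P, P))

  stp <- make_protocol("step", p_max = P, t_end = 60)
  expect_equal(protocol_value(stp, c(0, 1e-9, 33)), c(0, P, P))

  tab <- make_protocol("table", table = cbind(c(0, 45), c(0, P)))
  expect_equal(protocol_value(tab, 50), P)          # right-constant
  expect_equal(protocol_value(tab, 22.5), P / 2)    # exact at midpoint
  expect_equal(protocol_value(tab, 0), 0)
  # a table starting after t = 0 gets a leading (0, 0) breakpoint
  tab2 <- make_protocol("table", table = cbind(c(10, 20), c(5, 5)))
  expect_equal(protocol_value(tab2, 0), 0)
})

test_that("protocol breakpoints are reproduced exactly", {
  set.seed(3)
  times <- cumsum(runif(6, 0.5, 2))
  vals <- runif(6, 0, 1e4)
  tab <- make_protocol("table", table = cbind(times, vals))
  expect_equal(protocol_value(tab, times), vals)
})

test_that("invalid protocols are rejected", {
  expect_error(make_protocol("table", table = cbind(c(0, 1, 1), 1:3)),
               "strictly increasing")
  expect_error(make_protocol("ramp", p_max = 1, t_rise = 5, t_end = 2),
               "t_rise")
  expect_error(make_protocol("ramp", p_max = -1, t_rise = 1, t_end = 2),
               "p_max")
})

test_that("net pressure subtracts traces on the union grid", {
  pa <- cbind(c(0, 1), c(5, 6))
  pb <- cbind(c(0, 1), c(2, 2))
  np <- net_pressure(pa, pb)
  expect_equal(protocol_value(np, c(0, 1)), c(3, 4))
  expect_equal(np$label, "Pa-Pb")

  # identical traces cancel exactly
  z <- net_pressure(pa, pa)
  expect_equal(protocol_value(z, seq(0, 1, 0.1)), rep(0, 11))

  # single-point Pb interpolates constantly onto the union grid {0, 0.5, 1}
  np2 <- net_pressure(pa, cbind(0.5, 2))
  expect_equal(np2$table[, 1], c(0, 0.5, 1))
  expect_equal(protocol_value(np2, c(0, 0.5, 1)), c(3, 3.5, 4))

  # order swap flips the sign (and keeps the negatives, with a warning)
  expect_warning(np3 <- net_pressure(pb, pa, swap = FALSE), "negative")
  expect_equal(protocol_value(np3, 1), -4)
  expect_equal(attr(np3, "negative_count"), 2)

  expect_error(net_pressure(cbind(0:1, 1:2), cbind(5:6, 1:2)), "disjoint")
})

test_that("dilator comparison is symmetric and scale invariant", {
  mesh <- tiny_annulus()
  cfg <- quick_config(2, dt = 0.2)
  pa <- make_protocol("ramp", p_max = 8e3, t_rise = 0.5, t_end = 2,
                      label = "fast")
  pb <- make_protocol("ramp", p_max = 8e3, t_rise = 1.8, t_end = 2,
                      label = "slow")
  snap <- c(0.6, 1.4)
  cab <- compare_dilators(mesh, material(), pa, pb, cfg,
                          snapshot_times = snap, bc = canal_bc())
  cba <- compare_dilators(mesh, material(), pb, pa, cfg,
                          snapshot_times = snap, bc = canal_bc())
  expect_equal(cab$ratio, 1 / cba$ratio, tolerance = 1e-12)

  # identical protocols give ratio exactly 1
  cid <- compare_dilators(mesh, material(), pa, pa, cfg,
                          snapshot_times = snap, bc = canal_bc())
  expect_equal(cid$ratio[-1], rep(1, length(cid$ratio) - 1))

  # a common pressure scale cancels in the ratio (linear tissue model)
  c2 <- compare_dilators(mesh, material(), cervodil:::scale_protocol(pa, 3),
                         cervodil:::scale_protocol(pb, 3), cfg,
                         snapshot_times = snap, bc = canal_bc())
  expect_equal(c2$ratio[-1], cab$ratio[-1], tolerance = 1e-10)

  # zero protocols: ratio undefined and flagged as NA
  z <- make_protocol("ramp", p_max = 0, t_rise = 1, t_end = 2)
  c0 <- compare_dilators(mesh, material(), z, z, cfg, snapshot_times = snap)
  expect_true(all(is.na(c0$ratio)))
  expect_identical(max(c0$peak_vm_a), 0)
})
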