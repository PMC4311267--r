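# Integration, equilibration, and oscillation metrics.

test_that("trivial dynamics integrate exactly", {
  sys <- ode_system("x", c(a = 0), list(x = "a*x"), init = c(x = 5))
  tr <- integrate_system(sys, t_end = 10, dt = 1)
  expect_true(all(tr$states[, "x"] == 5))
  sys2 <- ode_system("x", c(a = 1), list(x = "a - x"))
  expect_equal(unname(equilibrate(sys2)["x"]), 1, tolerance = 1e-7)
})

test_that("period of a sampled sinusoid is recovered to sub-grid precision", {
  tr <- toy_sine_trajectory(period = 7, t_end = 100, dt = 0.01)
  m <- oscillation_metrics(tr, "x")
  expect_true(m$oscillatory)
  expect_equal(m$period_min, 7 / 60, tolerance = 1e-4)
  expect_equal(m$amplitude, 2, tolerance = 1e-3)
})

test_that("constant and unknown readouts are handled", {
  sys <- ode_system("x", c(a = 0), list(x = "a*x"), init = c(x = 1))
  tr <- integrate_system(sys, t_end = 100, dt = 1)
  m <- oscillation_metrics(tr, "x")
  expect_false(m$oscillatory)
  expect_error(oscillation_metrics(tr, "nope"), "nope")
})

test_that("integration restarts at protocol edges match one smooth run", {
  # with a constant-value "pulse" equal to the default, segment restarts are
  # pure bookkeeping and must not perturb the solution
  sys <- ode_system(c("x", "y"), c(a = 1, b = 0.1, k24 = 1),
                    list(x = "-a*x + k24*y", y = "b*x - y"),
                    inputs = "k24", init = c(x = 1, y = 0.5))
  smooth <- integrate_system(sys, protocol = protocol_constant("k24", 1),
                             t_end = 50, dt = 0.5,
                             rtol = 1e-11, atol = 1e-13)
  seg <- stimulus_protocol("k24",
                           data.frame(start = c(10, 30), end = c(20, 40),
                                      value = 1), default = 1)
  chopped <- integrate_system(sys, protocol = seg, t_end = 50, dt = 0.5,
                              rtol = 1e-11, atol = 1e-13)
  common <- intersect(smooth$times, chopped$times)
  i1 <- match(common, smooth$times); i2 <- match(common, chopped$times)
  expect_lt(max(abs(smooth$states[i1, ] - chopped$states[i2, ])), 1e-8)
})

test_that("waveform MSE is zero for identical and for period-rescaled waveforms", {
  trA <- toy_sine_trajectory(period = 7, t_end = 100, dt = 0.01)
  expect_equal(shape_mse(trA, trA, "x"), 0)
  trB <- toy_sine_trajectory(period = 11, t_end = 150, dt = 0.01)
  expect_lt(shape_mse(trA, trB, "x"), 1e-5)
  const <- toy_sine_trajectory(period = 7, t_end = 100)
  const$states[, "x"] <- 1
  expect_error(shape_mse(trA, const, "x"), "not oscillatory")
})

test_that("trajectory CSV export keeps times and variables", {
  sys <- ode_system("x", c(a = 1), list(x = "-a*x"), init = c(x = 1))
  tr <- integrate_system(sys, t_end = 5, dt = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("time", "x"))
  expect_equal(back$x, unname(tr$states[, "x"]))
})

test_that("total IKK bound holds along the stimulated solution", {
  traj <- sm_continuous_traj()
  k2 <- build_sm()$parameters[["k2"]]
  expect_true(all(traj$states[, "v"] + traj$states[, "w"] <= k2 + 1e-9))
  expect_true(all(traj$states >= -1e-9))
})
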