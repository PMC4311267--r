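# Newton equilibria, eigenvalue stability, Hopf localisation, envelopes.

test_that("Newton finds linear and nonlinear equilibria", {
  sys <- ode_system("x", c(a = 2, b = 6), list(x = "b - a*x"))
  eq <- find_equilibrium(sys, guess = c(x = 0))
  expect_equal(unname(eq["x"]), 3, tolerance = 1e-10)
  expect_error(find_equilibrium(sys, guess = c(x = NaN)), "non-finite")
  # two independent routes to the unstimulated steady state agree
  sm <- build_sm()
  eq1 <- equilibrate(sm)
  eq2 <- find_equilibrium(sm, param_overrides = c(k24 = 0), guess = eq1)
  expect_lt(max(abs(eq1 - eq2)), 1e-6)
})

test_that("the Hopf normal form bifurcates at zero", {
  sys <- ode_system(c("x", "y"), c(mu = 0),
                    list(x = "mu*x - y - x*(x^2 + y^2)",
                         y = "x + mu*y - y*(x^2 + y^2)"))
  hs <- hopf_scan(sys, "mu", c(-1, 1), n_grid = 21,
                  guess = c(x = 0, y = 0))
  expect_length(hs$hopf, 1)
  expect_equal(hs$hopf[[1]]$value, 0, tolerance = 1e-4)
  expect_equal(hs$hopf[[1]]$im, 1, tolerance = 1e-3)
  expect_identical(hs$hopf[[1]]$direction, "loss of stability")
})

test_that("real-eigenvalue crossings are reported as non-Hopf", {
  sys <- ode_system("x", c(mu = 0), list(x = "mu*x - x^3 - 0.001"))
  hs <- hopf_scan(sys, "mu", c(-1, 1), n_grid = 21, guess = c(x = 0))
  expect_length(hs$hopf, 0)
  expect_gte(length(hs$non_hopf), 1)
})

test_that("cycle envelope collapses to the equilibrium where stable", {
  sm <- build_sm()
  env <- cycle_envelope(sm, "k24", c(0.1, 0.2), readout = "r",
                        t_end = 30000, transient = 15000)
  expect_true(all(env$ok))
  expect_true(all(env$stable))
  expect_equal(env$cyc_min, env$equilibrium)
  expect_equal(env$cyc_max, env$equilibrium)
  expect_error(cycle_envelope(sm, "k24", c(0.3, 0.1)), "sorted")
})

test_that("the stimulated model has an unstable equilibrium with a limit cycle", {
  sm <- build_sm()
  env <- cycle_envelope(sm, "k24", c(0.3, 1), readout = "r",
                        t_end = 90000, transient = 45000)
  expect_true(all(env$ok))
  expect_true(env$stable[1])    # below the bifurcation
  expect_false(env$stable[2])   # saturating dose: limit cycle
  expect_lt(env$cyc_min[2], env$equilibrium[2])
  expect_gt(env$cyc_max[2], env$equilibrium[2])
})
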