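# The model zoo and stimulus protocols.

test_that("the simplified model has the documented structure", {
  sm <- build_sm()
  expect_length(sm$variables, 10)
  expect_setequal(sm$variables,
                  c("p", "q", "r", "s", "u", "v", "w", "x", "y", "z"))
  expect_identical(sm$inputs, "k24")
  # without stimulus the active-IKK equation is pure decay
  dw <- expr_substitute(sm$rhs$w, list(k24 = 0))
  expect_expr_equal(expr_simplify(dw), "-k23*w", fixed = sm$parameters)
  # free NF-kB forms never exceed the conserved total along the solution
  traj <- sm_continuous_traj()
  p <- sm$parameters
  d <- p[["k3"]] - traj$states[, "p"] - traj$states[, "z"] -
    traj$states[, "r"] / p[["k1"]]
  expect_true(all(d > 0 & d < p[["k3"]]))
})

test_that("minimal-model builders give the documented dimensions and substitutions", {
  m4 <- build_minimal_continuous()
  expect_identical(m4$lineage, "z0p0y0v0s0w1")
  expect_setequal(m4$variables, c("q", "r", "u", "x"))
  m4p <- build_minimal_continuous(as_printed = TRUE)
  expect_setequal(m4p$variables, c("q", "r", "u", "x"))
  m6 <- build_minimal_pulsed()
  expect_identical(m6$lineage, "z0p0y0w0")
  expect_setequal(m6$variables, c("q", "r", "s", "u", "v", "x"))
  # active-IKK and A20 substitutions of the pulsed model
  subs <- setNames(lapply(m6$substitutions, `[[`, "expr"),
                   vapply(m6$substitutions, `[[`, "", "variable"))
  expect_expr_equal(subs$w, "k24*k22*v/k23", fixed = m6$parameters)
  expect_expr_equal(subs$y, "k10*x/k12", fixed = m6$parameters)
  # the nuclear-IkBa equation keeps its cytoplasmic-IkBa source by default
  expect_true("q" %in% all.vars(m6$rhs$s))
  m6t <- build_minimal_pulsed(fix_typo = FALSE)
  expect_setequal(m6t$variables, m6$variables)
})

test_that("standard protocols have the documented schedule", {
  pr <- build_protocols(t_end = 60000)
  expect_identical(protocol_value(pr$continuous, c(0, 1e5)), c(1, 1))
  expect_identical(protocol_value(pr$pulsed, c(0, 100, 299)), c(1, 1, 1))
  expect_identical(protocol_value(pr$pulsed, c(300, 5999)), c(0, 0))
  expect_identical(protocol_value(pr$pulsed, 6000), 1)
  # duty cycle 5 min / 100 min
  seg <- pr$pulsed$segments
  expect_true(all(seg$end - seg$start == 300))
  expect_true(all(diff(seg$start) == 6000))
  edges <- protocol_edges(pr$pulsed, 12000)
  expect_identical(edges, c(300, 6000, 6300))
})

test_that("overlapping or inverted protocol segments are rejected", {
  expect_error(stimulus_protocol("k24",
                                 data.frame(start = c(0, 50), end = c(100, 150),
                                            value = 1)), "overlap")
  expect_error(stimulus_protocol("k24",
                                 data.frame(start = 10, end = 5, value = 1)),
               "end <= start")
})

test_that("fast-slow toy system matches its analytic slow manifold", {
  toy <- build_toy_tikhonov(0.05)
  cc <- attr(toy, "slow_rate")
  expect_equal(cc, 1 + 0.05 + 2 * 0.05^2, tolerance = 1e-3)
  # starting on the manifold, x decays at exactly the slow rate
  tr <- integrate_system(toy, t_end = 3, dt = 0.01,
                         rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(tr$states[, "x"] - exp(-cc * tr$times))), 1e-8)
  # derived reduced models have the closed-form rates
  r0 <- reduce_once(toy, "z", 0L)
  expect_expr_equal(r0$rhs$x, "-x", fixed = toy$parameters)
  r1 <- reduce_once(toy, "z", 1L)
  expect_expr_equal(r1$rhs$x, "-(1 + eps)*x", fixed = toy$parameters)
})
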