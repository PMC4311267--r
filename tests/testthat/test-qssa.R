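# Affine decomposition, quasi-steady-state expressions, single reduction
# steps, and the derived closed forms of the NF-kB minimal models.

test_that("affine decomposition extracts alpha and beta", {
  sm <- build_sm()
  # nuclear-IkBa balance: ds/dt = k13*k1*q - (k4*r + k8 + k14*k1) s
  pr <- affine_decompose(sm, "s")
  expect_expr_equal(pr$alpha, "k13*k1*q", fixed = sm$parameters)
  expect_expr_equal(pr$beta, "k4*r + k8 + k14*k1", fixed = sm$parameters)
  # phospho-complex: dz/dt = k18*w*(k3 - p - r/k1) - k19*z
  pz <- affine_decompose(sm, "z")
  expect_expr_equal(pz$alpha, "k18*w*(k3 - p - r/k1)", fixed = sm$parameters)
  expect_expr_equal(pz$beta, "k19", fixed = sm$parameters)
})

test_that("nonlinear or degenerate equations are rejected", {
  quad <- ode_system("x", c(a = 1), list(x = "-a*x^2"))
  expect_error(affine_decompose(quad, "x"), "nonlinear")
  drift <- ode_system("x", c(a = 1), list(x = "a"))
  expect_error(affine_decompose(drift, "x"), "beta")
  expect_error(affine_decompose(build_sm(), "nope"), "not a dynamic")
})

test_that("total time derivatives follow the chain rule", {
  sys <- ode_system("x", c(a = 1), list(x = "-a*x"))
  expect_identical(total_time_derivative("3.5", sys), 0)
  # identity: d/dt of x is the rhs itself
  expect_expr_equal(total_time_derivative("x", sys), "-a*x")
  # chain rule: d/dt of x^2 = 2x * (-x) = -2x^2 at a = 1
  expect_expr_equal(total_time_derivative("x^2", sys), "2*x*(-a*x)")
  expect_error(total_time_derivative("x + q", sys), "q")
})

test_that("constant affine pairs have vanishing first-order correction", {
  sys <- ode_system(c("x", "z"), c(a = 2, b = 3),
                    list(x = "-x", z = "a - b*z"))
  pr <- affine_decompose(sys, "z")
  s0 <- qssa_expression(pr, 0L)
  red0 <- reduce_once(sys, "z", 0L)
  s1 <- qssa_expression(pr, 1L, deriv_sys = red0)
  expect_expr_equal(s0$expr, "a/b")
  expect_expr_equal(s1$expr, "a/b")
})

test_that("single reduction steps shrink the system and extend the label", {
  sm <- build_sm()
  red <- reduce_once(sm, "z", 0L)
  expect_identical(length(red$variables), length(sm$variables) - 1L)
  expect_identical(red$lineage, "z0")
  expect_false("z" %in% red$variables)
  red2 <- reduce_once(red, "p", 1L)
  expect_identical(red2$lineage, "z0p1")
  expect_error(reduce_once(red, "z"), "not a dynamic")
  # eliminated variable no longer appears in any rhs
  for (v in red2$variables) {
    expect_false(any(c("z", "p") %in% all.vars(red2$rhs[[v]])))
  }
})

test_that("reduction preserves the solution when the variable is truly fast", {
  # stiff linear pair: z relaxes 1000x faster than x moves
  sys <- ode_system(c("x", "z"), c(kf = 1000),
                    list(x = "z - x", z = "kf*(x - z)"),
                    init = c(x = 1, z = 1))
  red <- reduce_once(sys, "z", 0L)
  trf <- integrate_system(sys, t_end = 5, dt = 0.01,
                          rtol = 1e-10, atol = 1e-12)
  trr <- integrate_system(red, t_end = 5, dt = 0.01,
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(trf$states[, "x"] - trr$states[, "x"])), 2e-3)
})

test_that("derived nuclear-IkBa and cytoplasmic-NF-kB substitutions match the printed closed forms", {
  sm <- build_sm()
  m4 <- reduce_sequence(sm, c("z", "p", "y", "v"), orders = 0L)
  sbar <- qssa_expression(affine_decompose(m4, "s"), 0L)$expr
  expect_expr_equal(sbar, "k1*k13*q/(k4*r + k1*k14 + k8)",
                    fixed = sm$parameters)
  mz <- reduce_once(sm, "z", 0L)
  pbar <- qssa_expression(affine_decompose(mz, "p"), 0L)$expr
  expect_expr_equal(pbar, "(k16*r + k18*w*(k3 - r/k1))/(k4*q + k15 + k18*w)",
                    fixed = sm$parameters)
})

test_that("derived first-order active-IKK substitution has the rational + correction structure", {
  sm <- build_sm()
  m5 <- reduce_sequence(sm, c("z", "p", "y", "v", "s"), orders = 0L)
  w1 <- reduce_once(m5, "w", 1L)
  sub <- w1$substitutions[[length(w1$substitutions)]]
  pars <- names(sm$parameters)
  expect_identical(sort(setdiff(all.vars(sub$expr0), pars)), "x")
  expect_identical(sort(setdiff(all.vars(sub$expr), pars)), c("r", "x"))
  # correction term is proportional to dx/dt: the ratio depends on x only
  ratio <- function(r, x) {
    b <- c(as.list(sm$parameters), list(r = r, x = x))
    fx <- expr_eval(parse_expr("k9*r^h/(r^h + k^h) - k11*x"), b)
    (expr_eval(sub$expr, b) - expr_eval(sub$expr0, b)) / fx
  }
  expect_equal(ratio(0.01, 1e-4), ratio(0.15, 1e-4), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(ratio(0.01, 1e-4), ratio(0.01, 3e-4),
                                tolerance = 1e-4)))
})

test_that("lineage nomenclature reproduces the published model names", {
  sm <- build_sm()
  mA <- reduce_sequence(sm, c("z", "p", "y", "v", "s", "w"),
                        orders = c(0, 0, 0, 0, 0, 1))
  expect_identical(mA$lineage, "z0p0y0v0s0w1")
  mB <- reduce_sequence(sm, c("z", "p", "y", "w"), orders = 0L)
  expect_identical(mB$lineage, "z0p0y0w0")
})

test_that("comparing a model against itself gives unit folds and zero MSE", {
  sm <- build_sm()
  cmp <- compare_models(sm, sm, protocol_constant("k24", 1), readout = "r",
                        traj_full = sm_continuous_traj())
  expect_equal(cmp$period_fold, 1, tolerance = 1e-6)
  expect_equal(cmp$amplitude_fold, 1, tolerance = 1e-6)
  expect_equal(cmp$shape_mse, 0, tolerance = 1e-12)
})

test_that("zero-step reduction returns just the root", {
  sm <- build_sm()
  lin <- reduce_iteratively(sm, protocol_constant("k24", 1), n_steps = 0)
  expect_length(lin$steps, 0)
  expect_identical(model_label(lin$root), "SM")
  expect_error(reduce_iteratively(sm, protocol_constant("k24", 1),
                                  n_steps = 10), "smaller")
})
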