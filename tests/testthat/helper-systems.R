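# Small systems used across tests; everything is built in code.

# n independent linear decays dx_i/dt = -rate_i * x_i
toy_decays <- function(rates) {
  vars <- paste0("x", seq_along(rates))
  pars <- setNames(rates, paste0("c", seq_along(rates)))
  rhs <- setNames(lapply(seq_along(rates), function(i)
    parse_expr(paste0("-c", i, "*x", i))), vars)
  ode_system(variables = vars, parameters = pars, rhs = rhs,
             label = "decays", init = setNames(rep(1, length(rates)), vars))
}

# conserved exchange pair: dx/dt = -kf*x + kf*y, dy/dt = kf*x - kf*y
toy_conserved_pair <- function(kf = 2) {
  ode_system(variables = c("x", "y"),
             parameters = c(kf = kf, Ctot = 1),
             rhs = list(x = "-kf*x + kf*y", y = "kf*x - kf*y"),
             label = "pair", init = c(x = 1, y = 0))
}

# damped-oscillator readout for peak detection: x follows sin with period P
toy_sine_trajectory <- function(period = 7, t_end = 100, dt = 0.01) {
  sys <- ode_system(variables = "x", parameters = c(a = 1),
                    rhs = list(x = "0*x"), label = "sine")
  t <- seq(0, t_end, by = dt)
  structure(list(times = t,
                 states = matrix(sin(2 * pi * t / period),
                                 dimnames = list(NULL, "x")),
                 input = rep(NA_real_, length(t)),
                 protocol = NULL, system = sys),
            class = "ode_trajectory")
}

expect_expr_equal <- function(e1, e2, ...) {
  if (is.character(e1)) e1 <- parse_expr(e1)
  if (is.character(e2)) e2 <- parse_expr(e2)
  expect_true(expr_identical_num(e1, e2, ...))
}
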