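# Model zoo: the 10-variable simplified NF-kB/IkBa/A20 oscillator, its
# published minimal reductions, the stimulus protocols, and a linear
# fast-slow toy system with a closed-form slow manifold for convergence
# oracles.
#
# Short names: p cytoplasmic NF-kB, q cytoplasmic IkBa, r nuclear NF-kB,
# s nuclear IkBa, u IkBa mRNA, v neutral IKK, w active IKK, x A20 mRNA,
# y A20 protein, z phospho-IkBa:NF-kB complex. k24 is the TNFa stimulus
# switch (1 = saturating dose, 0 = off). Units: seconds and µM throughout;
# periods are reported in minutes by the metrics layer.

nfkb_parameters <- function() {
  c(k1 = 3.3, k2 = 0.08, k3 = 0.08, k4 = 0.5,
    k5 = 1.4e-7, k6 = 0.5, k7 = 0.0003, k8 = 0.0005,
    k9 = 1.4e-7, k10 = 0.5, k11 = 0.00048, k12 = 0.0045,
    k13 = 0.00067, k14 = 3.35e-4, k15 = 0.0026, k16 = 0.000052,
    k17 = 0.074, k18 = 0.37, k19 = 0.1, k20 = 0.0006,
    k21 = 0.0018, k22 = 0.004, k23 = 0.003, k24 = 1,
    k = 0.065, h = 2)
}

nfkb_units <- function() {
  c(k1 = "1", k2 = "uM", k3 = "uM", k4 = "1/(uM s)",
    k5 = "uM/s", k6 = "1/s", k7 = "1/s", k8 = "1/s",
    k9 = "uM/s", k10 = "1/s", k11 = "1/s", k12 = "1/s",
    k13 = "1/s", k14 = "1/s", k15 = "1/s", k16 = "1/s",
    k17 = "1/s", k18 = "1/s", k19 = "1/s", k20 = "1/s",
    k21 = "uM", k22 = "1/s", k23 = "1/s", k24 = "1",
    k = "uM", h = "1")
}

# Reference initial conditions: the unstimulated steady state of the
# original 14-variable two-feedback model, to printed precision.
nfkb_init <- function() {
  c(p = 3.81e-3, q = 1.58e-2, r = 9.79e-3, s = 5.44e-3, u = 2.07e-5,
    v = 0.08, w = 0, x = 6.46e-6, y = 7.19e-4, z = 0)
}

#' Build the 10-variable simplified NF-kB model
#'
#' The two-feedback NF-kB/IkBa/A20 oscillator after elimination of the
#' conserved IKK and NF-kB moieties, the decoupled phospho-IkBa pool, and
#' the consistently small nuclear complex terms. Under continuous
#' stimulation (`k24 = 1`) it sustains nuclear-to-cytoplasmic oscillations
#' with a period of roughly 100 minutes.
#'
#' @return An [ode_system()] with dynamic variables p, q, r, s, u, v, w, x,
#'   y, z; `k24` declared as the stimulus input. The attribute
#'   `equilibrate_overrides` carries the unstimulated-equilibration seeds
#'   (v at total IKK `k2`, r at `k1*k3`).
#' @export
build_sm <- function() {
  rhs <- list(
    p = "k19*z - k4*q*p - k15*p + k16*r",
    q = "-k4*q*p + k6*u - k8*q - k13*q + k14*s - k17*w*q",
    r = "k15*k1*p - k4*s*r - k16*k1*r",
    s = "k13*k1*q - k4*s*r - k8*s - k14*k1*s",
    u = "k5*r^h/(r^h + k^h) - k7*u",
    v = "k20*(k21/(k21 + k24*y))*(k2 - v) - k24*k22*v",
    w = "k24*k22*v - k23*w",
    x = "k9*r^h/(r^h + k^h) - k11*x",
    y = "k10*x - k12*y",
    z = "k18*w*(k3 - p - r/k1) - k19*z")
  sys <- ode_system(variables = names(rhs),
                    parameters = nfkb_parameters(),
                    rhs = rhs, inputs = "k24",
                    label = "SM", init = nfkb_init(),
                    units = nfkb_units())
  attr(sys, "equilibrate_overrides") <-
    c(v = unname(sys$parameters["k2"]),
      r = unname(sys$parameters["k1"] * sys$parameters["k3"]))
  sys
}

#' Build the 4-variable minimal model for continuous stimulation
#'
#' The end point of the continuous-input reduction: z, p, y, v, s eliminated
#' at zeroth order and w at first order, leaving dynamic variables q, r, u,
#' x. By default the substitution chain is derived algorithmically from
#' [build_sm()]; `as_printed = TRUE` instead uses the published closed-form
#' constants for the active-IKK substitution, which are retained verbatim as
#' a documented, non-authoritative variant.
#'
#' @param as_printed Use the literal published active-IKK closed form.
#' @return An [ode_system()] with variables q, r, u, x.
#' @export
build_minimal_continuous <- function(as_printed = FALSE) {
  if (!as_printed) {
    sys <- reduce_sequence(build_sm(), c("z", "p", "y", "v", "s", "w"),
                           orders = c(0L, 0L, 0L, 0L, 0L, 1L))
    attr(sys, "equilibrate_overrides") <-
      c(r = unname(sys$parameters["k1"] * sys$parameters["k3"]))
    return(sys)
  }
  # literal published variant: wbar = A/B(x) + k24^2 k22 k10 A (dx/dt)/B^2,
  # A = k24 k22 k20 k21 k12 k3, B = k20 k21 k12 + k24 k22 k21 k12
  #     + k24^2 k22 k10 k23 x
  p <- nfkb_parameters()
  A <- "(k24*k22*k20*k21*k12*k3)"
  B <- "(k20*k21*k12 + k24*k22*k21*k12 + k24^2*k22*k10*k23*x)"
  wbar <- paste0(A, "/", B,
                 " + k24^2*k22*k10*", A,
                 "*(k9*r^h/(r^h + k^h) - k11*x)/", B, "^2")
  sbar <- "k1*k13*q/(k4*r + k1*k14 + k8)"
  pbar <- paste0("(k16*r + k18*(", wbar, ")*(k3 - r/k1))",
                 "/(k4*q + k15 + k18*(", wbar, "))")
  rhs <- list(
    q = paste0("-k4*q*(", pbar, ") + k6*u - k8*q - k13*q + k14*(", sbar,
               ") - k17*(", wbar, ")*q"),
    r = paste0("k15*k1*(", pbar, ") - k4*(", sbar, ")*r - k16*k1*r"),
    u = "k5*r^h/(r^h + k^h) - k7*u",
    x = "k9*r^h/(r^h + k^h) - k11*x")
  subs <- list(
    list(variable = "w", order = 1L, expr = parse_expr(wbar),
         alpha = NULL, beta = NULL),
    list(variable = "s", order = 0L, expr = parse_expr(sbar),
         alpha = NULL, beta = NULL),
    list(variable = "p", order = 0L, expr = parse_expr(pbar),
         alpha = NULL, beta = NULL))
  init <- nfkb_init()[c("q", "r", "u", "x")]
  sys <- ode_system(variables = c("q", "r", "u", "x"), parameters = p,
                    rhs = rhs, inputs = "k24", substitutions = subs,
                    label = "SM", lineage = "z0p0y0v0s0w1_printed",
                    init = init, units = nfkb_units())
  attr(sys, "equilibrate_overrides") <- c(r = unname(p["k1"] * p["k3"]))
  sys
}

#' Build the 6-variable minimal model for pulsed stimulation
#'
#' The alternative reduction obtained with the periodically pulsed stimulus
#' as the representative solution: z, p, y, then the *active* IKK `w`
#' eliminated at zeroth order, leaving q, r, s, u, v, x. The neutral IKK
#' `v` stays dynamic, which is what lets this variant entrain 1:1 to
#' 100-minute stimulus pulses where the continuous-input reduction
#' (`v` eliminated) responds with a doubled period.
#'
#' By default the chain is derived algorithmically, under which the nuclear
#' IkBa balance keeps its cytoplasmic-IkBa (`q`) import term.
#' `fix_typo = FALSE` reproduces the published system literally, whose
#' nuclear-IkBa equation carries the cytoplasmic NF-kB substitution in place
#' of `q`; both variants are retained so the discrepancy is testable.
#'
#' @param fix_typo Use the algorithmically derived nuclear-IkBa equation
#'   (default) instead of the literal published one.
#' @return An [ode_system()] with variables q, r, s, u, v, x.
#' @export
build_minimal_pulsed <- function(fix_typo = TRUE) {
  if (fix_typo) {
    sys <- reduce_sequence(build_sm(), c("z", "p", "y", "w"), orders = 0L)
    attr(sys, "equilibrate_overrides") <-
      c(v = unname(sys$parameters["k2"]),
        r = unname(sys$parameters["k1"] * sys$parameters["k3"]))
    return(sys)
  }
  p <- nfkb_parameters()
  wbar <- "(k24*k22*v/k23)"
  ybar <- "(k10*x/k12)"
  pbar <- paste0("((k16*r*k1 + k18*", wbar, "*k3*k1 - k18*", wbar,
                 "*r)/(k1*(k4*q + k15 + k18*", wbar, ")))")
  rhs <- list(
    q = paste0("-k4*q*", pbar, " + k6*u - k8*q - k13*q + k14*s - k17*",
               wbar, "*q"),
    r = paste0("k15*k1*", pbar, " - k4*s*r - k16*k1*r"),
    s = paste0("k13*k1*", pbar, " - k4*s*r - k8*s - k14*k1*s"),
    u = "k5*r^h/(r^h + k^h) - k7*u",
    v = paste0("k20*(k21/(k21 + k24*", ybar, "))*(k2 - v) - k24*k22*v"),
    x = "k9*r^h/(r^h + k^h) - k11*x")
  subs <- list(
    list(variable = "z", order = 0L,
         expr = parse_expr(paste0("k18*", wbar, "*(k3 - ", pbar,
                                  " - r/k1)/k19")),
         alpha = NULL, beta = NULL),
    list(variable = "p", order = 0L, expr = parse_expr(pbar),
         alpha = NULL, beta = NULL),
    list(variable = "y", order = 0L, expr = parse_expr(ybar),
         alpha = NULL, beta = NULL),
    list(variable = "w", order = 0L, expr = parse_expr(wbar),
         alpha = NULL, beta = NULL))
  init <- nfkb_init()[c("q", "r", "s", "u", "v", "x")]
  sys <- ode_system(variables = c("q", "r", "s", "u", "v", "x"),
                    parameters = p, rhs = rhs, inputs = "k24",
                    substitutions = subs, label = "SM",
                    lineage = "z0p0y0w0_printed",
                    init = init, units = nfkb_units())
  attr(sys, "equilibrate_overrides") <-
    c(v = unname(p["k2"]), r = unname(p["k1"] * p["k3"]))
  sys
}

#' Standard stimulus protocols
#'
#' `continuous`: the stimulus switch held at 1. `pulsed`: 5-minute pulses of
#' 1 delivered every 100 minutes on a baseline of 0, starting at t = 0.
#'
#' @param t_end Schedule horizon for the pulsed protocol (s).
#' @return List with elements `continuous` and `pulsed`.
#' @export
build_protocols <- function(t_end = 6e5) {
  list(continuous = protocol_constant("k24", 1),
       pulsed = protocol_pulsed("k24", width = 300, period = 6000,
                                t_end = t_end))
}

#' Linear fast-slow toy system with a closed-form slow manifold
#'
#' The pair `dx/dt = -z`, `dz/dt = (x - z)/eps` relaxes onto the exact slow
#' manifold `z = c(eps) x` with `c = (1 - sqrt(1 - 4 eps)) / (2 eps)
#' = 1 + eps + 2 eps^2 + ...`, so the slow decay rate is known in closed
#' form. The zeroth-order quasi-steady-state reduction gives `dx/dt = -x`
#' (rate error O(eps)); the first-order reduction gives
#' `dx/dt = -(1 + eps) x` (rate error O(eps^2)). Initial conditions start
#' exactly on the slow manifold so the comparison isolates the
#' approximation-order error.
#'
#' @param eps Time-scale separation parameter (0 < eps < 1/4).
#' @return An [ode_system()] with variables x, z; the attribute
#'   `slow_rate` carries the exact slow decay rate `c(eps)`.
#' @export
build_toy_tikhonov <- function(eps = 0.01) {
  stopifnot(eps > 0, eps < 0.25)
  cc <- (1 - sqrt(1 - 4 * eps)) / (2 * eps)
  sys <- ode_system(variables = c("x", "z"),
                    parameters = c(eps = eps),
                    rhs = list(x = "-z", z = "(x - z)/eps"),
                    label = sprintf("toy_fast_slow_eps%g", eps),
                    init = c(x = 1, z = cc))
  attr(sys, "slow_rate") <- cc
  sys
}

#' Load a packaged model fixture by name
#'
#' Parses one of the model definition files shipped under `extdata`
#' (currently `"sm"`, `"minimal_continuous_printed"`,
#' `"minimal_pulsed_printed"`).
#'
#' @param name Fixture name without extension.
#' @return An [ode_system()].
#' @export
load_model_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".model"),
                      package = "speedred")
  if (!nzchar(path)) stop("no packaged fixture named '", name, "'",
                          call. = FALSE)
  parse_model(path)
}
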