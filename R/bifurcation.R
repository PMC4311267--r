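# Equilibrium tracking, Jacobian eigenvalue analysis, Hopf-point bisection,
# and limit-cycle envelope scans over a parameter.

# Symbolic Jacobian (list of rows of language objects), computed once.
symbolic_jacobian <- function(sys) {
  lapply(sys$variables, function(vi)
    lapply(sys$variables, function(vj) expr_deriv(sys$rhs[[vi]], vj)))
}

eval_jacobian <- function(sys, jac, state, param_overrides = NULL) {
  pars <- sys$parameters
  if (!is.null(param_overrides)) pars[names(param_overrides)] <- param_overrides
  bind <- c(as.list(pars), as.list(setNames(as.numeric(state), sys$variables)))
  n <- length(sys$variables)
  J <- matrix(0, n, n, dimnames = list(sys$variables, sys$variables))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    J[i, j] <- expr_eval(jac[[i]][[j]], bind)
  }
  J
}

#' Find an equilibrium by damped Newton iteration
#'
#' Solves `f(x) = 0` with the symbolic Jacobian, halving the step while the
#' residual does not decrease.
#'
#' @param sys An [ode_system()].
#' @param param_overrides Named numeric of parameter values for this solve
#'   (e.g. the bifurcation parameter).
#' @param guess Named or ordered numeric starting point.
#' @param tol Residual tolerance on `max |f_i|`.
#' @param maxit Iteration cap.
#' @return Named numeric equilibrium with attributes `jacobian` (numeric
#'   matrix) and `eigenvalues`.
#' @export
find_equilibrium <- function(sys, param_overrides = NULL, guess,
                             tol = 1e-12, maxit = 200L) {
  x <- setNames(as.numeric(if (is.null(names(guess))) guess
                           else guess[sys$variables]), sys$variables)
  if (any(!is.finite(x))) stop("non-finite starting guess", call. = FALSE)
  jac <- symbolic_jacobian(sys)
  fval <- eval_rhs(sys, x, param_overrides)
  res <- max(abs(fval))
  for (it in seq_len(maxit)) {
    if (res < tol) break
    J <- eval_jacobian(sys, jac, x, param_overrides)
    step <- tryCatch(solve(J, fval), error = function(e)
      stop("singular Jacobian in Newton iteration", call. = FALSE))
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- eval_rhs(sys, xn, param_overrides)
      rn <- max(abs(fn))
      if (is.finite(rn) && (rn < res || lam < 1e-8)) break
      lam <- lam / 2
    }
    if (!is.finite(rn) || rn >= res) {
      stop("Newton iteration stalled (residual ", signif(res, 3), ")",
           call. = FALSE)
    }
    x <- xn; fval <- fn; res <- rn
  }
  if (res >= tol) {
    stop("Newton did not converge: residual ", signif(res, 3), call. = FALSE)
  }
  J <- eval_jacobian(sys, jac, x, param_overrides)
  attr(x, "jacobian") <- J
  attr(x, "eigenvalues") <- eigen(J, only.values = TRUE)$values
  x
}

# Continue an equilibrium from (from_value, state) to to_value by Newton
# steps along a parameter ramp, halving the step on failure.
continue_equilibrium <- function(sys, param, state, from_value, to_value,
                                 max_halvings = 12L) {
  if (from_value == to_value) {
    return(find_equilibrium(sys, setNames(from_value, param), state))
  }
  value <- from_value
  step <- (to_value - from_value)
  halvings <- 0L
  while (value != to_value) {
    target <- if (abs(step) >= abs(to_value - value)) to_value else
      value + step
    eq <- tryCatch(find_equilibrium(sys, setNames(target, param), state),
                   error = function(e) NULL)
    if (is.null(eq)) {
      halvings <- halvings + 1L
      if (halvings > max_halvings) {
        stop("equilibrium continuation failed between ", param, " = ",
             value, " and ", target, call. = FALSE)
      }
      step <- step / 2
      next
    }
    state <- eq
    value <- target
  }
  state
}

# Default equilibrium seed for a scan starting at value v1: relax the system
# there when the branch is stable; otherwise ramp the parameter up from rest.
# (The rest state of the NF-kB models is non-hyperbolic, so plain Newton
# cannot start from it; integration-based relaxation can.)
scan_seed <- function(sys, param, v1) {
  direct <- tryCatch({
    if (param %in% sys$inputs) equilibrate(sys, input_value = v1)
    else equilibrate(set_parameters(sys, setNames(v1, param)))
  }, error = function(e) NULL)
  if (!is.null(direct)) {
    return(find_equilibrium(sys, setNames(v1, param), direct))
  }
  rest <- equilibrate(sys, input_value = 0)
  from <- if (param %in% sys$inputs) 0 else sys$parameters[[param]]
  continue_equilibrium(sys, param, rest, from, v1)
}

# Max real part over eigenvalues, plus the imaginary part of the dominant one.
dominant_eig <- function(eigs) {
  i <- which.max(Re(eigs))
  c(re = Re(eigs[i]), im = abs(Im(eigs[i])))
}

#' Scan a parameter for Hopf bifurcations of the equilibrium branch
#'
#' Continues the equilibrium over a grid (each solution seeding the next
#' guess), tracks the maximal real part of the Jacobian eigenvalues, and
#' refines every sign change by bisection. A crossing is classified as a
#' Hopf point when the dominant eigenvalue pair is complex
#' (`|Im| > 1e-6` 1/s) at the crossing; real-eigenvalue crossings are
#' reported separately as non-Hopf.
#'
#' @param sys An [ode_system()].
#' @param param Parameter name (e.g. `"k24"`).
#' @param range Length-2 numeric, scan interval.
#' @param n_grid Grid size.
#' @param guess Equilibrium guess at `range[1]`; defaults to
#'   [equilibrate()] of the system with the stimulus input at `range[1]`.
#' @param bisect_tol Bisection stops at `|dparam| <` this.
#' @return List with `hopf` (list of located points: `param`, `value`,
#'   `bracket`, `im`, `direction`), `non_hopf` (real crossings), and `scan`
#'   (data.frame param, max_re, im, stable).
#' @export
hopf_scan <- function(sys, param, range, n_grid = 80L, guess = NULL,
                      bisect_tol = 1e-4) {
  stopifnot(length(range) == 2L, range[2] > range[1])
  grid <- seq(range[1], range[2], length.out = n_grid)
  if (is.null(guess)) guess <- scan_seed(sys, param, range[1])
  eq_at <- function(v, seed) {
    find_equilibrium(sys, setNames(v, param), seed)
  }
  scan <- data.frame(param = grid, max_re = NA_real_, im = NA_real_,
                     stable = NA)
  eqs <- vector("list", n_grid)
  seed <- guess
  for (i in seq_len(n_grid)) {
    eq <- tryCatch(eq_at(grid[i], seed), error = function(e) NULL)
    if (is.null(eq)) {
      warning("equilibrium continuation lost at ", param, " = ", grid[i])
      scan <- scan[seq_len(i - 1L), ]
      break
    }
    d <- dominant_eig(attr(eq, "eigenvalues"))
    scan$max_re[i] <- d["re"]; scan$im[i] <- d["im"]
    scan$stable[i] <- d["re"] < 0
    eqs[[i]] <- eq
    seed <- eq
  }
  hopf <- list(); non_hopf <- list()
  for (i in seq_len(nrow(scan) - 1L)) {
    if (is.na(scan$max_re[i]) || is.na(scan$max_re[i + 1L])) next
    # a grid point landing exactly on the crossing is its own bracket
    if (scan$max_re[i] == 0) {
      d <- dominant_eig(attr(eqs[[i]], "eigenvalues"))
      prev_re <- if (i > 1L) scan$max_re[i - 1L] else -scan$max_re[i + 1L]
      rec <- list(param = param, value = scan$param[i],
                  bracket = rep(scan$param[i], 2L),
                  re = unname(d["re"]), im = unname(d["im"]),
                  equilibrium = eqs[[i]],
                  direction = if (prev_re < 0) "loss of stability"
                              else "gain of stability")
      if (d["im"] > 1e-6) hopf[[length(hopf) + 1L]] <- rec
      else non_hopf[[length(non_hopf) + 1L]] <- rec
      next
    }
    if (scan$max_re[i] * scan$max_re[i + 1L] < 0) {
      lo <- scan$param[i]; hi <- scan$param[i + 1L]
      seed <- eqs[[i]]
      re_lo <- scan$max_re[i]
      while (hi - lo > bisect_tol) {
        mid <- (lo + hi) / 2
        eq <- eq_at(mid, seed)
        d <- dominant_eig(attr(eq, "eigenvalues"))
        if (sign(d["re"]) == sign(re_lo)) {
          lo <- mid; re_lo <- d["re"]
        } else hi <- mid
        seed <- eq
      }
      crit <- (lo + hi) / 2
      eq <- eq_at(crit, seed)
      d <- dominant_eig(attr(eq, "eigenvalues"))
      rec <- list(param = param, value = crit,
                  bracket = c(scan$param[i], scan$param[i + 1L]),
                  re = unname(d["re"]), im = unname(d["im"]),
                  equilibrium = eq,
                  direction = if (scan$max_re[i] < 0) "loss of stability"
                              else "gain of stability")
      if (d["im"] > 1e-6) hopf[[length(hopf) + 1L]] <- rec
      else non_hopf[[length(non_hopf) + 1L]] <- rec
    }
  }
  structure(list(hopf = hopf, non_hopf = non_hopf, scan = scan,
                 param = param),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  cat("<hopf_scan> over ", x$param, " in [",
      min(x$scan$param), ", ", max(x$scan$param), "]\n", sep = "")
  if (length(x$hopf)) {
    for (h in x$hopf) {
      cat(sprintf("  Hopf at %s = %.4f (Im = %.3g 1/s, %s)\n",
                  x$param, h$value, h$im, h$direction))
    }
  } else cat("  no Hopf point located\n")
  if (length(x$non_hopf)) {
    cat("  plus", length(x$non_hopf), "real-eigenvalue crossing(s)\n")
  }
  invisible(x)
}

#' Limit-cycle envelope over a parameter
#'
#' For each parameter value: locate the equilibrium and its stability; when
#' unstable, integrate from a slightly perturbed equilibrium, discard the
#' transient, and record the min/max of the readout over the remaining
#' window.
#'
#' @param sys An [ode_system()].
#' @param param Parameter name.
#' @param values Sorted numeric vector of parameter values.
#' @param readout Readout variable.
#' @param guess Equilibrium guess at `values[1]`.
#' @param t_end,transient Integration horizon and discard window (s).
#' @param dt Reporting step (s).
#' @return Data frame: param, equilibrium readout, stable, cyc_min, cyc_max,
#'   ok (FALSE where the point failed).
#' @export
cycle_envelope <- function(sys, param, values, readout = "r", guess = NULL,
                           t_end = 180000, transient = 90000, dt = 20) {
  if (is.unsorted(values)) stop("values must be sorted", call. = FALSE)
  if (is.null(guess)) guess <- scan_seed(sys, param, values[1])
  out <- data.frame(param = values, equilibrium = NA_real_, stable = NA,
                    cyc_min = NA_real_, cyc_max = NA_real_, ok = FALSE)
  seed <- guess
  for (i in seq_along(values)) {
    res <- tryCatch({
      eq <- find_equilibrium(sys, setNames(values[i], param), seed)
      seed <- eq
      d <- dominant_eig(attr(eq, "eigenvalues"))
      stable <- d["re"] < 0
      row <- list(equilibrium = unname(eq[readout]), stable = unname(stable))
      if (stable) {
        row$cyc_min <- row$equilibrium; row$cyc_max <- row$equilibrium
      } else {
        y0 <- eq * (1 + 1e-3) + 1e-6
        sysv <- set_parameters(sys, setNames(values[i], param))
        traj <- integrate_system(sysv, y0, protocol = NULL, t_end = t_end,
                                 dt = dt)
        sel <- traj$times >= transient
        row$cyc_min <- min(traj$states[sel, readout])
        row$cyc_max <- max(traj$states[sel, readout])
      }
      row
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$equilibrium[i] <- res$equilibrium
      out$stable[i] <- res$stable
      out$cyc_min[i] <- res$cyc_min
      out$cyc_max[i] <- res$cyc_max
      out$ok[i] <- TRUE
    }
  }
  out
}
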