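# Stiff integration of ode_system objects under stimulus protocols, plus
# equilibration and oscillation metrics.

# Compile the system into a deSolve-style derivative function. A single
# evaluation environment is reused across calls, and the whole step is one
# eval() of a `{...}` block: the substitution chain is evaluated in reverse
# elimination order (each stored substitution refers only to surviving or
# later-eliminated variables), then the unsubstituted right-hand sides.
# Chain evaluation shares every substitution across equations, which is far
# cheaper than the flattened expressions for deeply reduced models.
make_rhs_function <- function(sys, param_overrides = NULL) {
  pars <- sys$parameters
  if (!is.null(param_overrides)) pars[names(param_overrides)] <- param_overrides
  env <- list2env(as.list(pars), parent = baseenv())
  vars <- sys$variables
  n <- length(vars)
  stmts <- lapply(rev(sys$substitutions), function(s)
    call("<-", as.name(s$variable), s$expr))
  stmts <- c(stmts, as.call(c(as.name("c"), unname(sys$raw_rhs))))
  rhs_call <- as.call(c(as.name("{"), stmts))
  force(rhs_call)
  f <- function(t, y, parms) {
    for (i in seq_len(n)) assign(vars[[i]], y[[i]], envir = env)
    list(eval(rhs_call, env))
  }
  attr(f, "env") <- env
  f
}

# Evaluate the rhs at a single state (named or ordered numeric vector).
eval_rhs <- function(sys, state, param_overrides = NULL) {
  f <- make_rhs_function(sys, param_overrides)
  y <- if (is.null(names(state))) as.numeric(state) else
    as.numeric(state[sys$variables])
  f(0, y, NULL)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate a system under a stimulus protocol
#'
#' Stiff integration (lsoda) with the solver stopped and restarted at every
#' protocol discontinuity, so each segment is smooth. States are reported on
#' a uniform grid plus the segment edges.
#'
#' @param sys An [ode_system()].
#' @param state0 Named numeric initial state; defaults to `sys$init` (missing
#'   entries 0).
#' @param protocol A [stimulus_protocol()] or `NULL` (inputs then take their
#'   default parameter values).
#' @param t_end Integration horizon (s).
#' @param dt Reporting grid step (s).
#' @param rtol,atol Solver tolerances.
#' @param method deSolve method name.
#' @return An `ode_trajectory`: list with `times` (s), `states`
#'   (time x variable matrix, µM), `input` (input signal values on the grid),
#'   `protocol`, and `system`.
#' @export
integrate_system <- function(sys, state0 = NULL, protocol = NULL,
                             t_end, dt = 10, rtol = 1e-8, atol = 1e-10,
                             method = "lsoda") {
  y0 <- setNames(numeric(length(sys$variables)), sys$variables)
  if (!is.null(sys$init)) {
    common <- intersect(names(sys$init), sys$variables)
    y0[common] <- sys$init[common]
  }
  if (!is.null(state0)) {
    if (is.null(names(state0))) {
      stopifnot(length(state0) == length(y0))
      y0[] <- state0
    } else y0[names(state0)] <- state0
  }
  if (!is.null(protocol) && !(protocol$input %in% sys$inputs) &&
      !(protocol$input %in% names(sys$parameters))) {
    stop("protocol drives '", protocol$input,
         "' which the system does not declare", call. = FALSE)
  }
  edges <- if (is.null(protocol)) numeric(0) else
    protocol_edges(protocol, t_end)
  bounds <- unique(c(0, edges, t_end))
  f <- make_rhs_function(sys)
  env <- attr(f, "env")
  times_all <- NULL; states_all <- NULL
  y <- y0
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    if (!is.null(protocol)) {
      assign(protocol$input, protocol_value(protocol, (a + b) / 2), envir = env)
    }
    grid <- seq(ceiling(a / dt) * dt, b, by = dt)
    tt <- unique(c(a, grid[grid > a & grid < b], b))
    out <- deSolve::ode(y = y, times = tt, func = f, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(out, "istate")[1] < 0) {
      stop("integration failed in segment [", a, ", ", b, "] of ",
           model_label(sys), call. = FALSE)
    }
    y <- out[nrow(out), -1]
    drop_first <- if (is.null(times_all)) 0L else 1L
    times_all <- c(times_all, out[(1 + drop_first):nrow(out), 1])
    states_all <- rbind(states_all,
                        out[(1 + drop_first):nrow(out), -1, drop = FALSE])
  }
  states_all <- as.matrix(states_all)
  colnames(states_all) <- sys$variables
  if (any(!is.finite(states_all))) {
    stop("trajectory contains non-finite values", call. = FALSE)
  }
  input_vals <- if (is.null(protocol)) {
    rep(if (length(sys$inputs)) sys$parameters[[sys$inputs[1]]] else NA_real_,
        length(times_all))
  } else protocol_value(protocol, times_all)
  structure(list(times = times_all, states = states_all,
                 input = input_vals, protocol = protocol, system = sys),
            class = "ode_trajectory")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat("<ode_trajectory> ", model_label(x$system), ": ",
      length(x$times), " points over [", min(x$times), ", ", max(x$times),
      "] s, variables ", paste(colnames(x$states), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.ode_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' First column is time in seconds, remaining columns the dynamic variables.
#' @param traj An `ode_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Relax a system to its unstimulated steady state
#'
#' Integrates with the stimulus input held at `input_value` until the scaled
#' residual `max_i |f_i| / max(|x_i|, 1e-6)` falls below `tol`, doubling the
#' integration span until convergence or until `t_cap` is exceeded.
#'
#' @param sys An [ode_system()].
#' @param overrides Named numeric of nonzero starting values; all other
#'   variables start at 0. Defaults to `attr(sys, "equilibrate_overrides")`
#'   when present.
#' @param input_value Value of the stimulus input during equilibration
#'   (default 0).
#' @param tol Residual tolerance.
#' @param t_cap Maximum total integration time (s).
#' @return Named numeric steady state.
#' @export
equilibrate <- function(sys, overrides = NULL, input_value = 0,
                        tol = 1e-9, t_cap = 1e7) {
  if (is.null(overrides)) overrides <- attr(sys, "equilibrate_overrides")
  y <- setNames(numeric(length(sys$variables)), sys$variables)
  if (!is.null(overrides)) {
    y[intersect(names(overrides), sys$variables)] <-
      overrides[intersect(names(overrides), sys$variables)]
  }
  po <- if (length(sys$inputs)) setNames(rep(input_value, length(sys$inputs)),
                                         sys$inputs) else NULL
  f <- make_rhs_function(sys, po)
  residual <- function(y) {
    d <- f(0, as.numeric(y), NULL)[[1]]
    max(abs(d) / pmax(abs(y), 1e-6))
  }
  span <- 1e4; total <- 0
  while (total < t_cap) {
    out <- deSolve::ode(y = y, times = c(0, span), func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12,
                        maxsteps = 50000)
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out))) {
      stop("equilibration diverged for ", model_label(sys), call. = FALSE)
    }
    y[] <- out[nrow(out), -1]
    total <- total + span
    if (residual(y) < tol) return(y)
    span <- span * 2
  }
  stop("equilibration did not converge within ", t_cap, " s (residual ",
       signif(residual(y), 3), ")", call. = FALSE)
}

# --- oscillation metrics -----------------------------------------------------

# Local maxima with a prominence filter: candidate peaks are strict local
# maxima; a peak is kept when it rises at least `prominence` above the
# deeper of the troughs separating it from its kept neighbours. Peak times
# are refined by quadratic interpolation for sub-grid precision.
find_peaks <- function(t, x, prominence) {
  n <- length(x)
  if (n < 3L) return(data.frame(time = numeric(0), value = numeric(0)))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0)))
  # merge candidates separated by shallow troughs, keeping the higher peak
  kept <- idx[1]
  for (i in idx[-1]) {
    j <- kept[length(kept)]
    trough <- min(x[j:i])
    if (x[i] - trough < prominence || x[j] - trough < prominence) {
      if (x[i] > x[j]) kept[length(kept)] <- i
    } else kept <- c(kept, i)
  }
  # outer prominence: drop edge peaks that never fall away by `prominence`
  ok <- vapply(seq_along(kept), function(k) {
    i <- kept[k]
    left <- if (k == 1L) min(x[1:i]) else min(x[kept[k - 1L]:i])
    right <- if (k == length(kept)) min(x[i:n]) else min(x[i:kept[k + 1L]])
    (x[i] - left) >= prominence && (x[i] - right) >= prominence
  }, logical(1))
  kept <- kept[ok]
  refine <- function(i) {
    if (i <= 1L || i >= n) return(c(t[i], x[i]))
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den >= 0) return(c(t[i], x[i]))
    d <- 0.5 * (y1 - y3) / den
    d <- max(min(d, 0.5), -0.5)
    # local grid may be non-uniform at segment edges; use mean spacing
    h <- (t[i + 1] - t[i - 1]) / 2
    c(t[i] + d * h, y2 - 0.25 * (y1 - y3) * d)
  }
  ref <- t(vapply(kept, refine, numeric(2)))
  data.frame(time = ref[, 1], value = ref[, 2])
}

#' Oscillation metrics of a trajectory readout
#'
#' Discards `[0, transient)`, finds local maxima of the readout with
#' prominence at least 5% of the post-transient range, and reports the mean
#' peak-to-peak period, the amplitude (max - min over the window), and the
#' coefficient of variation of the peak intervals. The trajectory is flagged
#' non-oscillatory when fewer than 3 peaks are found or the interval CV
#' exceeds 10%.
#'
#' @param traj An `ode_trajectory`.
#' @param readout Variable name to analyse.
#' @param transient Length of the initial transient to discard (s).
#' @param prominence_frac Peak prominence as a fraction of the window range.
#' @return An `oscillation_metrics` object: `oscillatory`, `period_min`,
#'   `amplitude`, `peak_times_min`, `n_cycles`, `cv_intervals`.
#' @export
oscillation_metrics <- function(traj, readout, transient = 0,
                                prominence_frac = 0.05) {
  if (!(readout %in% colnames(traj$states))) {
    stop("readout '", readout, "' is not a dynamic variable of ",
         model_label(traj$system), call. = FALSE)
  }
  sel <- traj$times >= transient
  t <- traj$times[sel]
  x <- traj$states[sel, readout]
  rng <- diff(range(x))
  out <- list(readout = readout, amplitude = rng,
              period_min = NA_real_, peak_times_min = numeric(0),
              n_cycles = 0L, cv_intervals = NA_real_, oscillatory = FALSE)
  if (rng <= 0 || !is.finite(rng)) {
    class(out) <- "oscillation_metrics"
    return(out)
  }
  pk <- find_peaks(t, x, prominence = prominence_frac * rng)
  out$peak_times_min <- pk$time / 60
  if (nrow(pk) >= 3L) {
    iv <- diff(pk$time)
    cv <- stats::sd(iv) / mean(iv)
    out$period_min <- mean(iv) / 60
    out$n_cycles <- length(iv)
    out$cv_intervals <- cv
    out$oscillatory <- cv <= 0.10
  }
  class(out) <- "oscillation_metrics"
  out
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  if (x$oscillatory) {
    cat(sprintf("<oscillation_metrics> %s: period %.2f min (CV %.2f%%, %d cycles), amplitude %.4g uM\n",
                x$readout, x$period_min, 100 * x$cv_intervals, x$n_cycles,
                x$amplitude))
  } else {
    cat("<oscillation_metrics> ", x$readout, ": not oscillatory\n", sep = "")
  }
  invisible(x)
}

# One full cycle of the readout, peak-aligned and rescaled to unit period,
# resampled on `n` points.
unit_cycle <- function(traj, readout, transient, n = 1000L) {
  m <- oscillation_metrics(traj, readout, transient)
  if (!m$oscillatory) {
    stop("trajectory of ", model_label(traj$system),
         " is not oscillatory in '", readout, "'", call. = FALSE)
  }
  pt <- m$peak_times_min * 60
  k <- length(pt) - 1L           # last full cycle, well past the transient
  a <- pt[k]; b <- pt[k + 1L]
  u <- seq(0, 1, length.out = n + 1L)[seq_len(n)]
  stats::approx(traj$times, traj$states[, readout], xout = a + u * (b - a),
                rule = 2)$y
}

#' Waveform mean squared error between two oscillatory trajectories
#'
#' One full cycle of each trajectory is extracted peak-to-peak, rescaled to
#' unit period (so period differences do not contribute), aligned at the
#' peak, resampled on a common 1000-point grid, and compared pointwise.
#'
#' @param trajA,trajB `ode_trajectory` objects.
#' @param readout Variable name present in both.
#' @param transient Transient to discard before peak detection (s).
#' @return Mean squared difference (µM^2).
#' @export
shape_mse <- function(trajA, trajB, readout, transient = 0) {
  a <- unit_cycle(trajA, readout, transient)
  b <- unit_cycle(trajB, readout, transient)
  mean((a - b)^2)
}
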