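# Quasi-steady-state elimination: affine decomposition of a fast variable's
# equation, zeroth- and first-order substitution expressions, single
# reduction steps, the iterative rank-and-reduce driver, and full-vs-reduced
# model comparison.

#' Affine decomposition of a variable's equation
#'
#' Writes the right-hand side of variable `j` as `alpha - beta * x_j`, with
#' `alpha` and `beta` free of `x_j`. Fails when the equation is nonlinear in
#' `x_j` or when `beta` vanishes identically.
#'
#' @param sys An [ode_system()].
#' @param j Variable name.
#' @return List `variable`, `alpha`, `beta` (language objects).
#' @export
affine_decompose <- function(sys, j) {
  if (!(j %in% sys$variables)) {
    stop("'", j, "' is not a dynamic variable of ", model_label(sys),
         call. = FALSE)
  }
  f <- sys$rhs[[j]]
  d1 <- expr_deriv(f, j)
  d2 <- expr_deriv(d1, j)
  if (!expr_is_zero(d2, fixed = sys$parameters)) {
    stop("equation for '", j, "' is nonlinear in '", j,
         "': d2f/dx2 = ", deparse1s(d2), call. = FALSE)
  }
  beta <- expr_simplify(call("-", d1))
  if (expr_is_zero(beta, fixed = sys$parameters)) {
    stop("decay coefficient beta for '", j, "' vanishes identically",
         call. = FALSE)
  }
  # for an affine rhs, alpha is the rhs evaluated at x_j = 0
  alpha <- expr_simplify(expr_substitute(f, setNames(list(0), j)))
  recon <- call("-", alpha, call("*", beta, as.name(j)))
  if (!expr_identical_num(recon, f, fixed = sys$parameters)) {
    stop("affine decomposition identity failed for '", j, "'", call. = FALSE)
  }
  list(variable = j, alpha = alpha, beta = beta)
}

#' Total time derivative through the system dynamics
#'
#' Chain rule over the dynamic variables: `sum_i (dexpr/dx_i) f_i`. Inputs
#' are piecewise constant, so their contribution is zero within protocol
#' segments.
#'
#' @param expr Language object or string.
#' @param sys An [ode_system()] supplying the dynamics.
#' @return Simplified language object.
#' @export
total_time_derivative <- function(expr, sys) {
  if (is.character(expr)) expr <- parse_expr(expr)
  unk <- setdiff(all.vars(expr), system_symbols(sys))
  if (length(unk)) {
    stop("expression references symbol(s) outside the system: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  acc <- 0
  for (v in intersect(all.vars(expr), sys$variables)) {
    term <- call("*", expr_deriv(expr, v), call("(", sys$rhs[[v]]))
    acc <- if (identical(acc, 0)) term else call("+", acc, term)
  }
  expr_simplify(acc)
}

#' Quasi-steady-state substitution expression
#'
#' Zeroth order: `alpha / beta`. First order adds the correction
#' `(alpha * beta. - beta * alpha.) / beta^3`, where dots are total time
#' derivatives expanded through the dynamics of `deriv_sys` (the system
#' *after* the elimination, so the correction is expressed in the surviving
#' variables only).
#'
#' @param pair Output of [affine_decompose()].
#' @param order 0 or 1.
#' @param deriv_sys System supplying the dynamics for the first-order time
#'   derivatives; ignored for order 0.
#' @return Substitution record: `variable`, `order`, `expr`, `alpha`, `beta`.
#' @export
qssa_expression <- function(pair, order = 0L, deriv_sys = NULL) {
  j <- pair$variable
  expr0 <- expr_simplify(call("/", wrap_call(pair$alpha),
                              wrap_call(pair$beta)))
  expr <- expr0
  if (order == 1L) {
    if (is.null(deriv_sys)) {
      stop("first-order correction requires the reduced system", call. = FALSE)
    }
    adot <- total_time_derivative(pair$alpha, deriv_sys)
    bdot <- total_time_derivative(pair$beta, deriv_sys)
    num <- call("-", call("*", wrap_call(pair$alpha), wrap_call(bdot)),
                call("*", wrap_call(pair$beta), wrap_call(adot)))
    corr <- expr_simplify(call("/", call("(", num),
                               call("^", wrap_call(pair$beta), 3)))
    expr <- expr_simplify(call("+", expr, corr))
  } else if (order != 0L) {
    stop("order must be 0 or 1", call. = FALSE)
  }
  if (j %in% all.vars(expr)) {
    stop("substitution for '", j, "' is self-referential", call. = FALSE)
  }
  list(variable = j, order = as.integer(order), expr = expr,
       alpha = pair$alpha, beta = pair$beta)
}

wrap_call <- function(e) if (is.call(e) &&
                             !identical(e[[1]], as.name("("))) call("(", e) else e

#' Eliminate one variable by QSSA
#'
#' Decomposes the equation of `j` affinely, forms the zeroth- (and, if
#' requested, first-) order quasi-steady-state expression, removes `j` from
#' the dynamic variables and substitutes the closed form into every
#' remaining equation. The lineage label is extended by `j` with its order
#' subscript (e.g. `"z0"` then `"z0p1"`).
#'
#' @details
#' The affine decomposition and (for order 1) the total time derivatives of
#' `alpha` and `beta` are taken from the system's zeroth-order substitution
#' skeleton: earlier first-order corrections refine what is substituted, but
#' not what is differentiated. The neglected cross-terms are of second
#' asymptotic order; without this convention a chain with several
#' first-order substitutions can make a later equation non-affine in its
#' own variable.
#'
#' @param sys An [ode_system()].
#' @param j Variable to eliminate.
#' @param order 0 or 1.
#' @return The reduced [ode_system()], one dimension smaller.
#' @export
reduce_once <- function(sys, j, order = 0L) {
  pair <- affine_decompose(shadow_system(sys), j)
  keep <- setdiff(sys$variables, j)
  if (!length(keep)) stop("cannot reduce a one-variable system", call. = FALSE)
  sub0 <- expr_simplify(call("/", wrap_call(pair$alpha), wrap_call(pair$beta)))
  sub0_map <- setNames(list(sub0), j)
  new_shadow <- lapply(sys$shadow_rhs[keep], function(e)
    expr_simplify(expr_substitute(e, sub0_map)))
  shadow_red0 <- ode_system(variables = keep, parameters = sys$parameters,
                            rhs = new_shadow, inputs = sys$inputs,
                            substitutions = sys$substitutions,
                            label = sys$label, lineage = sys$lineage,
                            init = if (is.null(sys$init)) NULL else
                              sys$init[keep],
                            units = sys$units)
  sub <- if (order == 1L) qssa_expression(pair, 1L, deriv_sys = shadow_red0)
         else qssa_expression(pair, 0L)
  sub$expr0 <- sub0
  new_rhs <- lapply(sys$rhs[keep], function(e)
    expr_simplify(expr_substitute(e, setNames(list(sub$expr), j))))
  ode_system(variables = keep, parameters = sys$parameters, rhs = new_rhs,
             inputs = sys$inputs,
             substitutions = c(sys$substitutions, list(sub)),
             label = sys$label,
             lineage = paste0(sys$lineage, j, sub$order),
             init = if (is.null(sys$init)) NULL else sys$init[keep],
             units = sys$units, shadow_rhs = new_shadow,
             raw_rhs = sys$raw_rhs[keep])
}

#' Eliminate a fixed sequence of variables
#'
#' Applies [reduce_once()] for each (variable, order) pair in turn, without
#' simulating or ranking. Used to construct named model variants directly.
#'
#' @param sys An [ode_system()].
#' @param variables Character vector, elimination order.
#' @param orders Integer vector (0/1), recycled.
#' @return The reduced [ode_system()].
#' @export
reduce_sequence <- function(sys, variables, orders = 0L) {
  orders <- rep_len(orders, length(variables))
  for (i in seq_along(variables)) {
    sys <- reduce_once(sys, variables[i], orders[i])
  }
  sys
}

#' Relative magnitude of the first-order correction along a trajectory
#'
#' For an order-0 elimination the leading error term is the first-order
#' correction `x_j^1 = (alpha beta. - beta alpha.) / beta^3`. This returns
#' `max_t |x_j^1(t)| / max_t |xbar_j^0(t)|` along the reduced model's own
#' solution: a dimensionless validity score for the quasi-steady-state
#' assumption (small means the eliminated variable really was fast).
#'
#' @param red Reduced system whose *last* substitution is checked.
#' @param traj Trajectory of `red`.
#' @param transient Transient to discard (s).
#' @return Dimensionless residual.
#' @export
qssa_residual <- function(red, traj, transient = 0) {
  sub <- red$substitutions[[length(red$substitutions)]]
  corr_sub <- qssa_expression(list(variable = sub$variable,
                                   alpha = sub$alpha, beta = sub$beta),
                              1L, deriv_sys = shadow_system(red))
  corr <- expr_simplify(call("-", corr_sub$expr,
                             call("/", wrap_call(sub$alpha),
                                  wrap_call(sub$beta))))
  sel <- traj$times >= transient
  bind <- c(as.list(red$parameters),
            lapply(seq_along(red$variables),
                   function(i) traj$states[sel, i]))
  names(bind)[length(red$parameters) + seq_along(red$variables)] <-
    red$variables
  if (length(red$inputs) && !all(is.na(traj$input))) {
    bind[[red$inputs[1]]] <- traj$input[sel]
  }
  x0 <- expr_eval(call("/", wrap_call(sub$alpha), wrap_call(sub$beta)), bind)
  x1 <- expr_eval(corr, bind)
  max(abs(x1)) / max(abs(x0))
}

#' Compare a reduced model against its parent
#'
#' Both systems are simulated from their stored initial conditions under the
#' same protocol; oscillation metrics, fold changes and the waveform MSE of
#' the readout are reported.
#'
#' @param full,reduced [ode_system()] objects (reduced dynamic variables must
#'   be a subset of the full model's).
#' @param protocol A [stimulus_protocol()].
#' @param readout Readout variable (default `"r"`, nuclear NF-kB).
#' @param t_end Horizon (s).
#' @param transient Transient discarded before metrics (s).
#' @param dt Reporting step (s).
#' @param traj_full Optional precomputed trajectory of `full` (saves a
#'   simulation).
#' @return List with both metrics, `period_fold`, `amplitude_fold`,
#'   `shape_mse`, and `max_deviation` (max pointwise difference of shared
#'   variables over one rescaled cycle).
#' @export
compare_models <- function(full, reduced, protocol, readout = "r",
                           t_end = 180000, transient = 60000, dt = 10,
                           traj_full = NULL) {
  if (!all(reduced$variables %in% full$variables)) {
    stop("reduced model's variables are not a subset of the full model's",
         call. = FALSE)
  }
  if (is.null(traj_full)) {
    traj_full <- integrate_system(full, protocol = protocol, t_end = t_end,
                                  dt = dt)
  }
  traj_red <- integrate_system(reduced, protocol = protocol, t_end = t_end,
                               dt = dt)
  mf <- oscillation_metrics(traj_full, readout, transient)
  mr <- oscillation_metrics(traj_red, readout, transient)
  out <- list(metrics_full = mf, metrics_reduced = mr,
              period_fold = NA_real_, amplitude_fold = NA_real_,
              shape_mse = NA_real_, max_deviation = NA_real_,
              traj_reduced = traj_red)
  if (mf$amplitude > 0) out$amplitude_fold <- mr$amplitude / mf$amplitude
  if (mf$oscillatory && mr$oscillatory) {
    out$period_fold <- mr$period_min / mf$period_min
    out$shape_mse <- shape_mse(traj_full, traj_red, readout, transient)
    devs <- vapply(reduced$variables, function(v) {
      a <- unit_cycle(traj_full, v, transient)
      b <- unit_cycle(traj_red, v, transient)
      max(abs(a - b))
    }, numeric(1))
    out$max_deviation <- max(devs)
  }
  out
}

#' Iterative speed-ranked model reduction
#'
#' Runs the full rank-and-reduce loop: simulate a representative solution,
#' compute speed coefficients, pick the variable that is fastest at its
#' slowest, eliminate it by QSSA (order taken from `order_policy`, default
#' 0), re-simulate, and record comparison metrics against the root model.
#' When an order-0 step loses the oscillation that its parent had, the step
#' is retried at first order if `auto_first_order` allows; if the rescue
#' fails too, the loop stops early with a flag.
#'
#' @param sys Root [ode_system()].
#' @param protocol Representative-solution [stimulus_protocol()].
#' @param n_steps Number of elimination steps.
#' @param order_policy Named list/vector mapping variable name to QSSA order.
#' @param exclude Variables never eliminated.
#' @param readout Metrics readout variable.
#' @param t_end,transient,dt Simulation horizon, transient, and reporting
#'   step (s).
#' @param speed_transient Portion of each representative solution excluded
#'   from the min-over-time speed ranking (s). Defaults to `transient`: the
#'   entrainment transient right after stimulation onset probes far deeper
#'   troughs than the attractor does, and ranking on it can misorder the
#'   eliminations; set to 0 to rank over the full simulated interval.
#' @param auto_first_order Retry a failed order-0 step at order 1.
#' @param verbose Narrate each step.
#' @return A `reduction_lineage`: `root`, `steps` (list of per-step records),
#'   and `table` (one row per step: label, variable, order, min_speed,
#'   period_min, amplitude, period_fold, amplitude_fold, shape_mse,
#'   qssa_residual, oscillatory).
#' @export
reduce_iteratively <- function(sys, protocol, n_steps,
                               order_policy = list(), exclude = character(),
                               readout = "r", t_end = 180000,
                               transient = 60000, dt = 10,
                               speed_transient = transient,
                               auto_first_order = TRUE, verbose = FALSE) {
  if (n_steps >= length(sys$variables)) {
    stop("n_steps must be smaller than the system dimension", call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  traj_root <- integrate_system(sys, protocol = protocol, t_end = t_end,
                                dt = dt)
  m_root <- oscillation_metrics(traj_root, readout, transient)
  current <- sys; traj <- traj_root
  steps <- list()
  stopped_early <- FALSE
  for (step in seq_len(n_steps)) {
    prof <- speed_coefficients(current, traj, transient = speed_transient)
    ranking <- rank_fastest(prof, exclude)
    j <- ranking$variable[1]
    ord <- if (j %in% names(order_policy)) as.integer(order_policy[[j]]) else 0L
    say("step %d: eliminating %s (min lambda %.3g 1/s) at order %d",
        step, j, ranking$min_speed[1], ord)
    attempt <- function(o) {
      red <- reduce_once(current, j, o)
      traj_r <- integrate_system(red, protocol = protocol, t_end = t_end,
                                 dt = dt)
      m <- oscillation_metrics(traj_r, readout, transient)
      list(red = red, traj = traj_r, metrics = m, order = o)
    }
    res <- attempt(ord)
    parent_osc <- oscillation_metrics(traj, readout, transient)$oscillatory
    if (!res$metrics$oscillatory && parent_osc && ord == 0L &&
        auto_first_order) {
      say("step %d: order-0 elimination of %s lost the oscillation; retrying at order 1",
          step, j)
      res <- attempt(1L)
    }
    rec <- list(variable = j, order = res$order,
                label = model_label(res$red),
                min_speed = ranking$min_speed[1],
                ranking = ranking,
                system = res$red, metrics = res$metrics,
                trajectory = res$traj)
    rec$period_fold <- if (res$metrics$oscillatory && m_root$oscillatory)
      res$metrics$period_min / m_root$period_min else NA_real_
    rec$amplitude_fold <- if (m_root$amplitude > 0)
      res$metrics$amplitude / m_root$amplitude else NA_real_
    rec$shape_mse <- if (res$metrics$oscillatory && m_root$oscillatory)
      shape_mse(traj_root, res$traj, readout, transient) else NA_real_
    rec$qssa_residual <- if (res$order == 0L)
      qssa_residual(res$red, res$traj, transient) else NA_real_
    steps[[step]] <- rec
    if (!res$metrics$oscillatory && parent_osc) {
      say("step %d: reduced model is not oscillatory; stopping early", step)
      stopped_early <- TRUE
      break
    }
    current <- res$red
    traj <- res$traj
  }
  tab <- do.call(rbind, lapply(steps, function(s)
    data.frame(label = s$label, variable = s$variable, order = s$order,
               min_speed = s$min_speed,
               period_min = s$metrics$period_min,
               amplitude = s$metrics$amplitude,
               period_fold = s$period_fold,
               amplitude_fold = s$amplitude_fold,
               shape_mse = s$shape_mse,
               qssa_residual = s$qssa_residual,
               oscillatory = s$metrics$oscillatory)))
  structure(list(root = sys, root_trajectory = traj_root,
                 root_metrics = m_root, steps = steps, table = tab,
                 stopped_early = stopped_early,
                 readout = readout),
            class = "reduction_lineage")
}

#' @export
print.reduction_lineage <- function(x, ...) {
  cat("<reduction_lineage> root ", model_label(x$root), " (",
      length(x$root$variables), " variables), ", length(x$steps),
      " step(s)", if (x$stopped_early) ", stopped early" else "", "\n",
      sep = "")
  if (!is.null(x$table)) print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
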