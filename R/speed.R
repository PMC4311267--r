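# Speed coefficients: per-variable relaxation rates along a trajectory.
#
# The speed coefficient of variable i is lambda_i = |df_i/dx_i|, the absolute
# diagonal Jacobian entry, evaluated pointwise along a representative
# solution. Its minimum over the solution ranks variables for quasi-steady-
# state elimination ("fastest at its slowest").

#' Speed coefficients along a trajectory
#'
#' Differentiates each right-hand side with respect to its own variable once
#' symbolically, then evaluates the absolute value along the trajectory.
#'
#' @param sys The [ode_system()] the trajectory was produced from.
#' @param traj An `ode_trajectory` of `sys`.
#' @param transient Portion of the trajectory to exclude from the
#'   min-over-time summary (s). The default 0 includes the whole simulated
#'   interval, transient included.
#' @return A `speed_profile`: `times` (s), `lambda` (time x variable matrix,
#'   1/s), and `summary` (data.frame: variable, min_speed, t_min).
#' @export
speed_coefficients <- function(sys, traj, transient = 0) {
  if (!identical(colnames(traj$states), sys$variables)) {
    stop("trajectory does not match the system's dynamic variables",
         call. = FALSE)
  }
  bind <- c(as.list(sys$parameters),
            lapply(seq_along(sys$variables), function(i) traj$states[, i]))
  names(bind)[length(sys$parameters) + seq_along(sys$variables)] <-
    sys$variables
  if (length(sys$inputs) && !all(is.na(traj$input))) {
    bind[[sys$inputs[1]]] <- traj$input
  }
  nt <- length(traj$times)
  lam <- matrix(NA_real_, nt, length(sys$variables),
                dimnames = list(NULL, sys$variables))
  for (v in sys$variables) {
    d <- expr_deriv(sys$rhs[[v]], v)
    val <- expr_eval(d, bind)
    lam[, v] <- abs(rep_len(val, nt))
  }
  sel <- traj$times >= transient
  mins <- apply(lam[sel, , drop = FALSE], 2, min)
  argm <- apply(lam[sel, , drop = FALSE], 2, which.min)
  structure(list(times = traj$times,
                 lambda = lam,
                 summary = data.frame(variable = sys$variables,
                                      min_speed = as.numeric(mins),
                                      t_min = traj$times[sel][argm],
                                      row.names = NULL)),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat("<speed_profile> over", length(x$times), "time points\n")
  s <- x$summary[order(-x$summary$min_speed), ]
  print(s, row.names = FALSE)
  invisible(x)
}

#' Rank variables for elimination
#'
#' Sorts variables by decreasing minimum speed coefficient; the top entry is
#' the "fastest at its slowest" and the next candidate for quasi-steady-state
#' elimination. Ties are broken lexicographically by variable name.
#'
#' @param profile A `speed_profile` from [speed_coefficients()].
#' @param exclude Character vector of variables to leave out of the ranking.
#' @return Data frame (variable, min_speed, t_min) sorted by rank; the first
#'   row is the elimination candidate.
#' @export
rank_fastest <- function(profile, exclude = character()) {
  s <- profile$summary
  s <- s[!(s$variable %in% exclude), , drop = FALSE]
  if (!nrow(s)) stop("all variables excluded from the ranking", call. = FALSE)
  s <- s[order(-s$min_speed, s$variable), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Write speed-coefficient series to CSV
#'
#' @param profile A `speed_profile`.
#' @param path Output path; first column time (s), then one lambda column per
#'   variable.
#' @export
write_speed_csv <- function(profile, path) {
  utils::write.csv(data.frame(time = profile$times, profile$lambda,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
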