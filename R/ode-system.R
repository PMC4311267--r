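# Symbolic representation of reaction ODE systems.
#
# An `ode_system` holds an ordered set of dynamic variables, a parameter map,
# one right-hand-side expression per variable, optional time-dependent input
# signals, and an ordered chain of substitutions for variables that have been
# eliminated (by conservation or by quasi-steady-state approximation). The
# rhs expressions are kept *flattened*: they refer only to current dynamic
# variables, parameters and inputs, never to eliminated variables.

#' Construct a symbolic ODE system
#'
#' @param variables Character vector of dynamic variable names (ordered).
#' @param parameters Named numeric vector of parameter values.
#' @param rhs Named list of right-hand-side expressions, one per variable;
#'   entries may be language objects or strings.
#' @param inputs Character vector of time-dependent input signal names.
#'   An input must also have a default value in `parameters`, which is used
#'   when no stimulus protocol is attached.
#' @param substitutions Ordered list of substitution records for eliminated
#'   variables (see [reduce_once()]); normally empty at construction.
#' @param label Model label, e.g. `"SM"`.
#' @param lineage Reduction lineage string, e.g. `"z0p1"`; empty for a root
#'   model.
#' @param init Optional named numeric vector of default initial conditions.
#' @param units Optional named character vector of parameter unit strings
#'   (documentation only).
#' @param shadow_rhs Named list of right-hand sides with every substitution
#'   taken at zeroth order (the "QSSA skeleton"); defaults to `rhs`. Used to
#'   derive affine decompositions and first-order corrections during
#'   iterated reduction.
#' @param raw_rhs Named list of the *unsubstituted* right-hand sides (which
#'   may reference eliminated variables resolved through the substitution
#'   chain at evaluation time); defaults to `rhs`. Kept alongside the
#'   flattened form because chain evaluation is much cheaper for deeply
#'   reduced models.
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(variables, parameters, rhs, inputs = character(),
                       substitutions = list(), label = "model",
                       lineage = "", init = NULL, units = NULL,
                       shadow_rhs = NULL, raw_rhs = NULL) {
  if (length(variables) == 0L) stop("system declares no variables", call. = FALSE)
  if (anyDuplicated(variables)) {
    stop("duplicate variable name: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  rhs <- lapply(rhs, function(e) if (is.character(e)) parse_expr(e) else e)
  if (!setequal(names(rhs), variables)) {
    stop("rhs must have exactly one entry per variable", call. = FALSE)
  }
  rhs <- rhs[variables]
  sub_vars <- vapply(substitutions, function(s) s$variable, character(1))
  if (length(intersect(sub_vars, variables))) {
    stop("substitution chain contains a dynamic variable", call. = FALSE)
  }
  known <- c(variables, names(parameters), inputs)
  for (v in variables) {
    unk <- setdiff(all.vars(rhs[[v]]), known)
    if (length(unk)) {
      stop("equation for '", v, "' references undeclared symbol(s): ",
           paste(unk, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(raw_rhs)) {
    raw_rhs <- rhs
  } else {
    raw_rhs <- lapply(raw_rhs, function(e)
      if (is.character(e)) parse_expr(e) else e)
    stopifnot(setequal(names(raw_rhs), variables))
    raw_rhs <- raw_rhs[variables]
  }
  if (is.null(shadow_rhs)) {
    shadow_rhs <- rhs
  } else {
    shadow_rhs <- lapply(shadow_rhs, function(e)
      if (is.character(e)) parse_expr(e) else e)
    stopifnot(setequal(names(shadow_rhs), variables))
    shadow_rhs <- shadow_rhs[variables]
  }
  structure(list(variables = variables,
                 parameters = parameters,
                 rhs = rhs,
                 inputs = inputs,
                 substitutions = substitutions,
                 label = label,
                 lineage = lineage,
                 init = init,
                 units = units,
                 shadow_rhs = shadow_rhs,
                 raw_rhs = raw_rhs),
            class = "ode_system")
}

# View of the system with the zeroth-order (skeleton) right-hand sides.
shadow_system <- function(sys) {
  if (identical(sys$shadow_rhs, sys$rhs)) return(sys)
  out <- sys
  out$rhs <- sys$shadow_rhs
  out
}

#' @export
print.ode_system <- function(x, ...) {
  lab <- model_label(x)
  cat("<ode_system> ", lab, ": ", length(x$variables),
      " dynamic variable(s)\n", sep = "")
  for (v in x$variables) {
    cat("  d", v, "/dt = ", deparse1s(x$rhs[[v]]), "\n", sep = "")
  }
  if (length(x$substitutions)) {
    cat("  eliminated:",
        paste(vapply(x$substitutions, function(s)
          paste0(s$variable, if (!is.null(s$order) && is.finite(s$order))
            s$order else ""), character(1)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ode_system <- function(x) length(x$variables)

#' Display label of a model
#'
#' The reduction lineage string (e.g. `"z0p0y0v0s0w1"`) when the model has
#' been reduced, otherwise the base label.
#' @param sys An [ode_system()].
#' @return Character scalar.
#' @export
model_label <- function(sys) {
  if (nzchar(sys$lineage)) sys$lineage else sys$label
}

# All symbols a rhs may legally reference.
system_symbols <- function(sys) {
  c(sys$variables, names(sys$parameters), sys$inputs)
}

#' Reconstruct an eliminated variable along a set of bindings
#'
#' Evaluates the substitution chain in order so that later substitutions may
#' refer to earlier eliminated variables.
#' @keywords internal
chain_bindings <- function(sys, bindings) {
  for (s in sys$substitutions) {
    bindings[[s$variable]] <- expr_eval(s$expr, bindings)
  }
  bindings
}

#' Parse a model definition file
#'
#' Reads the structured text format with sections `[label]`, `[variables]`,
#' `[parameters]`, `[inputs]`, `[equations]`, `[init]` and
#' `[substitutions]`. Equations are written as `var' = expression`;
#' substitutions as `var:order = expression` with order `0`, `1` or `c`
#' (conservation).
#'
#' @param path Path to a model file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return An [ode_system()].
#' @export
parse_model <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  section <- NA_character_
  label <- "model"
  vars <- character(); inputs <- character()
  params <- numeric(); units <- character()
  eqs <- list(); init <- numeric(); subs <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[([a-z]+)\\]\\s*(.*)$", ln))[[1]]
    if (length(m)) {
      section <- m[2]
      if (section == "label" && nzchar(m[3])) label <- m[3]
      next
    }
    loc <- paste0("line ", k)
    if (is.na(section)) stop("content before first section (", loc, ")",
                             call. = FALSE)
    switch(section,
      label = { label <- ln },
      variables = { vars <- c(vars, strsplit(ln, "[,[:space:]]+")[[1]]) },
      inputs = {
        kv <- parse_kv(ln, loc)
        inputs <- c(inputs, kv$key)
        params[kv$key] <- as.numeric(eval(kv$expr, baseenv()))
      },
      parameters = {
        kv <- parse_kv(ln, loc)
        params[kv$key] <- as.numeric(eval(kv$expr, baseenv()))
        if (!is.null(kv$unit)) units[kv$key] <- kv$unit
      },
      equations = {
        m2 <- regmatches(ln, regexec("^([A-Za-z][A-Za-z0-9_.]*)'\\s*=\\s*(.+)$",
                                     ln))[[1]]
        if (!length(m2)) stop("cannot parse equation at ", loc, ": '", ln, "'",
                              call. = FALSE)
        eqs[[m2[2]]] <- parse_expr(m2[3])
      },
      init = {
        kv <- parse_kv(ln, loc)
        init[kv$key] <- as.numeric(eval(kv$expr, baseenv()))
      },
      substitutions = {
        m2 <- regmatches(ln, regexec(
          "^([A-Za-z][A-Za-z0-9_.]*):([01c])\\s*=\\s*(.+)$", ln))[[1]]
        if (!length(m2)) stop("cannot parse substitution at ", loc, call. = FALSE)
        subs[[length(subs) + 1L]] <- list(
          variable = m2[2],
          order = if (m2[3] == "c") NA_integer_ else as.integer(m2[3]),
          expr = parse_expr(m2[4]))
      },
      stop("unknown section [", section, "]", call. = FALSE))
  }
  ode_system(variables = vars, parameters = params, rhs = eqs,
             inputs = inputs, substitutions = subs, label = label,
             init = if (length(init)) init else NULL,
             units = if (length(units)) units else NULL)
}

parse_kv <- function(ln, loc) {
  m <- regmatches(ln, regexec(
    "^([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*([^|]+)(\\|\\s*(.*))?$", ln))[[1]]
  if (!length(m)) stop("cannot parse 'name = value' at ", loc, ": '", ln, "'",
                       call. = FALSE)
  list(key = m[2], expr = parse_expr(trimws(m[3])),
       unit = if (nzchar(m[5])) trimws(m[5]) else NULL)
}

#' Serialize a model to the definition format
#'
#' @param sys An [ode_system()].
#' @param path Optional path; when given, lines are written there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
serialize_model <- function(sys, path = NULL) {
  fmt_num <- function(x) sprintf("%.15g", x)
  out <- c(paste0("[label] ", model_label(sys)),
           "[variables]",
           paste(sys$variables, collapse = " "))
  pars <- setdiff(names(sys$parameters), sys$inputs)
  out <- c(out, "[parameters]")
  for (p in pars) {
    u <- if (!is.null(sys$units) && p %in% names(sys$units))
      paste0("  | ", sys$units[[p]]) else ""
    out <- c(out, paste0(p, " = ", fmt_num(sys$parameters[[p]]), u))
  }
  if (length(sys$inputs)) {
    out <- c(out, "[inputs]",
             vapply(sys$inputs, function(i)
               paste0(i, " = ", fmt_num(sys$parameters[[i]])), character(1)))
  }
  out <- c(out, "[equations]",
           vapply(sys$variables, function(v)
             paste0(v, "' = ", deparse1s(sys$rhs[[v]])), character(1)))
  if (!is.null(sys$init)) {
    out <- c(out, "[init]",
             vapply(names(sys$init), function(v)
               paste0(v, " = ", fmt_num(sys$init[[v]])), character(1)))
  }
  if (length(sys$substitutions)) {
    out <- c(out, "[substitutions]",
             vapply(sys$substitutions, function(s)
               paste0(s$variable, ":",
                      if (is.na(s$order)) "c" else s$order, " = ",
                      deparse1s(s$expr)), character(1)))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Eliminate a variable through a conserved total
#'
#' Checks symbolically (by sampling) that `d(total)/dt` vanishes under the
#' system dynamics, solves `total = constant` for `victim` (which must enter
#' the total linearly), removes the victim's ODE and substitutes its closed
#' form everywhere.
#'
#' @param sys An [ode_system()].
#' @param total Conserved expression (string or language), e.g. `"v + w + a"`.
#' @param victim Name of the variable to eliminate.
#' @param constant Name of a parameter, or a number, fixing the value of the
#'   total. Defaults to evaluating the total at `sys$init`.
#' @return The reduced [ode_system()].
#' @export
eliminate_by_conservation <- function(sys, total, victim, constant = NULL) {
  if (is.character(total)) total <- parse_expr(total)
  if (!(victim %in% sys$variables)) {
    stop("victim '", victim, "' is not a dynamic variable", call. = FALSE)
  }
  if (!(victim %in% all.vars(total))) {
    stop("victim '", victim, "' does not appear in the conserved total",
         call. = FALSE)
  }
  # d(total)/dt = sum_i dtotal/dx_i * f_i must vanish identically
  ddt <- 0
  for (v in intersect(all.vars(total), sys$variables)) {
    ddt <- call("+", ddt, call("*", expr_deriv(total, v), sys$rhs[[v]]))
  }
  ddt <- expr_simplify(ddt)
  if (!expr_is_zero(ddt, fixed = sys$parameters, tol = 1e-8)) {
    stop("total '", deparse1s(total), "' is not conserved: d/dt = ",
         deparse1s(ddt), call. = FALSE)
  }
  coef <- expr_deriv(total, victim)
  if (victim %in% all.vars(coef)) {
    stop("victim '", victim, "' does not enter the total linearly",
         call. = FALSE)
  }
  if (is.null(constant)) {
    if (is.null(sys$init)) {
      stop("no conservation constant given and the system has no initial ",
           "conditions to fix it from", call. = FALSE)
    }
    constant <- expr_eval(total, as.list(c(sys$init, sys$parameters)))
  }
  const_expr <- if (is.character(constant)) as.name(constant) else constant
  rest <- expr_simplify(expr_substitute(total, setNames(list(0), victim)))
  victim_expr <- expr_simplify(
    call("/", call("(", call("-", const_expr, rest)), coef))
  keep <- setdiff(sys$variables, victim)
  sub_map <- setNames(list(victim_expr), victim)
  new_rhs <- lapply(sys$rhs[keep], function(e)
    expr_simplify(expr_substitute(e, sub_map)))
  new_shadow <- lapply(sys$shadow_rhs[keep], function(e)
    expr_simplify(expr_substitute(e, sub_map)))
  subs <- c(sys$substitutions,
            list(list(variable = victim, order = NA_integer_,
                      expr = victim_expr, alpha = NULL, beta = NULL)))
  ode_system(variables = keep, parameters = sys$parameters, rhs = new_rhs,
             inputs = sys$inputs, substitutions = subs, label = sys$label,
             lineage = sys$lineage,
             init = if (is.null(sys$init)) NULL else sys$init[keep],
             units = sys$units, shadow_rhs = new_shadow,
             raw_rhs = sys$raw_rhs[keep])
}

#' Remove decoupled variables
#'
#' A variable is decoupled when it appears in no right-hand side other than
#' its own (and in no substitution expression); its solution can be recovered
#' post hoc by quadrature, so it can be dropped without changing the retained
#' dynamics. Removal repeats until a fixpoint.
#'
#' @param sys An [ode_system()].
#' @return List with elements `system` (the pruned [ode_system()]) and
#'   `dropped` (variable names in removal order).
#' @export
drop_decoupled <- function(sys) {
  dropped <- character()
  repeat {
    if (length(sys$variables) == 1L) break
    hit <- NULL
    for (v in sys$variables) {
      used <- FALSE
      for (w in setdiff(sys$variables, v)) {
        if (v %in% all.vars(sys$rhs[[w]])) { used <- TRUE; break }
      }
      if (!used && length(sys$substitutions)) {
        for (s in sys$substitutions) {
          if (v %in% all.vars(s$expr)) { used <- TRUE; break }
        }
      }
      if (!used) { hit <- v; break }
    }
    if (is.null(hit)) break
    dropped <- c(dropped, hit)
    keep <- setdiff(sys$variables, hit)
    sys <- ode_system(variables = keep, parameters = sys$parameters,
                      rhs = sys$rhs[keep], inputs = sys$inputs,
                      substitutions = sys$substitutions, label = sys$label,
                      lineage = sys$lineage,
                      init = if (is.null(sys$init)) NULL else sys$init[keep],
                      units = sys$units,
                      shadow_rhs = sys$shadow_rhs[keep],
                      raw_rhs = sys$raw_rhs[keep])
  }
  list(system = sys, dropped = dropped)
}

#' Override parameter values
#'
#' @param sys An [ode_system()].
#' @param ... Name-value pairs, or a single named numeric vector.
#' @return The modified system.
#' @export
set_parameters <- function(sys, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  unk <- setdiff(names(dots), names(sys$parameters))
  if (length(unk)) stop("unknown parameter(s): ", paste(unk, collapse = ", "),
                        call. = FALSE)
  sys$parameters[names(dots)] <- unlist(dots)
  sys
}
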