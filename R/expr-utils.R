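# Lightweight symbolic-expression layer on top of base R language objects.
# Expressions are ordinary calls built from + - * / ^ and parentheses; this is
# all that mass-action and Hill-type rate laws need, so stats::D() can
# differentiate everything we generate.

#' Free symbols of an expression
#'
#' @param expr A language object (call, name, or numeric literal).
#' @return Character vector of symbol names appearing in `expr`.
#' @keywords internal
expr_symbols <- function(expr) {
  all.vars(expr)
}

#' Substitute symbols in an expression
#'
#' Replaces every occurrence of the named symbols by the supplied
#' expressions (language objects or numerics). Substitution is simultaneous,
#' not sequential.
#'
#' @param expr Language object.
#' @param map Named list; names are symbols to replace, values are language
#'   objects or numbers.
#' @return The rewritten language object.
#' @keywords internal
expr_substitute <- function(expr, map) {
  if (is.numeric(expr) || is.logical(expr)) return(expr)
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(map)) {
      rep <- map[[nm]]
      if (is.numeric(rep)) return(rep)
      # parenthesise compound replacements to preserve precedence
      if (is.call(rep) && !identical(rep[[1]], as.name("("))) {
        return(call("(", rep))
      }
      return(rep)
    }
    return(expr)
  }
  if (is.call(expr)) {
    for (i in seq_along(expr)[-1]) {
      expr[[i]] <- expr_substitute(expr[[i]], map)
    }
    return(expr)
  }
  expr
}

# Constant folding and algebraic identity removal. Keeps derivative output
# and substitution chains from ballooning; this is not a CAS and makes no
# attempt at cancellation beyond 0/1 identities.
expr_simplify <- function(expr) {
  if (is.numeric(expr) || is.name(expr)) return(expr)
  if (!is.call(expr)) return(expr)
  op <- as.character(expr[[1]])
  if (op == "(") {
    inner <- expr_simplify(expr[[2]])
    if (is.numeric(inner) || is.name(inner)) return(inner)
    return(call("(", inner))
  }
  args <- lapply(as.list(expr)[-1], expr_simplify)
  is_num <- vapply(args, is.numeric, logical(1))
  if (all(is_num) && op %in% c("+", "-", "*", "/", "^", "exp", "log", "sqrt")) {
    val <- tryCatch(eval(as.call(c(as.name(op), args)), baseenv()),
                    error = function(e) NULL)
    if (!is.null(val) && is.finite(val)) return(val)
  }
  strip <- function(e) {
    while (is.call(e) && identical(e[[1]], as.name("("))) e <- e[[2]]
    e
  }
  zero <- function(e) is.numeric(e) && length(e) == 1L && e == 0
  one  <- function(e) is.numeric(e) && length(e) == 1L && e == 1
  a <- strip(args[[1]])
  b <- if (length(args) >= 2L) strip(args[[2]]) else NULL
  wrap <- function(e) if (is.call(e) && !identical(e[[1]], as.name("("))) call("(", e) else e
  if (op == "+" && length(args) == 2L) {
    if (zero(a)) return(args[[2]])
    if (zero(b)) return(args[[1]])
  } else if (op == "-" && length(args) == 2L) {
    if (zero(b)) return(args[[1]])
    if (zero(a)) return(call("-", args[[2]]))
  } else if (op == "-" && length(args) == 1L) {
    if (is.numeric(a)) return(-a)
    if (is.call(a) && identical(a[[1]], as.name("-")) && length(a) == 2L) {
      return(a[[2]])   # -(-x) = x
    }
  } else if (op == "*") {
    if (zero(a) || zero(b)) return(0)
    if (one(a)) return(args[[2]])
    if (one(b)) return(args[[1]])
  } else if (op == "/") {
    if (zero(a)) return(0)
    if (one(b)) return(args[[1]])
  } else if (op == "^") {
    if (one(b)) return(args[[1]])
    if (zero(b)) return(1)
    if (one(a)) return(1)
  }
  as.call(c(as.name(op), args))
}

#' Symbolic partial derivative
#'
#' @param expr Language object.
#' @param var Variable name (character).
#' @return Simplified language object for d(expr)/d(var).
#' @keywords internal
expr_deriv <- function(expr, var) {
  if (!(var %in% all.vars(expr))) return(0)
  d <- stats::D(expr, var)
  expr_simplify(d)
}

# Vectorised evaluation of an expression against a named list/data.frame of
# (possibly vector) bindings.
expr_eval <- function(expr, bindings) {
  eval(expr, envir = bindings, enclos = baseenv())
}

#' Numerical test of symbolic identity
#'
#' Two expressions are declared equivalent when they agree to relative
#' tolerance `tol` at `n` quasi-random strictly positive sample points for
#' every free symbol. Used wherever an exact algebraic identity is asserted;
#' the sampling is deterministic.
#'
#' @param e1,e2 Language objects.
#' @param symbols Character vector of symbols to sample; defaults to the
#'   union of free symbols.
#' @param fixed Named numeric of symbols to hold at given values (e.g.
#'   rate constants).
#' @param n Number of sample points.
#' @param tol Relative tolerance.
#' @param lower,upper Sampling range (log-uniform).
#' @return Logical scalar.
#' @keywords internal
expr_identical_num <- function(e1, e2, symbols = NULL, fixed = numeric(0),
                               n = 24L, tol = 1e-8,
                               lower = 1e-2, upper = 3) {
  if (is.null(symbols)) {
    symbols <- setdiff(union(all.vars(e1), all.vars(e2)), names(fixed))
  }
  # deterministic low-discrepancy points (Halton), mapped log-uniformly
  pts <- halton_points(n, length(symbols))
  lo <- log(lower); hi <- log(upper)
  for (i in seq_len(n)) {
    b <- as.list(fixed)
    for (j in seq_along(symbols)) {
      b[[symbols[j]]] <- exp(lo + (hi - lo) * pts[i, j])
    }
    v1 <- tryCatch(expr_eval(e1, b), error = function(e) NA_real_)
    v2 <- tryCatch(expr_eval(e2, b), error = function(e) NA_real_)
    if (!is.finite(v1) || !is.finite(v2)) return(FALSE)
    if (abs(v1 - v2) > tol * max(abs(v1), abs(v2), 1e-12)) return(FALSE)
  }
  TRUE
}

# Halton low-discrepancy sequence (radical inverse in the first d primes):
# deterministic sample points for the identity checks above.
halton_points <- function(n, d) {
  if (d == 0L) return(matrix(0, n, 0))
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (d > length(primes)) stop("too many symbols to sample", call. = FALSE)
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  vapply(seq_len(d), function(j)
    vapply(seq_len(n) + 16L, radical_inverse, numeric(1), b = primes[j]),
    numeric(n))
}

# Upper bound on the term magnitudes of an expression: every subtraction
# becomes an addition and numeric leaves take their absolute value. For
# positive symbol values this bounds the largest intermediate term, giving
# the natural scale against which "numerically zero" is judged.
expr_magnitude <- function(expr) {
  if (is.numeric(expr)) return(abs(expr))
  if (is.name(expr)) return(expr)
  if (!is.call(expr)) return(expr)
  op <- as.character(expr[[1]])
  args <- lapply(as.list(expr)[-1], expr_magnitude)
  if (op == "-" && length(args) == 2L) {
    return(call("+", args[[1]], args[[2]]))
  }
  if (op == "-" && length(args) == 1L) return(args[[1]])
  as.call(c(as.name(op), args))
}

# TRUE when expr vanishes identically: |expr| stays below tol times the
# magnitude bound of its own terms at every sampled point.
expr_is_zero <- function(expr, fixed = numeric(0), tol = 1e-8) {
  s <- expr_simplify(expr)
  if (is.numeric(s)) return(abs(s) == 0)
  mag <- expr_magnitude(s)
  symbols <- setdiff(all.vars(s), names(fixed))
  pts <- halton_points(24L, length(symbols))
  lo <- log(1e-2); hi <- log(3)
  for (i in seq_len(nrow(pts))) {
    b <- as.list(fixed)
    for (j in seq_along(symbols)) {
      b[[symbols[j]]] <- exp(lo + (hi - lo) * pts[i, j])
    }
    v <- tryCatch(expr_eval(s, b), error = function(e) NA_real_)
    m <- tryCatch(expr_eval(mag, b), error = function(e) NA_real_)
    if (!is.finite(v) || !is.finite(m)) return(FALSE)
    if (abs(v) > tol * max(m, 1e-12)) return(FALSE)
  }
  TRUE
}

# Parse a single expression string into a language object.
parse_expr <- function(text) {
  out <- tryCatch(parse(text = text, keep.source = FALSE),
                  error = function(e) stop("unparseable expression: '", text,
                                           "' (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(out) != 1L) {
    stop("expected a single expression, got ", length(out), ": '", text, "'",
         call. = FALSE)
  }
  out[[1]]
}

deparse1s <- function(expr) paste(deparse(expr, width.cutoff = 500L),
                                  collapse = " ")
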