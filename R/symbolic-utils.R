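# Lightweight symbolic layer: R call objects play the role of expressions,
# stats::D supplies exact derivatives, and identities ("simplifies to zero")
# are certified by evaluation on outcome/parameter grids.

#' Substitute symbols in an expression
#'
#' Replaces symbols in an unevaluated R expression by other expressions or
#' values, without evaluating the result.
#'
#' @param expr A `call`, `symbol` or atomic value (quoted expression).
#' @param bindings Named list mapping symbol names to replacement expressions
#'   or numeric values.
#' @return The substituted expression (still unevaluated).
#' @keywords internal
subst_expr <- function(expr, bindings) {
  stopifnot(is.list(bindings))
  do.call(substitute, list(expr, bindings))
}

#' Evaluate an expression at named values
#'
#' @param expr Quoted expression.
#' @param vars Named list of values (vectors recycle as usual).
#' @return Numeric result.
#' @keywords internal
eval_expr <- function(expr, vars = list()) {
  eval(expr, envir = vars, enclos = baseenv())
}

# All symbols appearing in an expression.
expr_symbols <- function(expr) {
  if (is.symbol(expr)) return(as.character(expr))
  if (!is.call(expr)) return(character(0))
  unique(unlist(lapply(as.list(expr)[-1], expr_symbols)))
}

# Derivative of a quoted expression with respect to `name`, as a call.
deriv_expr <- function(expr, name) {
  stats::D(expr, name)
}

# Build a call multiplying a list of expressions together.
prod_expr <- function(exprs) {
  Reduce(function(a, b) call("*", a, b), exprs)
}

# Evaluate expr on an expanded grid given as a named list of vectors; returns
# a numeric vector over the full expansion.
eval_on_grid <- function(expr, grid) {
  g <- do.call(expand.grid, c(grid, KEEP.OUT.ATTRS = FALSE))
  eval_expr(expr, as.list(g))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Asymptotic Kolmogorov-Smirnov critical values.
# One-sample: D_crit = c(alpha)/sqrt(n); two-sample: c(alpha)*sqrt((n+m)/(n*m)),
# with c(alpha) = sqrt(-log(alpha/2)/2).
ks_critical <- function(alpha, n, m = NULL) {
  calpha <- sqrt(-log(alpha / 2) / 2)
  if (is.null(m)) calpha / sqrt(n) else calpha * sqrt((n + m) / (n * m))
}

# Central finite difference of f at x with step h.
num_deriv <- function(f, x, h) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Empirical CDF values of a candidate density at sorted query points by
# incremental adaptive quadrature from `lower`; returns a vectorised CDF
# function usable with stats::ks.test.
density_cdf <- function(dens, lower = 0, rel.tol = 1e-10) {
  force(dens)
  function(q) {
    ord <- order(q)
    qs <- q[ord]
    out <- numeric(length(qs))
    prev_q <- lower
    acc <- 0
    for (i in seq_along(qs)) {
      if (qs[i] > prev_q) {
        acc <- acc + stats::integrate(dens, prev_q, qs[i],
                                      rel.tol = rel.tol, abs.tol = 1e-12)$value
        prev_q <- qs[i]
      }
      out[i] <- acc
    }
    pmin(pmax(out[order(ord)], 0), 1)
  }
}
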