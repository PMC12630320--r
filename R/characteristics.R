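# Method of characteristics for the nuisance-elimination PDE
# a(u,v) ds/du + b(u,v) ds/dv = 0: solutions are first integrals of the
# characteristic ODE dv/du = b/a. The solver classifies the field into the
# structural families that arise from product densities (ratio-power,
# constant-ratio, degenerate) and falls back to a numerically traced first
# integral for general separable directions.

new_ft_transformation <- function(expr, outcomes, parameter_free,
                                  family = list(kind = "generic"),
                                  completion = NULL, method = "symbolic",
                                  fun = NULL, params_ref = list(),
                                  extra = list()) {
  structure(c(list(expr = expr, outcomes = outcomes,
                   parameter_free = parameter_free, family = family,
                   completion = completion, method = method, fun = fun,
                   params_ref = params_ref), extra),
            class = "ft_transformation")
}

#' @export
print.ft_transformation <- function(x, ...) {
  cat("<ft_transformation> s(", paste(x$outcomes, collapse = ", "), ") = ",
      if (!is.null(x$expr)) deparse1(x$expr) else "<numeric first integral>",
      "\n", sep = "")
  cat("  parameter-free: ", x$parameter_free,
      "; method: ", x$method, sep = "")
  if (!is.null(x$completion))
    cat("; completion A = ", deparse1(x$completion), sep = "")
  cat("\n")
  invisible(x)
}

#' Evaluate a transformation on outcome data
#'
#' @param tr An `ft_transformation`.
#' @param params Named parameter values for parameter-dependent
#'   transformations (merged over the stored reference values).
#' @return A function taking a matrix/data frame with one column per outcome
#'   (or separate vectors in outcome order) and returning the statistic.
#' @export
transformation_fun <- function(tr, params = list()) {
  pars <- utils::modifyList(tr$params_ref, params)
  force(tr)
  function(...) {
    args <- list(...)
    if (length(args) == 1 && (is.matrix(args[[1]]) || is.data.frame(args[[1]]))) {
      m <- args[[1]]
      vars <- stats::setNames(lapply(seq_along(tr$outcomes),
                                     function(j) as.numeric(m[, j])),
                              tr$outcomes)
    } else {
      vars <- stats::setNames(args[seq_along(tr$outcomes)], tr$outcomes)
    }
    if (!is.null(tr$fun)) return(do.call(tr$fun, c(vars, list(params = pars))))
    eval_expr(tr$expr, c(vars, pars))
  }
}

# Is an expression free of every symbol in `params`?
is_parameter_free <- function(expr, param_names) {
  !any(expr_symbols(expr) %in% param_names)
}

# Evaluate a field coefficient on the expanded outcome grid at parameters ps.
.eval_coeff <- function(field, name, ps) {
  vars <- c(do.call(expand.grid,
                    c(field$grid$outcomes, KEEP.OUT.ATTRS = FALSE)), ps)
  val <- eval_expr(field$coeffs[[name]], vars)
  rep_len(val, nrow(do.call(expand.grid, field$grid$outcomes)))
}

#' Solve the homogeneous characteristic PDE
#'
#' Finds a first integral of `a ds/du + b ds/dv = 0` for a two-outcome
#' characteristic field, canonicalised to a single representative of the
#' equivalence class of powers: the ratio `u/v` when the characteristic
#' direction is `dv/du = v/u`; `v/u^k` when it is `k*v/u` with exponent `k`
#' (possibly parameter-dependent); `u - v/k` when the direction is constant;
#' the single free outcome when one coefficient vanishes identically; and a
#' numerically traced first integral for general separable directions
#' (flagged `method = "numeric"`).
#'
#' @param field An `ft_field` over two outcomes.
#' @param tol Tolerance for the structural classification.
#' @return An `ft_transformation` with the suggested completion statistic
#'   (the last outcome symbol) and a `parameter_free` flag from a symbol
#'   scan.
#' @examples
#' solve_characteristics(characteristic_field(make_model("exp_hazard_pair")))
#' @export
solve_characteristics <- function(field, tol = 1e-8) {
  if (length(field$outcomes) != 2)
    stop("use solve_characteristics_block() for block size > 2", call. = FALSE)
  u <- field$outcomes[1]; v <- field$outcomes[2]
  usym <- as.name(u); vsym <- as.name(v)
  og <- field$grid$outcomes
  gg <- do.call(expand.grid, c(og, KEEP.OUT.ATTRS = FALSE))
  settings <- field$grid$params
  param_names <- unique(unlist(lapply(settings, names)))

  aa <- lapply(settings, function(ps) eval_expr(field$coeffs[[u]], c(gg, ps)))
  bb <- lapply(settings, function(ps) eval_expr(field$coeffs[[v]], c(gg, ps)))
  a_zero <- all(vapply(aa, function(x) all(abs(x) < tol), TRUE))
  b_zero <- all(vapply(bb, function(x) all(abs(x) < tol), TRUE))
  if (a_zero && b_zero)
    stop("both coefficients vanish identically", call. = FALSE)
  completion <- as.name(field$outcomes[length(field$outcomes)])
  if (a_zero)   # b ds/dv = 0: s must be free of v
    return(new_ft_transformation(usym, field$outcomes, TRUE,
                                 family = list(kind = "degenerate"),
                                 completion = vsym,
                                 params_ref = field$params_ref))
  if (b_zero)
    return(new_ft_transformation(vsym, field$outcomes, TRUE,
                                 family = list(kind = "degenerate"),
                                 completion = usym,
                                 params_ref = field$params_ref))

  rel_const <- function(x) max(abs(x / x[1] - 1))
  q <- Map(function(x, y) y / x, aa, bb)   # dv/du = b/a on the grid

  # ratio-power family: b/a = k * v/u with k constant in (u, v)
  kvals <- vapply(q, function(qq) {
    kk <- qq * gg[[u]] / gg[[v]]
    if (rel_const(kk) < 1e-6) kk[1] else NA_real_
  }, 0)
  if (!anyNA(kvals)) {
    k_across <- max(abs(kvals / kvals[1] - 1))
    if (k_across < 1e-6 && abs(kvals[1] - 1) < 1e-6) {
      expr <- call("/", usym, vsym)       # canonical representative u/v
      return(new_ft_transformation(
        expr, field$outcomes, TRUE,
        family = list(kind = "power_ratio", num = u, den = v, exponent = 1),
        completion = completion, params_ref = field$params_ref))
    }
    k_expr <- if (k_across < 1e-6) kvals[1] else
      bquote((.(field$coeffs[[v]]) * .(usym)) / (.(field$coeffs[[u]]) * .(vsym)))
    pf <- if (k_across < 1e-6) TRUE else FALSE
    expr <- bquote(.(vsym) / .(usym)^.(k_expr))
    return(new_ft_transformation(
      expr, field$outcomes, pf,
      family = list(kind = "power_ratio", num = v, den = u, exponent = k_expr),
      completion = completion, params_ref = field$params_ref))
  }

  # constant-direction family: b/a = k free of (u, v)
  kvals <- vapply(q, function(qq) if (rel_const(qq) < 1e-6) qq[1] else NA_real_, 0)
  if (!anyNA(kvals)) {
    k_across <- max(abs(kvals / kvals[1] - 1))
    if (k_across < 1e-6) {
      k0 <- kvals[1]
      expr <- if (abs(k0 - 1) < 1e-6) call("-", usym, vsym)
              else bquote(.(usym) - .(vsym) / .(k0))
      return(new_ft_transformation(
        expr, field$outcomes, TRUE,
        family = list(kind = "constant_ratio", exponent = k0),
        completion = completion, params_ref = field$params_ref))
    }
    k_expr <- bquote(.(field$coeffs[[v]]) / .(field$coeffs[[u]]))
    expr <- bquote(.(usym) - .(vsym) / .(k_expr))
    return(new_ft_transformation(
      expr, field$outcomes, FALSE,
      family = list(kind = "constant_ratio", exponent = k_expr),
      completion = completion, params_ref = field$params_ref))
  }

  # separable fallback: b/a = R1(u) R2(v); first integral int dv/R2 - int R1 du,
  # traced numerically at the reference parameter values.
  ps <- settings[[1]]
  qfun <- function(uu, vv) {
    vars <- stats::setNames(list(uu, vv), c(u, v))
    eval_expr(field$coeffs[[v]], c(vars, ps)) /
      eval_expr(field$coeffs[[u]], c(vars, ps))
  }
  u0 <- stats::median(og[[u]]); v0 <- stats::median(og[[v]])
  cross <- outer(og[[u]], og[[v]], qfun) * qfun(u0, v0) /
    (outer(og[[u]], rep(v0, length(og[[v]])), qfun) *
       outer(rep(u0, length(og[[u]])), og[[v]], qfun))
  if (max(abs(cross - 1)) > 1e-6)
    stop("no closed-form first integral and the direction field is not ",
         "separable; cannot trace characteristics", call. = FALSE)
  R1 <- function(x) qfun(x, v0)
  R2i <- function(x) qfun(u0, v0) / qfun(u0, x)  # 1/R2(v)
  Gf <- function(x) vapply(x, function(xi)
    stats::integrate(R1, u0, xi, rel.tol = 1e-10)$value, 0)
  Ff <- function(x) vapply(x, function(xi)
    stats::integrate(R2i, v0, xi, rel.tol = 1e-10)$value, 0)
  fun <- function(..., params = list()) {
    args <- list(...)
    Ff(args[[v]]) - Gf(args[[u]])
  }
  new_ft_transformation(NULL, field$outcomes, FALSE,
                        family = list(kind = "separable_numeric"),
                        completion = completion, method = "numeric",
                        fun = fun, params_ref = field$params_ref)
}

# cumulative trapezoid antiderivative on a grid
cumtrap <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Solve the characteristic system for a block of m outcomes
#'
#' For a product-structure block (each PDE coefficient depends only on its
#' own outcome), solves the pairwise equations against the last outcome,
#' yielding m-1 functionally independent first integrals plus the completion
#' statistic `r = y_m`, and checks joint bijectivity via a non-vanishing
#' Jacobian on the outcome grid.
#'
#' @param field An `ft_field` over m >= 2 outcomes.
#' @param tol Classification tolerance passed to [solve_characteristics()].
#' @return List with `transforms` (m-1 `ft_transformation`s), `completion`,
#'   and `jacobian_ok`.
#' @export
solve_characteristics_block <- function(field, tol = 1e-8) {
  m <- length(field$outcomes)
  if (m < 2) stop("block size must be at least 2", call. = FALSE)
  if (m == 2) {
    tr <- solve_characteristics(field, tol)
    return(list(transforms = list(tr), completion = tr$completion,
                jacobian_ok = completion_bijective(list(tr), field)))
  }
  last <- field$outcomes[m]
  transforms <- lapply(field$outcomes[-m], function(o) {
    sub <- field
    sub$outcomes <- c(o, last)
    sub$coeffs <- field$coeffs[c(o, last)]
    sub$grid$outcomes <- field$grid$outcomes[c(o, last)]
    solve_characteristics(sub, tol)
  })
  if (length(transforms) < m - 1)
    stop("fewer than m-1 independent first integrals found", call. = FALSE)
  list(transforms = transforms, completion = as.name(last),
       jacobian_ok = completion_bijective(transforms, field))
}

# Jacobian of (s_1, ..., s_{m-1}, y_m) wrt (y_1, ..., y_m) must not vanish
# anywhere on the outcome grid (checked at the reference parameters).
completion_bijective <- function(transforms, field) {
  outs <- field$outcomes
  m <- length(outs)
  exprs <- c(lapply(transforms, function(tr) tr$expr),
             list(as.name(outs[m])))
  if (any(vapply(exprs, is.null, TRUE))) return(NA)
  gg <- do.call(expand.grid, c(field$grid$outcomes, KEEP.OUT.ATTRS = FALSE))
  vars <- c(gg, field$params_ref)
  n <- nrow(gg)
  dets <- vapply(seq_len(n), function(i) {
    J <- matrix(0, m, m)
    vi <- lapply(vars, function(col) if (length(col) > 1) col[i] else col)
    for (r in seq_len(m)) for (cix in seq_len(m))
      J[r, cix] <- eval_expr(deriv_expr(exprs[[r]], outs[cix]), vi)
    det(J)
  }, 0)
  all(abs(dets) > 1e-12)
}

#' Residual of a transformation against its characteristic field
#'
#' Computes `sum_j a_j ds/dy_j`, with exact symbolic partial derivatives of
#' the transformation, scaled by the magnitude of the individual terms, and
#' maximised over the outcome-by-parameter grid. A valid first integral has
#' residual numerically zero.
#'
#' @param tr An `ft_transformation` with a symbolic expression.
#' @param field The `ft_field` it was derived from.
#' @return Maximum scaled residual (numeric).
#' @export
pde_residual <- function(tr, field) {
  gg <- do.call(expand.grid, c(field$grid$outcomes, KEEP.OUT.ATTRS = FALSE))
  worst <- 0
  for (ps in field$grid$params) {
    vars <- c(gg, ps)
    terms <- lapply(field$outcomes, function(o) {
      ds <- if (!is.null(tr$expr)) eval_expr(deriv_expr(tr$expr, o), vars)
      else num_partial(tr, o, gg, ps)
      eval_expr(field$coeffs[[o]], vars) * ds
    })
    tot <- Reduce(`+`, terms)
    scale <- Reduce(`+`, lapply(terms, abs))
    worst <- max(worst, max(abs(tot) / pmax(scale, 1e-300)))
  }
  worst
}

# central-difference partial for numeric-method transformations
num_partial <- function(tr, o, gg, ps) {
  f <- transformation_fun(tr, ps)
  h <- pmax(abs(gg[[o]]), 1) * 1e-6
  up <- gg; up[[o]] <- gg[[o]] + h
  dn <- gg; dn[[o]] <- gg[[o]] - h
  (do.call(f, as.list(up)) - do.call(f, as.list(dn))) / (2 * h)
}

#' Do two statistics share their level sets?
#'
#' Evaluates both on a scattered grid and checks for a strictly monotone
#' functional relationship (rank correlation of magnitude one), the
#' operational meaning of equivalence `{s^k : k != 0}`.
#'
#' @param f1,f2 Functions of the outcome vectors (e.g. from
#'   [transformation_fun()]).
#' @param grid Named list of outcome vectors (scattered points).
#' @param tol Tolerance on `1 - |spearman rho|`.
#' @return Logical.
#' @export
same_level_sets <- function(f1, f2, grid, tol = 1e-10) {
  s1 <- do.call(f1, unname(grid))
  s2 <- do.call(f2, unname(grid))
  abs(abs(stats::cor(rank(s1), rank(s2))) - 1) < tol
}

#' Canonical representative of a transformation's equivalence class
#'
#' Strips an outer numeric power or multiplicative/additive numeric constant
#' from the expression (any power `s^k`, `k != 0`, has the same level sets).
#' Idempotent.
#'
#' @param tr An `ft_transformation`.
#' @return The canonicalised `ft_transformation`.
#' @export
canonicalise <- function(tr) {
  e <- tr$expr
  if (is.null(e)) return(tr)
  repeat {
    if (is.call(e) && identical(e[[1]], as.name("("))) {
      e <- e[[2]]
    } else if (is.call(e) && identical(e[[1]], as.name("^")) && is.numeric(e[[3]])) {
      e <- e[[2]]
    } else if (is.call(e) && identical(e[[1]], as.name("*")) &&
               (is.numeric(e[[2]]) || is.numeric(e[[3]]))) {
      e <- if (is.numeric(e[[2]])) e[[3]] else e[[2]]
    } else if (is.call(e) && identical(e[[1]], as.name("+")) &&
               (is.numeric(e[[2]]) || is.numeric(e[[3]]))) {
      e <- if (is.numeric(e[[2]])) e[[3]] else e[[2]]
    } else break
  }
  tr$expr <- e
  tr
}

#' Perturbation specification for the inhomogeneous extension
#'
#' Quadratic local expansion `h(lambda) = kappa + eps1*(lambda - lambda0) +
#' eps2*(lambda - lambda0)^2` of a slowly varying right-hand side.
#'
#' @param lambda0 Base point of the expansion.
#' @param kappa Constant term.
#' @param eps1,eps2 Small linear and quadratic coefficients.
#' @return An object of class `ft_perturbation`.
#' @export
perturbation_spec <- function(lambda0 = 1, kappa = 0, eps1 = 0, eps2 = 0) {
  stopifnot(is.finite(eps1), is.finite(eps2), is.finite(kappa), is.finite(lambda0))
  structure(list(lambda0 = lambda0, kappa = kappa, eps1 = eps1, eps2 = eps2),
            class = "ft_perturbation")
}

#' Solve the inhomogeneous characteristic equation
#'
#' For `d/d lambda s(t(w; lambda), c(v; lambda)) = h(lambda)` with `h` the
#' quadratic expansion of a perturbation specification, returns the
#' homogeneous first integral plus the particular term
#' `P(lambda) = kappa*(lambda - lambda0) + eps1*(lambda - lambda0)^2/2 +
#' eps2*(lambda - lambda0)^3/3` obtained by integrating `h` along a
#' characteristic parameterised by the nuisance. As `eps1, eps2 -> 0` with
#' `kappa = 0` the solution reduces to the homogeneous one (verified by
#' substitution).
#'
#' @param field An `ft_field` over two outcomes.
#' @param pert An `ft_perturbation`.
#' @return An `ft_transformation` whose expression carries the explicit
#'   nuisance-integral term; element `homogeneous` holds the unperturbed
#'   solution and `limit_ok` records the eps -> 0 check.
#' @export
solve_inhomogeneous <- function(field, pert) {
  hom <- solve_characteristics(field)
  if (is.null(hom$expr))
    stop("characteristic parameterisation by the nuisance unavailable ",
         "(homogeneous solution is numeric)", call. = FALSE)
  L <- as.name(field$wrt)
  P <- bquote(.(pert$kappa) * (.(L) - .(pert$lambda0)) +
                .(pert$eps1) * (.(L) - .(pert$lambda0))^2 / 2 +
                .(pert$eps2) * (.(L) - .(pert$lambda0))^3 / 3)
  expr <- call("+", hom$expr, P)
  # eps, kappa -> 0 limit: the particular term with zeroed coefficients must
  # vanish identically in the nuisance, leaving the homogeneous solution
  Pzero <- bquote(0 * (.(L) - .(pert$lambda0)) +
                    0 * (.(L) - .(pert$lambda0))^2 / 2 +
                    0 * (.(L) - .(pert$lambda0))^3 / 3)
  lam_probe <- stats::setNames(list(c(0.3, 1, 2.7)), field$wrt)
  lim_ok <- all(abs(eval_expr(Pzero, lam_probe)) < 1e-14)
  new_ft_transformation(
    expr, field$outcomes, FALSE,
    family = list(kind = "inhomogeneous"),
    completion = hom$completion, params_ref = field$params_ref,
    extra = list(homogeneous = hom, perturbation = pert, limit_ok = lim_ok))
}

#' Leading-order simplification of a parameter-dependent transformation
#'
#' Substitutes an expansion point into the parameter-dependent parts of a
#' transformation (e.g. the exponent of a ratio-power solution) and returns
#' the parameter-free leading-order statistic. For ratio-power families it
#' also returns the plug-in variant in which the unknown exponent is
#' replaced by its crude data-based estimate, the outcome ratio itself.
#'
#' @param tr An `ft_transformation`.
#' @param at Named list giving the expansion point (e.g. `list(lambda = 0)`).
#' @return A parameter-free `ft_transformation`; for ratio-power inputs the
#'   element `plugin` holds the plug-in variant.
#' @export
taylor_simplify <- function(tr, at = list()) {
  if (tr$parameter_free) return(tr)
  if (is.null(tr$expr))
    stop("expansion requires a symbolic transformation", call. = FALSE)
  e <- subst_expr(tr$expr, at)
  if (identical(tr$family$kind, "power_ratio")) {
    # exponent limit at the expansion point: direct evaluation where finite,
    # otherwise approach along a shrinking step (the unsimplified exponent
    # can be 0/0 exactly at the point) with one Richardson step
    kexp <- tr$family$exponent
    probe <- function(fill) {
      free <- setdiff(expr_symbols(kexp), names(at))
      base <- stats::setNames(as.list(rep(fill, length(free))), free)
      k_of <- function(shift)
        eval_expr(kexp, c(base, lapply(at, function(v) v + shift)))
      v0 <- k_of(0)
      if (is.finite(v0)) return(v0)
      vs <- vapply(c(1e-3, 1e-4, 1e-5), k_of, 0)
      if (!all(is.finite(vs)) || abs(vs[2] - vs[3]) > 1e-2)
        stop("expansion not defined at the given point", call. = FALSE)
      vs[3] + (vs[3] - vs[2]) / 9
    }
    k1 <- probe(0.7); k2 <- probe(1.3)
    if (!is.finite(k1) || abs(k1 - k2) > 1e-6)
      stop("expansion point does not remove the parameter dependence",
           call. = FALSE)
    if (abs(k1 - 1) < 1e-6) k1 <- 1
    num <- as.name(tr$family$num); den <- as.name(tr$family$den)
    expr <- if (k1 == 1) call("/", num, den)
            else bquote(.(num) / .(den)^.(k1))
    out <- new_ft_transformation(
      expr, tr$outcomes, TRUE,
      family = list(kind = "power_ratio", num = tr$family$num,
                    den = tr$family$den, exponent = k1),
      completion = tr$completion, params_ref = tr$params_ref)
    # crude plug-in for the exponent: the inverse outcome ratio den/num
    out$plugin <- bquote(.(num) / .(den)^(.(den) / .(num)))
    return(out)
  }
  syms <- expr_symbols(e)
  pf <- !any(syms %in% names(tr$params_ref))
  if (!pf) stop("expansion not defined at the given point", call. = FALSE)
  new_ft_transformation(e, tr$outcomes, TRUE, family = tr$family,
                        completion = tr$completion, params_ref = tr$params_ref)
}
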