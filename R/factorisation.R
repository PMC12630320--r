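# Factorisation condition and characteristic fields.
#
# A model density f(y; psi, lambda) admits a nuisance-transferring change of
# variables when it can be written kappa * prod_j dw_j/dy_j * g(w_1,...,w_m;
# psi) with g free of the nuisance symbol. The per-outcome derivative of the
# inverse map with respect to the nuisance, back-substituted through the
# forward map, gives the coefficients of the first-order homogeneous PDE
# a_1 ds/dy_1 + ... + a_m ds/dy_m = 0 whose first integrals are the
# nuisance-free statistics.

#' Verify the factorisation condition for a change of variables
#'
#' Checks that the model's joint density equals
#' `kappa * prod_j w_j'(y_j) * g(w_1(y_1), ..., w_m(y_m))` identically, by
#' exact symbolic construction of the right-hand side followed by evaluation
#' on an outcome-by-parameter grid. Also checks that each forward map is
#' strictly monotone (bijective) on the support.
#'
#' @param model An `ft_model`.
#' @param cov A change of variables (class `ft_cov`); defaults to the model's.
#' @param n_grid Points per outcome axis (default 5, as a 5x5x5 grid over
#'   outcomes and parameter settings).
#' @param tol Maximum relative residual for a `TRUE` verdict.
#' @return List with `verdict` (logical), `max_residual`, and the grid sizes.
#' @examples
#' m <- make_model("exp_hazard_pair")
#' check_factorisation_form(m)$verdict
#' @export
check_factorisation_form <- function(model, cov = model$cov, n_grid = 5,
                                     tol = 1e-8) {
  if (is.null(cov)) stop("no change of variables supplied", call. = FALSE)
  if (model$discrete)
    stop("factorisation check requires continuous outcomes", call. = FALSE)
  if (!is.numeric(cov$kappa) || cov$kappa <= 0)
    stop("kappa must be a positive constant", call. = FALSE)

  # nuisance symbols must not survive in the base density
  g_syms <- expr_symbols(cov$base_density)
  bad <- intersect(g_syms, model$nuisances)
  if (length(bad))
    return(list(verdict = FALSE, max_residual = Inf,
                reason = paste("base density retains nuisance symbol(s):",
                               paste(bad, collapse = ", "))))

  # symbolic right-hand side: kappa * prod w_j' * g(w(y))
  dw <- lapply(model$outcomes, function(o) deriv_expr(cov$forward[[o]], o))
  wsub <- stats::setNames(lapply(model$outcomes, function(o) cov$forward[[o]]),
                          vapply(model$outcomes, function(o) cov$wsyms[[o]], ""))
  rhs <- call("*", cov$kappa, call("*", prod_expr(dw),
                                   subst_expr(cov$base_density, wsub)))

  settings <- model$test_points[seq_len(min(n_grid, length(model$test_points)))]
  max_res <- 0
  mono_ok <- TRUE
  for (ps in settings) {
    params <- resolve_params(model, shared = ps)
    og <- outcome_grid(model, params, n = n_grid)
    vars <- c(do.call(expand.grid, c(og, KEEP.OUT.ATTRS = FALSE)), params)
    f <- eval_expr(model$density, vars)
    r <- eval_expr(rhs, vars)
    max_res <- max(max_res, max(abs(r / f - 1)))
    # monotone forward maps: derivative keeps a constant, nonzero sign
    for (j in seq_along(model$outcomes)) {
      dv <- eval_expr(dw[[j]], vars)
      if (any(dv == 0) || length(unique(sign(dv))) > 1) mono_ok <- FALSE
    }
  }
  if (!mono_ok)
    stop("forward map is not strictly monotone on the support", call. = FALSE)
  list(verdict = max_res < tol, max_residual = max_res,
       n_settings = length(settings), n_grid = n_grid)
}

new_ft_field <- function(coeffs, wrt, outcomes, grid, params_ref,
                         model_name = NULL, nuisance_scope = "block") {
  structure(list(coeffs = coeffs, wrt = wrt, outcomes = outcomes,
                 grid = grid, params_ref = params_ref,
                 model_name = model_name, nuisance_scope = nuisance_scope),
            class = "ft_field")
}

#' @export
print.ft_field <- function(x, ...) {
  cat("<ft_field> d/d", x$wrt, " over (",
      paste(x$outcomes, collapse = ", "), ")\n", sep = "")
  for (o in x$outcomes)
    cat("  a_", o, " = ", deparse1(x$coeffs[[o]]), "\n", sep = "")
  invisible(x)
}

#' Characteristic field of the nuisance-elimination PDE
#'
#' For each outcome `y_j`, computes `a_j = d y_j(w_j; psi, nuisance) /
#' d nuisance` with the transformed coordinate back-substituted by the
#' forward map, i.e. the coefficient of `ds/dy_j` in the homogeneous
#' first-order PDE whose solutions have nuisance-free distributions.
#'
#' @param model An `ft_model` with a change of variables.
#' @param nuisance Name of the nuisance symbol to differentiate against
#'   (default the model's per-block nuisance).
#' @param cov Change of variables; defaults to the model's.
#' @param check If `TRUE` (default), first verify the factorisation
#'   condition.
#' @return An `ft_field` with one coefficient expression per outcome.
#' @examples
#' fld <- characteristic_field(make_model("exp_hazard_pair"))
#' fld
#' @export
characteristic_field <- function(model, nuisance = model$nuisances[1],
                                 cov = model$cov, check = TRUE) {
  if (is.null(cov)) stop("no change of variables available", call. = FALSE)
  if (!nuisance %in% c(model$nuisances, model$shared))
    stop("unknown nuisance symbol: ", nuisance, call. = FALSE)
  if (check) {
    chk <- check_factorisation_form(model, cov)
    if (!chk$verdict)
      stop("factorisation condition fails (max residual ",
           format(chk$max_residual), ")", call. = FALSE)
  }
  coeffs <- list()
  for (o in model$outcomes) {
    dinv <- deriv_expr(cov$inverse[[o]], nuisance)
    wsub <- stats::setNames(list(cov$forward[[o]]), cov$wsyms[[o]])
    coeffs[[o]] <- subst_expr(dinv, wsub)
  }
  settings <- model$test_points
  if (!is.null(model$covariates))
    settings <- lapply(settings, function(ps) c(ps, as.list(model$covariates)))
  grid <- list(
    outcomes = outcome_grid(model, model$ref, n = 8),
    params = settings)
  new_ft_field(coeffs, wrt = nuisance, outcomes = model$outcomes,
               grid = grid, params_ref = model$ref, model_name = model$name,
               nuisance_scope = if (nuisance %in% model$nuisances) "block" else "shared")
}

#' Joint solvability of two characteristic fields
#'
#' Two homogeneous PDEs over the same pair of outcomes share a non-constant
#' solution if and only if their characteristic directions coincide
#' everywhere, i.e. the determinant `a1*b2 - a2*b1` vanishes identically.
#' The determinant is evaluated on the outcome-by-parameter grid.
#'
#' @param field1,field2 `ft_field` objects over the same two outcomes.
#' @param tol Relative tolerance for the identical-vanishing verdict.
#' @return List with `solvable`, `max_scaled_determinant`, and when not
#'   solvable a `recommendation` naming which nuisance to eliminate (the
#'   per-block one is favoured, since each block contributes a fresh copy).
#' @export
joint_solvability <- function(field1, field2, tol = 1e-8) {
  if (!identical(field1$outcomes, field2$outcomes))
    stop("fields are over different outcome variables", call. = FALSE)
  if (length(field1$outcomes) != 2)
    stop("determinant criterion applies to two outcomes", call. = FALSE)
  u <- field1$outcomes[1]; v <- field1$outcomes[2]
  a1 <- field1$coeffs[[u]]; b1 <- field1$coeffs[[v]]
  a2 <- field2$coeffs[[u]]; b2 <- field2$coeffs[[v]]
  max_scaled <- 0
  for (ps in field1$grid$params) {
    vars <- c(do.call(expand.grid,
                      c(field1$grid$outcomes, KEEP.OUT.ATTRS = FALSE)), ps)
    t1 <- eval_expr(a1, vars) * eval_expr(b2, vars)
    t2 <- eval_expr(a2, vars) * eval_expr(b1, vars)
    sc <- pmax(abs(t1), abs(t2), 1e-300)
    max_scaled <- max(max_scaled, max(abs(t1 - t2) / sc))
  }
  solvable <- max_scaled < tol
  out <- list(solvable = solvable, max_scaled_determinant = max_scaled)
  if (!solvable) {
    rec <- if (field1$nuisance_scope == "block") field1$wrt
           else if (field2$nuisance_scope == "block") field2$wrt
           else field1$wrt
    out$recommendation <- paste0(
      "no common non-constant solution; eliminate the per-block nuisance '",
      rec, "' (each block introduces a fresh copy)")
  }
  out
}

# Multiply all coefficients of a field by a scalar or expression (used to
# test proportional-direction invariance).
scale_field <- function(field, factor) {
  field$coeffs <- lapply(field$coeffs, function(e) call("*", factor, e))
  field
}
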