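# Numerical certification that a statistic's distribution is free of the
# block nuisance parameter. The operational criterion is the Laplace
# transform of the statistic under the joint model, evaluated on a real grid
# of transform arguments: if T_lambda(s, z) = E[exp(-z s(Y))] has zero
# partial derivative in lambda identically in z and psi, the distribution of
# s(Y) cannot depend on lambda. A distributional Kolmogorov-Smirnov check on
# simulated values backs the transform criterion (and replaces it when the
# transform diverges, e.g. for statistics unbounded below under heavy
# tails). No transform inversion is ever performed.

#' Laplace transform of a statistic under a catalog model
#'
#' Computes `E[exp(-z * s(Y))]` by nested adaptive quadrature over the
#' outcome support at fixed parameter values.
#'
#' @param model A two-outcome `ft_model`.
#' @param s An `ft_transformation`, a quoted expression in the outcome
#'   symbols, or a function of the two outcomes.
#' @param z Positive transform argument.
#' @param psi,lambda Parameter values (interest / per-block nuisance).
#' @param shared Named list of shared parameter values.
#' @param rel_tol Quadrature relative tolerance.
#' @return The transform value (estimated absolute error below 1e-7 for
#'   integrable statistics).
#' @examples
#' m <- make_model("exp_hazard_pair")
#' laplace_transform_value(m, quote(t / c), z = 1, psi = 1, lambda = 2)
#' @export
laplace_transform_value <- function(model, s, z, psi, lambda, shared = list(),
                                    rel_tol = 1e-10) {
  if (z <= 0) stop("z must be positive", call. = FALSE)
  if (model$m != 2) stop("two-outcome models only", call. = FALSE)
  params <- resolve_params(model, psi = psi, nuisance = lambda, shared = shared)
  sfun <- as_s_function(s, model$outcomes)
  o1 <- model$outcomes[1]; o2 <- model$outcomes[2]
  d1 <- model$arm_density[[o1]]; d2 <- model$arm_density[[o2]]
  sup1 <- model$support[[o1]]; sup2 <- model$support[[o2]]
  inner <- function(t1) {
    f <- function(t2) {
      vars <- params; vars[[o1]] <- t1; vars[[o2]] <- t2
      exp(-z * sfun(t1, t2)) * eval_expr(d2, vars)
    }
    stats::integrate(Vectorize(f), sup2[1], sup2[2],
                     rel.tol = rel_tol, abs.tol = 1e-12,
                     stop.on.error = TRUE)$value
  }
  outer_f <- function(t1v) {
    vapply(t1v, function(t1) {
      vars <- params; vars[[o1]] <- t1
      eval_expr(d1, vars) * inner(t1)
    }, 0)
  }
  res <- tryCatch(
    stats::integrate(outer_f, sup1[1], sup1[2],
                     rel.tol = rel_tol, abs.tol = 1e-12),
    error = function(e)
      stop("divergent or non-evaluable transform integral: ",
           conditionMessage(e), " (use the KS-based check instead)",
           call. = FALSE))
  res$value
}

# Normalise the accepted statistic representations to function(t1, t2).
as_s_function <- function(s, outcomes) {
  if (inherits(s, "ft_transformation")) {
    f <- transformation_fun(s)
    return(function(t1, t2) f(t1, t2))
  }
  if (is.function(s)) return(s)
  if (is.language(s) || is.numeric(s)) {
    force(s)
    return(function(t1, t2)
      eval_expr(s, stats::setNames(list(t1, t2), outcomes)))
  }
  stop("unsupported statistic representation", call. = FALSE)
}

#' Grid specification for the transform-based independence probe
#'
#' @param z Positive transform arguments.
#' @param lambda Nuisance values (at least 3 for a meaningful check).
#' @param psi Interest value(s).
#' @return An object of class `ft_probe`.
#' @export
laplace_probe <- function(z = c(0.5, 1, 2), lambda = c(0.5, 1, 2), psi = 1) {
  stopifnot(all(z > 0), all(is.finite(lambda)), all(is.finite(psi)))
  if (length(lambda) < 3) stop("need at least 3 lambda values", call. = FALSE)
  structure(list(z = z, lambda = lambda, psi = psi), class = "ft_probe")
}

#' Certify nuisance independence of a statistic
#'
#' Two-pronged check that the distribution of `s(Y)` is free of the
#' per-block nuisance: (i) the supremum over the probe grid of the central
#' finite-difference derivative of the Laplace transform with respect to the
#' nuisance must be below `fd_tol`; (ii) all pairwise two-sample
#' Kolmogorov-Smirnov statistics between simulated statistic values at
#' different nuisance values must fall below the 1% critical value. When the
#' transform diverges for the given statistic, the verdict rests on the KS
#' table alone.
#'
#' @param model A two-outcome `ft_model`.
#' @param s Statistic (expression, function or `ft_transformation`).
#' @param probe An [laplace_probe()] grid.
#' @param n_mc Monte-Carlo sample size per nuisance value.
#' @param seed Integer seed.
#' @param fd_tol Tolerance on the transform derivative.
#' @return List of class `ft_independence`: `independent` (verdict),
#'   `max_abs_dTdlambda`, `ks_table`, `ks_critical`, `transform_ok`.
#' @export
lambda_independence_check <- function(model, s, probe = laplace_probe(),
                                      n_mc = 20000, seed = 1,
                                      fd_tol = 1e-5) {
  sfun <- as_s_function(s, model$outcomes)
  # (i) transform derivative on the grid
  max_d <- 0
  transform_ok <- TRUE
  for (psi in probe$psi) {
    for (lam in probe$lambda) {
      for (z in probe$z) {
        h <- 1e-4 * abs(lam)
        d <- tryCatch({
          tp <- laplace_transform_value(model, s, z, psi, lam + h)
          tm <- laplace_transform_value(model, s, z, psi, lam - h)
          abs(tp - tm) / (2 * h)
        }, error = function(e) NA_real_)
        if (is.na(d)) transform_ok <- FALSE else max_d <- max(max_d, d)
      }
    }
  }
  # (ii) pairwise KS across nuisance values at the first interest value
  nl <- length(probe$lambda)
  samples <- vector("list", nl)
  for (i in seq_len(nl)) {
    wide <- sample_blocks(model, b = n_mc, psi = probe$psi[1],
                          nuisance = probe$lambda[i], seed = seed + i,
                          format = "wide")
    samples[[i]] <- sfun(wide[, 1], wide[, 2])
  }
  ks <- matrix(NA_real_, nl, nl,
               dimnames = list(probe$lambda, probe$lambda))
  for (i in seq_len(nl - 1)) for (j in (i + 1):nl)
    ks[i, j] <- ks[j, i] <-
      suppressWarnings(stats::ks.test(samples[[i]], samples[[j]])$statistic)
  crit <- ks_critical(0.01, n_mc, n_mc)
  ks_ok <- all(ks[upper.tri(ks)] < crit)
  verdict <- ks_ok && (!transform_ok || max_d < fd_tol)
  structure(list(independent = verdict,
                 max_abs_dTdlambda = if (transform_ok) max_d else NA_real_,
                 transform_ok = transform_ok,
                 ks_table = ks, ks_critical = crit, n_mc = n_mc),
            class = "ft_independence")
}

#' @export
print.ft_independence <- function(x, ...) {
  cat("<ft_independence> verdict:",
      if (x$independent) "independent" else "NOT independent", "\n")
  cat("  max |dT/dlambda| =", format(x$max_abs_dTdlambda),
      if (!x$transform_ok) "(transform divergent; KS only)", "\n")
  cat("  max pairwise KS  =", format(max(x$ks_table, na.rm = TRUE)),
      " (1% critical ", format(x$ks_critical), ")\n", sep = "")
  invisible(x)
}

#' Compare the statistic's distribution between two parameter settings
#'
#' Two-sample Kolmogorov-Smirnov comparison of simulated statistic values
#' under two full parameter settings (used e.g. to show that a distribution
#' depends on the parameters only through a product such as `psi * lambda`).
#'
#' @param model A two-outcome `ft_model`.
#' @param s Statistic.
#' @param setting_a,setting_b Lists with components `psi` and `lambda`.
#' @param n_mc,seed Monte-Carlo controls.
#' @return List with the KS statistic `D` and the 1% critical value.
#' @export
transform_ks_compare <- function(model, s, setting_a, setting_b,
                                 n_mc = 20000, seed = 1) {
  sfun <- as_s_function(s, model$outcomes)
  wa <- sample_blocks(model, n_mc, psi = setting_a$psi,
                      nuisance = setting_a$lambda, seed = seed, format = "wide")
  wb <- sample_blocks(model, n_mc, psi = setting_b$psi,
                      nuisance = setting_b$lambda, seed = seed + 1,
                      format = "wide")
  D <- suppressWarnings(
    stats::ks.test(sfun(wa[, 1], wa[, 2]), sfun(wb[, 1], wb[, 2]))$statistic)
  list(D = as.numeric(D), critical = ks_critical(0.01, n_mc, n_mc))
}

#' Check a closed-form marginal density for a statistic
#'
#' Validates a candidate marginal density for `s(Y)`: the candidate must be
#' normalised (checked by quadrature), and one-sample Kolmogorov-Smirnov
#' tests of simulated statistic values against the candidate CDF must pass
#' at the 1% level for every nuisance value in the grid.
#'
#' @param model A two-outcome `ft_model`.
#' @param s Statistic.
#' @param density Candidate density: `function(sv)` of the statistic value
#'   (already parameterised), or a quoted expression in symbol `s` plus
#'   parameter symbols resolved from `psi`/`shared`.
#' @param psi Interest value.
#' @param lambda_grid Nuisance values to test under.
#' @param shared Shared parameter values.
#' @param support Support of the statistic (default `c(0, Inf)`).
#' @param n_mc,seed Monte-Carlo controls.
#' @return List of class `ft_density_check`: `pass`, per-lambda KS table,
#'   `normalisation`.
#' @export
marginal_density_check <- function(model, s, density, psi,
                                   lambda_grid = c(0.3, 1, 3),
                                   shared = list(), support = c(0, Inf),
                                   n_mc = 20000, seed = 1) {
  sfun <- as_s_function(s, model$outcomes)
  dens <- if (is.function(density)) density else {
    force(density)
    params <- resolve_params(model, psi = psi, shared = shared)
    function(sv) eval_expr(density, c(list(s = sv), params))
  }
  norm <- stats::integrate(dens, support[1], support[2], rel.tol = 1e-9)$value
  if (abs(norm - 1) > 1e-6)
    stop("candidate density is not normalised (mass ", format(norm), ")",
         call. = FALSE)
  cdf <- density_cdf(dens, lower = support[1])
  ks <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    wide <- sample_blocks(model, n_mc, psi = psi, nuisance = lambda_grid[i],
                          shared = shared, seed = seed + i, format = "wide")
    sv <- sfun(wide[, 1], wide[, 2])
    ks[i] <- suppressWarnings(stats::ks.test(sv, cdf)$statistic)
  }
  crit <- ks_critical(0.01, n_mc)
  structure(list(pass = all(ks < crit), ks = stats::setNames(ks, lambda_grid),
                 ks_critical = crit, normalisation = norm),
            class = "ft_density_check")
}

#' Ratio density for the exponential mean-shift pair
#'
#' Density of the crude ratio statistic `C/T` in the exponential pair model
#' with means `mu - psi` and `mu + psi`: it depends on the parameters only
#' through the product `rho = psi * lambda`,
#' `f(s; rho) = (1 - rho^2) / (1 + s + rho*(1 - s))^2` for `s > 0`.
#'
#' @param s Nonnegative statistic value(s).
#' @param rho Product `psi * lambda`, with `|rho| < 1`.
#' @return Density value(s).
#' @examples
#' exp_shift_ratio_density(1, 0.4)  # (1 - 0.16)/4
#' @export
exp_shift_ratio_density <- function(s, rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be below 1", call. = FALSE)
  if (any(s < 0)) stop("s must be nonnegative", call. = FALSE)
  (1 - rho^2) / (1 + s + rho * (1 - s))^2
}

#' @rdname exp_shift_ratio_density
#' @export
exp_shift_ratio_cdf <- function(s, rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be below 1", call. = FALSE)
  1 - (1 + rho) / ((1 + rho) + (1 - rho) * pmax(s, 0))
}
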