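# Auxiliary constructions: the Gram-Schmidt pair of exponential-kernel
# functions orthogonal on (0, Inf), the Stein operator characterising the
# exponential distribution, and the quantile-flow identity linking sample
# and parameter spaces in a local location model.

#' Gram-Schmidt orthogonal pair of exponential kernels
#'
#' From `f0(c) = exp(-lambda c / psi)` and the linearly independent
#' `f1(c) = exp(-lambda kappa c / psi)` (`kappa != 1`), builds the function
#' `phi1` orthogonal to `phi0 = f0` on `(0, Inf)`:
#' `phi1(c) = sqrt(2 kappa lambda) (kappa + 1) / ((kappa - 1) sqrt(psi)) *
#' exp(-lambda kappa c / psi) - 2 sqrt(2 kappa lambda) / ((kappa - 1)
#' sqrt(psi)) * exp(-lambda c / psi)`. The closed-form inner products are
#' `<f0, f0> = psi/(2 lambda)`, `<f0, f1> = psi/(lambda + kappa lambda)`,
#' `<f1, f1> = psi/(2 kappa lambda)`.
#'
#' @param kappa Index of the family, positive and different from 1.
#' @param lambda,psi Positive parameters of the kernels.
#' @return List of class `ft_ortho_pair` with functions `phi0`, `phi1`,
#'   `f1`, the closed-form `inner_products`, the `normaliser`
#'   `(D0 D1)^{-1/2}`, and `orthogonality` (the quadrature value of
#'   `integral phi0 phi1`, numerically zero).
#' @examples
#' op <- build_ortho_pair(kappa = 2, lambda = 1, psi = 1)
#' op$inner_products[["f0f1"]]  # 1/3
#' @export
build_ortho_pair <- function(kappa, lambda, psi) {
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (abs(kappa - 1) < 1e-12)
    stop("kappa = 1: f1 is not linearly independent of f0", call. = FALSE)
  if (lambda <= 0 || psi <= 0) stop("lambda, psi must be positive", call. = FALSE)
  phi0 <- function(c) exp(-lambda * c / psi)
  f1 <- function(c) exp(-lambda * kappa * c / psi)
  ip <- c(f0f0 = psi / (2 * lambda),
          f0f1 = psi / (lambda + kappa * lambda),
          f1f1 = psi / (2 * kappa * lambda))
  normaliser <- 2 * sqrt(2) * sqrt(kappa) * (kappa + 1) * lambda^(3 / 2) /
    ((kappa - 1) * psi^(3 / 2))
  A <- sqrt(2 * kappa * lambda) * (kappa + 1) / ((kappa - 1) * sqrt(psi))
  B <- 2 * sqrt(2 * kappa * lambda) / ((kappa - 1) * sqrt(psi))
  phi1 <- function(c) A * exp(-lambda * kappa * c / psi) - B * exp(-lambda * c / psi)
  # the target value is 0: absolute-accuracy quadrature, ignore the
  # unattainable relative-error flag
  orth <- stats::integrate(function(c) phi0(c) * phi1(c), 0, Inf,
                           rel.tol = 1e-10, abs.tol = 1e-12,
                           stop.on.error = FALSE)$value
  structure(list(phi0 = phi0, phi1 = phi1, f1 = f1,
                 inner_products = ip, normaliser = normaliser,
                 orthogonality = orth,
                 params = c(kappa = kappa, lambda = lambda, psi = psi)),
            class = "ft_ortho_pair")
}

#' @export
print.ft_ortho_pair <- function(x, ...) {
  p <- x$params
  cat("<ft_ortho_pair> kappa =", p["kappa"], " lambda =", p["lambda"],
      " psi =", p["psi"], "\n")
  cat("  <f0,f0> =", x$inner_products["f0f0"],
      " <f0,f1> =", x$inner_products["f0f1"],
      " <f1,f1> =", x$inner_products["f1f1"], "\n")
  cat("  integral phi0*phi1 =", format(x$orthogonality), "\n")
  invisible(x)
}

#' Expectation of the exponential Stein operator
#'
#' For the exponential distribution of rate `rho`, the operator
#' `(A f)(x) = (1 - rho x) f'(x) + x f''(x)` annihilates every smooth
#' bounded test function in expectation; a nonzero expectation under some
#' other law witnesses that the law is not Exp(rho). Computes
#' `E[(A f)(X)]` by adaptive quadrature. If `f` is given as a quoted
#' expression in `x`, the derivatives are exact (symbolic); for a plain
#' function, central differences with step `1e-4` are used.
#'
#' @param f Test function: quoted expression in `x`, or `function(x)`.
#' @param rho Positive rate of the exponential law defining the operator.
#' @param sample_rho Rate of the law under which the expectation is taken
#'   (defaults to `rho`, the characterising case).
#' @param fprime,fdblprime Optional explicit derivative functions.
#' @return The expectation (numerically zero iff the sampling law is
#'   Exp(rho), for admissible `f`).
#' @examples
#' stein_expectation(quote(sin(x) * exp(-x)), rho = 1)
#' @export
stein_expectation <- function(f, rho, sample_rho = rho,
                              fprime = NULL, fdblprime = NULL) {
  if (rho <= 0 || sample_rho <= 0) stop("rates must be positive", call. = FALSE)
  if (is.language(f)) {
    d1 <- deriv_expr(f, "x"); d2 <- deriv_expr(d1, "x")
    fprime <- function(x) eval_expr(d1, list(x = x)) + 0 * x
    fdblprime <- function(x) eval_expr(d2, list(x = x)) + 0 * x
  } else if (is.function(f)) {
    h <- 1e-4
    if (is.null(fprime)) fprime <- function(x) (f(x + h) - f(x - h)) / (2 * h)
    if (is.null(fdblprime))
      fdblprime <- function(x) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  } else stop("f must be an expression in x or a function", call. = FALSE)
  integrand <- function(x)
    ((1 - rho * x) * fprime(x) + x * fdblprime(x)) *
      sample_rho * exp(-sample_rho * x)
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                   stop.on.error = FALSE)$value
}

#' Quantile flow of a parametric family
#'
#' Rate of change of the `epsilon`-quantile path `y(theta)` defined by
#' `F(y(theta); theta) = epsilon`:
#' `dy/dtheta = -(dF/dtheta) / f(y; theta)`. The parameter derivative of
#' the CDF is taken by central differences unless supplied.
#'
#' @param cdf `function(y, theta)`.
#' @param pdf `function(y, theta)`, positive at `y`.
#' @param theta Parameter value.
#' @param y Outcome value at which to evaluate the flow.
#' @param dF_dtheta Optional exact `function(y, theta)`.
#' @return Numeric `dy/dtheta`.
#' @examples
#' # exponential rate family: dy/dtheta = -y/theta
#' quantile_flow(function(y, th) stats::pexp(y, th),
#'               function(y, th) stats::dexp(y, th), theta = 2, y = 1.5)
#' @export
quantile_flow <- function(cdf, pdf, theta, y, dF_dtheta = NULL) {
  dens <- pdf(y, theta)
  if (!is.finite(dens) || dens <= 0)
    stop("density must be positive at y", call. = FALSE)
  dF <- if (!is.null(dF_dtheta)) dF_dtheta(y, theta) else {
    h <- 1e-6 * max(1, abs(theta))
    (cdf(y, theta + h) - cdf(y, theta - h)) / (2 * h)
  }
  -dF / dens
}
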