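# Catalog of matched-comparison models: paired survival-type models with a
# per-pair nuisance (hazard-ratio exponential, Weibull, exponential mean
# shift), location pairs (normal, Cauchy), binary logistic pairs, an
# exponential triplet, and two single-block regression models (exponential
# and log-logistic accelerated life). Each entry carries the joint density
# as a symbolic expression, per-outcome support, parameter domains, a
# sampler, quantile functions, and -- where one exists -- the
# nuisance-transferring change of variables used by the factorisation
# machinery.

new_ft_model <- function(name, description, outcomes, arms, arm_density,
                         interest, nuisances, shared = character(0),
                         support, domains, ref, test_points,
                         sampler, qfun, cov = NULL, discrete = FALSE,
                         covariates = NULL, param_check = NULL,
                         closed = character(0)) {
  m <- list(
    name = name, description = description,
    outcomes = outcomes, arms = arms, m = length(outcomes),
    arm_density = arm_density,
    density = prod_expr(unname(arm_density)),
    interest = interest, nuisances = nuisances, shared = shared,
    support = support, domains = domains, ref = ref,
    test_points = test_points,
    sampler = sampler, qfun = qfun, cov = cov,
    discrete = discrete, covariates = covariates, closed = closed,
    param_check = param_check %||% function(params) TRUE
  )
  structure(m, class = "ft_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ft_model <- function(x, ...) {
  cat("<ft_model> ", x$name, "\n", sep = "")
  cat("  ", x$description, "\n", sep = "")
  cat("  outcomes: ", paste(x$outcomes, collapse = ", "),
      " (block size ", x$m, ")\n", sep = "")
  cat("  density:  ", deparse1(x$density), "\n", sep = "")
  cat("  interest: ", paste(x$interest, collapse = ", "),
      "; nuisance: ", paste(x$nuisances, collapse = ", "), sep = "")
  if (length(x$shared)) cat("; shared: ", paste(x$shared, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

# Change-of-variables container (one forward/inverse map per outcome, a
# nuisance-free base density over the transformed coordinates, and the
# positive constant absorbed by the factorisation).
new_ft_cov <- function(forward, inverse, wsyms, base_density, kappa = 1) {
  structure(list(forward = forward, inverse = inverse, wsyms = wsyms,
                 base_density = base_density, kappa = kappa),
            class = "ft_cov")
}

#' @export
print.ft_cov <- function(x, ...) {
  cat("<ft_cov> kappa =", x$kappa, "\n")
  for (nm in names(x$forward))
    cat("  ", x$wsyms[[nm]], "(", nm, ") = ", deparse1(x$forward[[nm]]), "\n", sep = "")
  cat("  base density g = ", deparse1(x$base_density), "\n", sep = "")
  invisible(x)
}

# ---- catalog entries -------------------------------------------------------

.catalog_builders <- list(

  normal_pair = function() {
    new_ft_model(
      name = "normal_pair",
      description = "Normal matched pairs, common variance, one free mean per pair",
      outcomes = c("y1", "y2"), arms = c("T", "C"),
      arm_density = list(
        y1 = quote(exp(-(y1 - mu)^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)),
        y2 = quote(exp(-(y2 - mu)^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2))),
      interest = "sigma2", nuisances = "mu",
      support = list(y1 = c(-Inf, Inf), y2 = c(-Inf, Inf)),
      domains = list(sigma2 = c(0, Inf), mu = c(-Inf, Inf)),
      ref = list(sigma2 = 1, mu = 0),
      test_points = lapply(
        list(c(0.5, -1), c(1, 0), c(2, 1), c(3, -2), c(0.25, 3)),
        function(p) list(sigma2 = p[1], mu = p[2])),
      closed = "sigma2",   # the degenerate sigma2 = 0 boundary is sampleable
      sampler = function(b, params, x = NULL) {
        sd <- sqrt(params$sigma2)
        cbind(T = stats::rnorm(b, params$mu, sd),
              C = stats::rnorm(b, params$mu, sd))
      },
      qfun = function(p, outcome, params)
        stats::qnorm(p, params$mu, sqrt(params$sigma2)),
      cov = new_ft_cov(
        forward = list(y1 = quote(y1 - mu), y2 = quote(y2 - mu)),
        inverse = list(y1 = quote(w + mu), y2 = quote(v + mu)),
        wsyms = list(y1 = "w", y2 = "v"),
        base_density = quote(exp(-(w^2 + v^2) / (2 * sigma2)) / (2 * pi * sigma2)),
        kappa = 1)
    )
  },

  logistic_pair = function() {
    new_ft_model(
      name = "logistic_pair",
      description = "Binary matched pairs, logistic treatment effect psi, one free log-odds lambda per pair",
      outcomes = c("t", "c"), arms = c("T", "C"),
      arm_density = list(
        t = quote(exp((lambda + psi) * t) / (1 + exp(lambda + psi))),
        c = quote(exp(lambda * c) / (1 + exp(lambda)))),
      interest = "psi", nuisances = "lambda",
      support = list(t = c(0, 1), c = c(0, 1)),
      domains = list(psi = c(-Inf, Inf), lambda = c(-Inf, Inf)),
      ref = list(psi = 1, lambda = 0),
      test_points = lapply(
        list(c(0, 0), c(1, -1), c(0.5, 1), c(2, 0.3), c(-1, 2)),
        function(p) list(psi = p[1], lambda = p[2])),
      sampler = function(b, params, x = NULL) {
        cbind(T = stats::rbinom(b, 1, stats::plogis(params$lambda + params$psi)),
              C = stats::rbinom(b, 1, stats::plogis(params$lambda)))
      },
      qfun = function(p, outcome, params) {
        pr <- if (outcome == "t") stats::plogis(params$lambda + params$psi)
              else stats::plogis(params$lambda)
        stats::qbinom(p, 1, pr)
      },
      discrete = TRUE
    )
  },

  exp_hazard_pair = function() {
    new_ft_model(
      name = "exp_hazard_pair",
      description = "Exponential pairs with constant hazard ratio psi^2 (rates lambda*psi and lambda/psi)",
      outcomes = c("t", "c"), arms = c("T", "C"),
      arm_density = list(
        t = quote(lambda * psi * exp(-lambda * psi * t)),
        c = quote((lambda / psi) * exp(-lambda * c / psi))),
      interest = "psi", nuisances = "lambda",
      support = list(t = c(0, Inf), c = c(0, Inf)),
      domains = list(psi = c(0, Inf), lambda = c(0, Inf)),
      ref = list(psi = 1.5, lambda = 1),
      test_points = lapply(
        list(c(1, 1), c(2, 0.5), c(0.5, 2), c(1.5, 1.2), c(3, 0.3)),
        function(p) list(psi = p[1], lambda = p[2])),
      sampler = function(b, params, x = NULL) {
        cbind(T = stats::rexp(b, rate = params$lambda * params$psi),
              C = stats::rexp(b, rate = params$lambda / params$psi))
      },
      qfun = function(p, outcome, params) {
        rate <- if (outcome == "t") params$lambda * params$psi
                else params$lambda / params$psi
        stats::qexp(p, rate)
      },
      cov = new_ft_cov(
        forward = list(t = quote(lambda * psi * t), c = quote(lambda * c / psi)),
        inverse = list(t = quote(w / (lambda * psi)), c = quote(psi * v / lambda)),
        wsyms = list(t = "w", c = "v"),
        base_density = quote(exp(-(w + v))),
        kappa = 1)
    )
  },

  exp_triplet = function() {
    new_ft_model(
      name = "exp_triplet",
      description = "Exponential triplets of rates lambda*psi1, lambda*psi2, lambda",
      outcomes = c("x1", "x2", "x3"), arms = c("arm1", "arm2", "arm3"),
      arm_density = list(
        x1 = quote(lambda * psi1 * exp(-lambda * psi1 * x1)),
        x2 = quote(lambda * psi2 * exp(-lambda * psi2 * x2)),
        x3 = quote(lambda * exp(-lambda * x3))),
      interest = c("psi1", "psi2"), nuisances = "lambda",
      support = list(x1 = c(0, Inf), x2 = c(0, Inf), x3 = c(0, Inf)),
      domains = list(psi1 = c(0, Inf), psi2 = c(0, Inf), lambda = c(0, Inf)),
      ref = list(psi1 = 1.5, psi2 = 0.8, lambda = 1),
      test_points = lapply(
        list(c(1, 1, 1), c(2, 0.5, 1), c(0.7, 1.3, 2), c(1.5, 0.8, 0.5), c(3, 2, 1.5)),
        function(p) list(psi1 = p[1], psi2 = p[2], lambda = p[3])),
      sampler = function(b, params, x = NULL) {
        cbind(arm1 = stats::rexp(b, params$lambda * params$psi1),
              arm2 = stats::rexp(b, params$lambda * params$psi2),
              arm3 = stats::rexp(b, params$lambda))
      },
      qfun = function(p, outcome, params) {
        rate <- switch(outcome,
                       x1 = params$lambda * params$psi1,
                       x2 = params$lambda * params$psi2,
                       x3 = params$lambda)
        stats::qexp(p, rate)
      },
      cov = new_ft_cov(
        forward = list(x1 = quote(lambda * psi1 * x1),
                       x2 = quote(lambda * psi2 * x2),
                       x3 = quote(lambda * x3)),
        inverse = list(x1 = quote(w1 / (lambda * psi1)),
                       x2 = quote(w2 / (lambda * psi2)),
                       x3 = quote(w3 / lambda)),
        wsyms = list(x1 = "w1", x2 = "w2", x3 = "w3"),
        base_density = quote(exp(-(w1 + w2 + w3))),
        kappa = 1)
    )
  },

  weibull_pair = function() {
    new_ft_model(
      name = "weibull_pair",
      description = "Weibull pairs, shared shape alpha, rates lambda*psi and lambda/psi",
      outcomes = c("t", "c"), arms = c("T", "C"),
      arm_density = list(
        t = quote(alpha * lambda * psi * t^(alpha - 1) * exp(-lambda * psi * t^alpha)),
        c = quote(alpha * (lambda / psi) * c^(alpha - 1) * exp(-(lambda / psi) * c^alpha))),
      interest = "psi", nuisances = "lambda", shared = "alpha",
      support = list(t = c(0, Inf), c = c(0, Inf)),
      domains = list(psi = c(0, Inf), lambda = c(0, Inf), alpha = c(0, Inf)),
      ref = list(psi = 1.5, lambda = 1, alpha = 2),
      test_points = lapply(
        list(c(1, 1, 2), c(2, 0.5, 1.5), c(0.5, 2, 3), c(1.5, 1.2, 0.8), c(3, 0.3, 2.5)),
        function(p) list(psi = p[1], lambda = p[2], alpha = p[3])),
      sampler = function(b, params, x = NULL) {
        a <- params$alpha
        cbind(T = stats::rweibull(b, shape = a,
                                  scale = (params$lambda * params$psi)^(-1 / a)),
              C = stats::rweibull(b, shape = a,
                                  scale = (params$lambda / params$psi)^(-1 / a)))
      },
      qfun = function(p, outcome, params) {
        a <- params$alpha
        sc <- if (outcome == "t") (params$lambda * params$psi)^(-1 / a)
              else (params$lambda / params$psi)^(-1 / a)
        stats::qweibull(p, shape = a, scale = sc)
      },
      cov = new_ft_cov(
        forward = list(t = quote(lambda * psi * t^alpha),
                       c = quote((lambda / psi) * c^alpha)),
        inverse = list(t = quote((w / (lambda * psi))^(1 / alpha)),
                       c = quote((psi * v / lambda)^(1 / alpha))),
        wsyms = list(t = "w", c = "v"),
        base_density = quote(exp(-(w + v))),
        kappa = 1)
    )
  },

  cauchy_pair = function() {
    new_ft_model(
      name = "cauchy_pair",
      description = "Cauchy pairs of common location lambda and interest scale psi",
      outcomes = c("t", "c"), arms = c("T", "C"),
      arm_density = list(
        t = quote(1 / (pi * psi * (1 + ((t - lambda) / psi)^2))),
        c = quote(1 / (pi * psi * (1 + ((c - lambda) / psi)^2)))),
      interest = "psi", nuisances = "lambda",
      support = list(t = c(-Inf, Inf), c = c(-Inf, Inf)),
      domains = list(psi = c(0, Inf), lambda = c(-Inf, Inf)),
      ref = list(psi = 1, lambda = 0),
      test_points = lapply(
        list(c(1, 0), c(2, 1), c(0.5, -1), c(1.5, 2), c(3, -3)),
        function(p) list(psi = p[1], lambda = p[2])),
      sampler = function(b, params, x = NULL) {
        cbind(T = stats::rcauchy(b, params$lambda, params$psi),
              C = stats::rcauchy(b, params$lambda, params$psi))
      },
      qfun = function(p, outcome, params)
        stats::qcauchy(p, params$lambda, params$psi),
      cov = new_ft_cov(
        forward = list(t = quote((t - lambda) / psi), c = quote((c - lambda) / psi)),
        inverse = list(t = quote(psi * w + lambda), c = quote(psi * v + lambda)),
        wsyms = list(t = "w", c = "v"),
        base_density = quote(1 / (pi^2 * (1 + w^2) * (1 + v^2))),
        kappa = 1)
    )
  },

  exp_regression = function() {
    new_ft_model(
      name = "exp_regression",
      description = "Exponential regression, E(Y_i) = lambda*exp(x_i*psi); pairwise reduction (y_i, y_1)",
      outcomes = c("yi", "y1"), arms = "y",
      arm_density = list(
        yi = quote(exp(-yi / (lambda * exp(xi * psi))) / (lambda * exp(xi * psi))),
        y1 = quote(exp(-y1 / (lambda * exp(x1 * psi))) / (lambda * exp(x1 * psi)))),
      interest = "psi", nuisances = "lambda",
      support = list(yi = c(0, Inf), y1 = c(0, Inf)),
      domains = list(psi = c(-Inf, Inf), lambda = c(0, Inf)),
      ref = list(psi = 0.5, lambda = 1),
      test_points = lapply(
        list(c(0, 1), c(0.5, 1), c(1, 0.5), c(-0.5, 2), c(0.3, 1.5)),
        function(p) list(psi = p[1], lambda = p[2])),
      sampler = function(b, params, x = NULL) {
        x <- x %||% seq(-1, 1, length.out = b)
        y <- stats::rexp(b, rate = 1 / (params$lambda * exp(x * params$psi)))
        structure(cbind(y = y), x = x)
      },
      qfun = function(p, outcome, params) {
        x <- if (outcome == "yi") params$xi else params$x1
        stats::qexp(p, rate = 1 / (params$lambda * exp(x * params$psi)))
      },
      covariates = c(xi = 1, x1 = 0),
      cov = new_ft_cov(
        forward = list(yi = quote(yi / (lambda * exp(xi * psi))),
                       y1 = quote(y1 / (lambda * exp(x1 * psi)))),
        inverse = list(yi = quote(lambda * exp(xi * psi) * w),
                       y1 = quote(lambda * exp(x1 * psi) * v)),
        wsyms = list(yi = "w", y1 = "v"),
        base_density = quote(exp(-(w + v))),
        kappa = 1)
    )
  },

  loglogistic_reg = function() {
    new_ft_model(
      name = "loglogistic_reg",
      description = "Log-logistic accelerated life regression, scale lambda*exp(x_i*psi), shared shape beta",
      outcomes = c("yi", "y1"), arms = "y",
      arm_density = list(
        yi = quote((beta / (lambda * exp(xi * psi))) *
                     (yi / (lambda * exp(xi * psi)))^(beta - 1) /
                     (1 + (yi / (lambda * exp(xi * psi)))^beta)^2),
        y1 = quote((beta / (lambda * exp(x1 * psi))) *
                     (y1 / (lambda * exp(x1 * psi)))^(beta - 1) /
                     (1 + (y1 / (lambda * exp(x1 * psi)))^beta)^2)),
      interest = "psi", nuisances = "lambda", shared = "beta",
      support = list(yi = c(0, Inf), y1 = c(0, Inf)),
      domains = list(psi = c(-Inf, Inf), lambda = c(0, Inf), beta = c(0, Inf)),
      ref = list(psi = 0.5, lambda = 1, beta = 2),
      test_points = lapply(
        list(c(0, 1, 2), c(0.5, 1, 1.5), c(1, 0.5, 3), c(-0.5, 2, 2), c(0.3, 1.5, 0.8)),
        function(p) list(psi = p[1], lambda = p[2], beta = p[3])),
      sampler = function(b, params, x = NULL) {
        x <- x %||% seq(-1, 1, length.out = b)
        u <- stats::runif(b)
        sc <- params$lambda * exp(x * params$psi)
        structure(cbind(y = sc * (u / (1 - u))^(1 / params$beta)), x = x)
      },
      qfun = function(p, outcome, params) {
        x <- if (outcome == "yi") params$xi else params$x1
        sc <- params$lambda * exp(x * params$psi)
        sc * (p / (1 - p))^(1 / params$beta)
      },
      covariates = c(xi = 1, x1 = 0),
      cov = new_ft_cov(
        forward = list(yi = quote(yi / (lambda * exp(xi * psi))),
                       y1 = quote(y1 / (lambda * exp(x1 * psi)))),
        inverse = list(yi = quote(lambda * exp(xi * psi) * w),
                       y1 = quote(lambda * exp(x1 * psi) * v)),
        wsyms = list(yi = "w", y1 = "v"),
        base_density = quote((beta * w^(beta - 1) / (1 + w^beta)^2) *
                               (beta * v^(beta - 1) / (1 + v^beta)^2)),
        kappa = 1)
    )
  },

  exp_mean_shift_pair = function() {
    new_ft_model(
      name = "exp_mean_shift_pair",
      description = "Exponential pairs of means mu_i - psi and mu_i + psi (rates lambda/(1 -/+ lambda*psi)), |lambda*psi| < 1",
      outcomes = c("t", "c"), arms = c("T", "C"),
      arm_density = list(
        t = quote((lambda / (1 - lambda * psi)) * exp(-lambda * t / (1 - lambda * psi))),
        c = quote((lambda / (1 + lambda * psi)) * exp(-lambda * c / (1 + lambda * psi)))),
      interest = "psi", nuisances = "lambda",
      support = list(t = c(0, Inf), c = c(0, Inf)),
      domains = list(psi = c(-Inf, Inf), lambda = c(0, Inf)),
      ref = list(psi = 0.5, lambda = 0.4),
      test_points = lapply(
        list(c(0.5, 0.4), c(0.25, 1), c(0.5, 1.5), c(-0.3, 0.8), c(0.1, 2)),
        function(p) list(psi = p[1], lambda = p[2])),
      sampler = function(b, params, x = NULL) {
        cbind(T = stats::rexp(b, rate = params$lambda / (1 - params$lambda * params$psi)),
              C = stats::rexp(b, rate = params$lambda / (1 + params$lambda * params$psi)))
      },
      qfun = function(p, outcome, params) {
        rate <- if (outcome == "t") params$lambda / (1 - params$lambda * params$psi)
                else params$lambda / (1 + params$lambda * params$psi)
        stats::qexp(p, rate)
      },
      param_check = function(params) {
        if (any(abs(params$lambda * params$psi) >= 1))
          stop("exp_mean_shift_pair requires -1 < lambda*psi < 1", call. = FALSE)
        TRUE
      },
      cov = new_ft_cov(
        forward = list(t = quote(t * lambda / (1 - lambda * psi)),
                       c = quote(c * lambda / (1 + lambda * psi))),
        inverse = list(t = quote(w * (1 - lambda * psi) / lambda),
                       c = quote(v * (1 + lambda * psi) / lambda)),
        wsyms = list(t = "w", c = "v"),
        base_density = quote(exp(-(w + v))),
        kappa = 1)
    )
  }
)

#' Names of the built-in model catalog
#'
#' @return Character vector of identifiers accepted by [make_model()].
#' @export
catalog_names <- function() names(.catalog_builders)

#' Construct a catalog model
#'
#' Builds the full symbolic and sampling representation of one of the built-in
#' matched-comparison models.
#'
#' @param name One of [catalog_names()].
#' @param shared_params Named list overriding reference values of shared
#'   parameters (e.g. `list(beta = 1)` for `"loglogistic_reg"`). Values must
#'   lie in the parameter domains.
#' @return An object of class `ft_model`: symbolic joint density (in the
#'   outcome and parameter symbols), per-outcome support, parameter domains
#'   and reference values, a seeded sampler, quantile functions and, where
#'   available, the nuisance-transferring change of variables (`$cov`).
#' @examples
#' m <- make_model("exp_hazard_pair")
#' m$density
#' @export
make_model <- function(name, shared_params = list()) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.catalog_builders))
    stop("unknown model name: ", paste(name, collapse = ", "),
         "; see catalog_names()", call. = FALSE)
  model <- .catalog_builders[[name]]()
  for (p in names(shared_params)) {
    if (!p %in% names(model$domains))
      stop("unknown parameter '", p, "' for model ", name, call. = FALSE)
    dom <- model$domains[[p]]
    val <- shared_params[[p]]
    if (!is.numeric(val) || any(val <= dom[1] & dom[1] != -Inf) || any(val < dom[1]) ||
        any(val > dom[2]) || (dom[1] == 0 && any(val <= 0)))
      stop("parameter '", p, "' = ", val, " outside its domain (",
           dom[1], ", ", dom[2], ")", call. = FALSE)
    model$ref[[p]] <- val
  }
  model
}

# Resolve a full named parameter list for a model: interest values (by
# position), nuisance value(s), shared values defaulting to the reference.
resolve_params <- function(model, psi = NULL, nuisance = NULL, shared = list()) {
  params <- model$ref
  if (!is.null(psi)) {
    if (length(psi) != length(model$interest) && length(model$interest) > 1)
      stop("model has ", length(model$interest), " interest parameters", call. = FALSE)
    for (i in seq_along(model$interest)) params[[model$interest[i]]] <- psi[i]
  }
  if (!is.null(nuisance)) params[[model$nuisances[1]]] <- nuisance
  for (p in names(shared)) params[[p]] <- shared[[p]]
  for (p in names(model$domains)) {
    dom <- model$domains[[p]]
    v <- params[[p]]
    open_zero <- dom[1] == 0 && !p %in% model$closed
    if (any(v < dom[1] | v > dom[2]) || (open_zero && any(v <= 0)))
      stop("parameter '", p, "' outside its domain", call. = FALSE)
  }
  model$param_check(params)
  if (!is.null(model$covariates))
    for (p in names(model$covariates))
      if (is.null(params[[p]])) params[[p]] <- model$covariates[[p]]
  params
}

#' Numerically check that a model density is normalised
#'
#' Integrates (or, for discrete outcomes, sums) each per-outcome density
#' factor over its support at the given parameter values.
#'
#' @param model An `ft_model`.
#' @param params Named parameter list; defaults to the model's reference.
#' @return Named numeric vector of per-outcome total masses (all should be 1).
#' @export
check_normalisation <- function(model, params = model$ref) {
  params <- resolve_params(model, shared = params)
  out <- numeric(length(model$outcomes))
  names(out) <- model$outcomes
  for (o in model$outcomes) {
    dens_expr <- model$arm_density[[o]]
    f <- function(x) {
      vars <- params
      vars[[o]] <- x
      eval_expr(dens_expr, vars)
    }
    if (model$discrete) {
      out[o] <- sum(vapply(model$support[[o]][1]:model$support[[o]][2], f, 0))
    } else {
      s <- model$support[[o]]
      out[o] <- stats::integrate(f, s[1], s[2], rel.tol = 1e-9)$value
    }
  }
  out
}

# Interior outcome grid from the model's quantile functions, used by the
# numeric identity checks (probability range 0.01-0.99 under `params`).
outcome_grid <- function(model, params = model$ref, n = 10) {
  params <- resolve_params(model, shared = params)
  probs <- seq(0.05, 0.95, length.out = n)
  g <- lapply(model$outcomes, function(o) model$qfun(probs, o, params))
  names(g) <- model$outcomes
  g
}
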