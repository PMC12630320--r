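# Shared fixtures and independent oracles used across the test files.

# Closed-form per-arm CDFs, written against stats p-functions only, so that
# sampler/density agreement is checked against an independent route.
arm_cdf <- function(model_name, outcome, params) {
  switch(model_name,
    normal_pair = function(q) pnorm(q, params$mu, sqrt(params$sigma2)),
    logistic_pair = {
      pr <- if (outcome == "t") plogis(params$lambda + params$psi)
            else plogis(params$lambda)
      function(q) pbinom(q, 1, pr)
    },
    exp_hazard_pair = {
      rate <- if (outcome == "t") params$lambda * params$psi
              else params$lambda / params$psi
      function(q) pexp(q, rate)
    },
    exp_triplet = {
      rate <- switch(outcome, x1 = params$lambda * params$psi1,
                     x2 = params$lambda * params$psi2, x3 = params$lambda)
      function(q) pexp(q, rate)
    },
    weibull_pair = {
      sc <- if (outcome == "t") (params$lambda * params$psi)^(-1 / params$alpha)
            else (params$lambda / params$psi)^(-1 / params$alpha)
      function(q) pweibull(q, params$alpha, sc)
    },
    cauchy_pair = function(q) pcauchy(q, params$lambda, params$psi),
    exp_regression = {
      x <- if (outcome == "t") 1 else 0   # covariate fixed by the test
      function(q) pexp(q, rate = 1 / (params$lambda * exp(x * params$psi)))
    },
    loglogistic_reg = {
      x <- if (outcome == "t") 1 else 0
      sc <- params$lambda * exp(x * params$psi)
      function(q) 1 / (1 + (q / sc)^(-params$beta))
    },
    exp_mean_shift_pair = {
      rate <- if (outcome == "t") params$lambda / (1 - params$lambda * params$psi)
              else params$lambda / (1 + params$lambda * params$psi)
      function(q) pexp(q, rate)
    },
    stop("no oracle CDF for ", model_name))
}

# Scattered outcome grid for level-set comparisons.
scatter_grid <- function(outcomes, n = 40, seed = 99, lower = 0.1, upper = 4) {
  set.seed(seed)
  g <- lapply(outcomes, function(o) runif(n, lower, upper))
  names(g) <- outcomes
  g
}

# Brute-force profile likelihood for the binary logistic pair model:
# for each trial psi, profile each pair's lambda numerically, then maximise
# over psi. Independent of the closed form used by the package.
brute_profile_logistic <- function(tmat) {
  pair_loglik <- function(t, c, psi, lam)
    (lam + psi) * t - log(1 + exp(lam + psi)) + lam * c - log(1 + exp(lam))
  prof <- function(psi)
    sum(vapply(seq_len(nrow(tmat)), function(i)
      optimize(function(l) pair_loglik(tmat[i, 1], tmat[i, 2], psi, l),
               c(-30, 30), maximum = TRUE)$objective, 0))
  optimize(prof, c(-8, 8), maximum = TRUE, tol = 1e-8)$maximum
}
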