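# Laplace-transform criterion, independence verdicts, marginal density
# validation, and the closed-form ratio density of the mean-shift pairs.

test_that("the transform of the ratio statistic is invariant in the nuisance", {
  m <- make_model("exp_hazard_pair")
  vals <- vapply(c(0.5, 1, 2), function(lam)
    laplace_transform_value(m, quote(t / c), z = 1, psi = 1, lambda = lam), 0)
  expect_lt(max(vals) - min(vals), 1e-6)
  # oracle: the ratio has nuisance-free density psi^2/(1 + psi^2 s)^2, so the
  # transform is the 1-D integral of exp(-z s) against it
  oracle <- integrate(function(s) exp(-s) / (1 + s)^2, 0, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(vals[2], oracle, tolerance = 1e-7)
  # s == 0 integrates the density itself
  expect_equal(laplace_transform_value(m, 0, z = 1, psi = 1, lambda = 2), 1,
               tolerance = 1e-9)
  # the sum T + C is gamma-type with nuisance-dependent scale: values differ
  v_sum <- vapply(c(1, 2), function(lam)
    laplace_transform_value(m, quote(t + c), z = 1, psi = 1, lambda = lam), 0)
  # oracle at psi = 1: T + C ~ Gamma(2, rate lambda), transform (lambda/(lambda+z))^2
  expect_equal(v_sum, (c(1, 2) / (c(1, 2) + 1))^2, tolerance = 1e-7)
  expect_gt(abs(diff(v_sum)), 1e-3)
  expect_error(laplace_transform_value(m, quote(t / c), z = -1, psi = 1, lambda = 1),
               "positive")
})

test_that("the independence verdict is positive for factorisable statistics and negative otherwise", {
  m <- make_model("exp_hazard_pair")
  probe <- laplace_probe(z = c(0.5, 1, 2), lambda = c(0.5, 1, 2), psi = 1.3)
  good <- lambda_independence_check(m, quote(t / c), probe, n_mc = 20000, seed = 4)
  expect_true(good$independent)
  expect_lt(good$max_abs_dTdlambda, 1e-5)
  bad_sum <- lambda_independence_check(m, quote(t + c), probe, n_mc = 20000, seed = 4)
  expect_false(bad_sum$independent)
  bad_prod <- lambda_independence_check(m, quote(t * c), probe, n_mc = 20000, seed = 4)
  expect_false(bad_prod$independent)
})

test_that("factorisable statistics across the catalog pass the verdict", {
  # Weibull pairs w.r.t. the pair rate: ratio is free of lambda at any shape
  mw <- make_model("weibull_pair")
  chk <- lambda_independence_check(mw, quote(t / c),
                                   laplace_probe(z = c(0.5, 1), lambda = c(0.5, 1, 2)),
                                   n_mc = 20000, seed = 5)
  expect_true(chk$independent)
  # Cauchy pairs: the difference is free of the common location
  mc <- make_model("cauchy_pair")
  # transform of t - c diverges for z > 0 (heavy tails): KS route only
  chk2 <- lambda_independence_check(mc, quote(t - c),
                                    laplace_probe(lambda = c(-1, 0, 2)),
                                    n_mc = 20000, seed = 6)
  expect_false(chk2$transform_ok)
  expect_true(chk2$independent)
})

test_that("the mean-shift ratio depends on the parameters only through their product", {
  m <- make_model("exp_mean_shift_pair")
  probe <- laplace_probe(z = c(0.5, 1), lambda = c(0.3, 0.8, 1.5), psi = 0.5)
  res <- lambda_independence_check(m, quote(c / t), probe, n_mc = 20000, seed = 7)
  expect_false(res$independent)
  # equal products psi*lambda give equal distributions
  cmp <- transform_ks_compare(m, quote(c / t),
                              list(psi = 0.5, lambda = 0.8),
                              list(psi = 0.25, lambda = 1.6),
                              n_mc = 20000, seed = 8)
  expect_lt(cmp$D, cmp$critical)
  # unequal products are told apart
  cmp2 <- transform_ks_compare(m, quote(c / t),
                               list(psi = 0.5, lambda = 0.8),
                               list(psi = 0.5, lambda = 0.1),
                               n_mc = 20000, seed = 9)
  expect_gt(cmp2$D, cmp2$critical)
})

test_that("closed-form marginal densities pass the distributional check", {
  # hazard-ratio pairs: ratio density psi^2/(1 + psi^2 s)^2
  m <- make_model("exp_hazard_pair")
  res <- marginal_density_check(m, quote(t / c),
                                quote(psi^2 / (1 + psi^2 * s)^2),
                                psi = 1.4, lambda_grid = c(0.3, 1, 3),
                                n_mc = 8000, seed = 10)
  expect_true(res$pass)
  # Weibull pairs: ratio density alpha psi^2 s^(alpha-1) / (1 + psi^2 s^alpha)^2
  mw <- make_model("weibull_pair")
  res2 <- marginal_density_check(mw, quote(t / c),
                                 quote(alpha * psi^2 * s^(alpha - 1) /
                                         (1 + psi^2 * s^alpha)^2),
                                 psi = 1.2, lambda_grid = c(0.5, 1, 2),
                                 shared = list(alpha = 2),
                                 n_mc = 8000, seed = 11)
  expect_true(res2$pass)
  # mean-shift pairs: crude ratio c/t against the product-indexed density
  ms <- make_model("exp_mean_shift_pair")
  for (lam in c(0.4, 0.8)) {
    rho <- 0.5 * lam
    res3 <- marginal_density_check(
      ms, quote(c / t), function(sv) exp_shift_ratio_density(sv, rho),
      psi = 0.5, lambda_grid = lam, n_mc = 8000, seed = 12)
    expect_true(res3$pass, info = paste("lambda =", lam))
  }
  # an unnormalised candidate is refused
  expect_error(
    marginal_density_check(m, quote(t / c), function(sv) 2 / (1 + sv)^2,
                           psi = 1, lambda_grid = 1, n_mc = 100, seed = 1),
    "not normalised")
})

test_that("the mean-shift ratio density has the stated closed form", {
  # rho = 0 reduces to 1/(1+s)^2; at s = 1 the value is (1-rho^2)/4
  s <- c(0, 0.5, 1, 4)
  expect_equal(exp_shift_ratio_density(s, 0), 1 / (1 + s)^2)
  for (rho in c(-0.6, 0.2, 0.8))
    expect_equal(exp_shift_ratio_density(1, rho), (1 - rho^2) / 4)
  # normalisation to 1e-8 across the admissible range
  for (rho in c(-0.9, -0.4, 0, 0.4, 0.9)) {
    mass <- integrate(function(x) exp_shift_ratio_density(x, rho), 0, Inf,
                      rel.tol = 1e-12)$value
    expect_lt(abs(mass - 1), 1e-8)
    # CDF consistent with the density by quadrature
    expect_equal(exp_shift_ratio_cdf(1.7, rho),
                 integrate(function(x) exp_shift_ratio_density(x, rho),
                           0, 1.7, rel.tol = 1e-12)$value,
                 tolerance = 1e-9)
  }
  expect_error(exp_shift_ratio_density(1, 1.2), "rho")
  expect_error(exp_shift_ratio_density(-0.5, 0.3), "nonnegative")
})
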