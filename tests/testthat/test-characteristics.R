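# Method-of-characteristics solver: round trips, equivalence classes,
# inhomogeneous extension, leading-order simplification.

test_that("the solver recovers the known nuisance-free statistics", {
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("exp_hazard_pair")))$expr), "t/c")
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("cauchy_pair")))$expr), "t - c")
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("exp_regression")))$expr), "yi/y1")
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("loglogistic_reg")))$expr), "yi/y1")
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("normal_pair")))$expr), "y1 - y2")
  # Weibull pairs: eliminating the pair rate still gives the outcome ratio
  expect_equal(deparse1(solve_characteristics(
    characteristic_field(make_model("weibull_pair"), "lambda"))$expr), "t/c")
})

test_that("the mean-shift solution is the ratio-power statistic c/t^beta", {
  m <- make_model("exp_mean_shift_pair")
  tr <- solve_characteristics(characteristic_field(m))
  expect_false(tr$parameter_free)
  expect_equal(tr$family$kind, "power_ratio")
  # exponent equals (1 - lambda*psi)/(1 + lambda*psi) on a parameter grid
  for (ps in list(c(0.5, 0.4), c(0.25, 1), c(-0.3, 0.8))) {
    k <- factrans:::eval_expr(tr$family$exponent,
                              list(t = 1.3, c = 0.6, psi = ps[1], lambda = ps[2]))
    expect_equal(k, (1 - ps[2] * ps[1]) / (1 + ps[2] * ps[1]), tolerance = 1e-10)
  }
  # level sets match the reference statistic at the stored parameters
  f1 <- transformation_fun(tr)
  ref <- tr$params_ref
  beta <- (1 - ref$lambda * ref$psi) / (1 + ref$lambda * ref$psi)
  f2 <- function(t, c) c / t^beta
  expect_true(same_level_sets(f1, f2, scatter_grid(c("t", "c"))))
})

test_that("triplet blocks yield m-1 independent ratios and a bijective completion", {
  m <- make_model("exp_triplet")
  bl <- solve_characteristics_block(characteristic_field(m))
  expect_equal(vapply(bl$transforms, function(t) deparse1(t$expr), ""),
               c("x1/x3", "x2/x3"))
  expect_equal(deparse1(bl$completion), "x3")
  expect_true(bl$jacobian_ok)
  # a two-outcome block reduces to the pairwise solution plus completion
  b2 <- solve_characteristics_block(characteristic_field(make_model("exp_hazard_pair")))
  expect_equal(deparse1(b2$transforms[[1]]$expr), "t/c")
  expect_equal(deparse1(b2$completion), "c")
})

test_that("degenerate fields force the statistic onto the free outcome", {
  fld <- characteristic_field(make_model("exp_hazard_pair"))
  fld$coeffs$t <- 0   # a == 0: s must not depend on c
  expect_equal(deparse1(solve_characteristics(fld)$expr), "t")
  fld2 <- characteristic_field(make_model("exp_hazard_pair"))
  fld2$coeffs$c <- 0
  expect_equal(deparse1(solve_characteristics(fld2)$expr), "c")
  fld3 <- characteristic_field(make_model("exp_hazard_pair"))
  fld3$coeffs$t <- 0; fld3$coeffs$c <- 0
  expect_error(solve_characteristics(fld3), "vanish")
})

test_that("derived statistics annihilate their field and form an equivalence class", {
  cases <- c("exp_hazard_pair", "cauchy_pair", "exp_regression",
             "loglogistic_reg", "exp_mean_shift_pair", "weibull_pair")
  for (nm in cases) {
    fld <- characteristic_field(make_model(nm))
    tr <- solve_characteristics(fld)
    expect_lt(pde_residual(tr, fld), 1e-8)
    # any power of the statistic has identical level sets (for statistics
    # that change sign, only odd powers keep the map single-valued)
    f <- transformation_fun(tr)
    g <- scatter_grid(fld$outcomes, lower = 0.2, upper = 3)
    pows <- if (any(do.call(f, unname(g)) <= 0)) 3 else c(-1, 2, 0.5)
    for (k in pows) {
      fk <- function(u, v) f(u, v)^k
      expect_true(same_level_sets(f, fk, g), info = paste(nm, k))
    }
  }
  # the canonicaliser strips outer powers/constants and is idempotent
  tr <- solve_characteristics(characteristic_field(make_model("exp_hazard_pair")))
  tr2 <- tr; tr2$expr <- quote(3 * (t/c)^2)
  can <- canonicalise(tr2)
  expect_equal(deparse1(can$expr), "t/c")
  expect_equal(deparse1(canonicalise(can)$expr), "t/c")
})

test_that("the separable numeric fallback traces a valid first integral", {
  # Weibull shared-shape field: direction (c log c)/(t log t) is separable
  # but has no entry in the structural families; restrict the grid to t,c > 1
  # where the characteristic coefficients are single-signed
  fld <- characteristic_field(make_model("weibull_pair"), "alpha")
  fld$grid$outcomes <- list(t = seq(1.2, 3, length.out = 8),
                            c = seq(1.3, 3.2, length.out = 8))
  tr <- solve_characteristics(fld)
  expect_equal(tr$method, "numeric")
  expect_lt(pde_residual(tr, fld), 1e-4)
  # oracle: log(log c) - log(log t) is an exact first integral there
  f <- transformation_fun(tr)
  g <- scatter_grid(c("t", "c"), lower = 1.3, upper = 2.9)
  expect_true(same_level_sets(f, function(t, c) log(log(c)) - log(log(t)), g,
                              tol = 1e-8))
})

test_that("the inhomogeneous solution integrates h along characteristics", {
  m <- make_model("exp_hazard_pair")
  fld <- characteristic_field(m)
  hom <- solve_characteristics(fld)
  # zero perturbation reproduces the homogeneous solution exactly
  tr0 <- solve_inhomogeneous(fld, perturbation_spec(lambda0 = 1))
  expect_true(tr0$limit_ok)
  vars <- list(t = 1.7, c = 0.6, lambda = 1.4, psi = 1.2)
  expect_equal(factrans:::eval_expr(tr0$expr, vars),
               factrans:::eval_expr(hom$expr, vars), tolerance = 1e-14)
  # with h(lambda) = kappa + eps1*(lambda-l0) + eps2*(lambda-l0)^2, the total
  # derivative of s along a characteristic (w, v fixed) equals h(lambda)
  pert <- perturbation_spec(lambda0 = 1, kappa = 0.3, eps1 = 0.05, eps2 = 0.02)
  tr <- solve_inhomogeneous(fld, pert)
  psi <- 1.5; w <- 0.8; v <- 1.3
  s_along <- function(lam) {
    tt <- factrans:::eval_expr(m$cov$inverse$t, list(w = w, lambda = lam, psi = psi))
    cc <- factrans:::eval_expr(m$cov$inverse$c, list(v = v, lambda = lam, psi = psi))
    factrans:::eval_expr(tr$expr, list(t = tt, c = cc, lambda = lam, psi = psi))
  }
  for (lam in c(0.7, 1, 1.8)) {
    h_lam <- pert$kappa + pert$eps1 * (lam - 1) + pert$eps2 * (lam - 1)^2
    expect_equal(factrans:::num_deriv(s_along, lam, 1e-5), h_lam,
                 tolerance = 1e-6)
  }
})

test_that("leading-order simplification removes the parameter dependence", {
  m <- make_model("exp_mean_shift_pair")
  tr <- solve_characteristics(characteristic_field(m))
  ts <- taylor_simplify(tr, at = list(lambda = 0))
  expect_true(ts$parameter_free)
  expect_equal(deparse1(ts$expr), "c/t")
  expect_equal(deparse1(ts$plugin), "c/t^(t/c)")
  # already parameter-free input is returned unchanged
  trh <- solve_characteristics(characteristic_field(make_model("exp_hazard_pair")))
  expect_identical(taylor_simplify(trh), trh)
  # an expansion point that keeps the dependence is rejected
  expect_error(taylor_simplify(tr, at = list(psi = 0.3)), "parameter dependence")
})
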