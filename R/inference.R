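# Estimators and interval procedures for the matched-comparison models:
# marginal (partial-likelihood) and joint maximum likelihood for the
# constant hazard-ratio exponential pairs, the naive profiled analyses whose
# inconsistency motivates nuisance elimination, the conditional analysis of
# binary pairs, a moment estimator with variance pivot for the exponential
# mean-shift pairs, and a confidence-set scan for parameter-dependent
# transformations.

new_ft_fit <- function(estimate, std_error = NA_real_, interval = c(NA, NA),
                       method = "", converged = TRUE, n_blocks = NA,
                       diagnostics = list()) {
  structure(list(estimate = estimate, std_error = std_error,
                 interval = interval, method = method, converged = converged,
                 n_blocks = n_blocks, diagnostics = diagnostics),
            class = "ft_fit")
}

#' @export
print.ft_fit <- function(x, ...) {
  cat("<ft_fit> ", x$method, "\n", sep = "")
  est <- x$estimate
  cat("  estimate: ", paste(format(est, digits = 5), collapse = ", "),
      if (is.finite(x$std_error)) paste0("  (s.e. ", format(x$std_error, digits = 4), ")"),
      "\n", sep = "")
  if (all(is.finite(x$interval)))
    cat("  interval: [", format(x$interval[1], digits = 5), ", ",
        format(x$interval[2], digits = 5), "]\n", sep = "")
  if (!x$converged) cat("  NOT converged\n")
  invisible(x)
}

# Bracketed root of g on log-psi with automatic bracket expansion.
.root_logpsi <- function(g, lower = log(1e-4), upper = log(1e4)) {
  glo <- g(lower); ghi <- g(upper)
  tries <- 0
  while (sign(glo) == sign(ghi) && tries < 10) {
    lower <- lower - 2; upper <- upper + 2
    glo <- g(lower); ghi <- g(upper)
    tries <- tries + 1
  }
  if (sign(glo) == sign(ghi))
    stop("no sign change in bracket: degenerate data", call. = FALSE)
  stats::uniroot(g, c(lower, upper), tol = 1e-12)
}

#' Marginal maximum likelihood for the hazard-ratio pair model
#'
#' Fits the treatment parameter `psi` from the ratio statistics
#' `S_i = T_i / C_i`, whose marginal density `psi^2 / (1 + psi^2 s)^2` is
#' free of the pair nuisances. The score equation
#' `1 = (2/b) * sum(psi^2 S_i / (1 + psi^2 S_i))` is solved by bracketed
#' root finding on `log psi`; the standard error comes from the observed
#' information of the marginal log-likelihood (central finite differences,
#' step `1e-5 * psi_hat`).
#'
#' @param s Positive ratio statistics, or a paired sample / wide matrix from
#'   which `T/C` is computed.
#' @param level Confidence level for the Wald interval.
#' @return An `ft_fit` with `estimate`, `std_error`, `interval`; the
#'   marginal log-likelihood value is in `diagnostics$loglik`.
#' @examples
#' fit_marginal_ratio(c(0.25))$estimate  # psi_hat = 2 for a single pair
#' @export
fit_marginal_ratio <- function(s, level = 0.95) {
  if (is.data.frame(s) || is.matrix(s)) {
    m <- block_matrix(s)
    s <- m[, 1] / m[, 2]
  }
  if (any(s <= 0)) stop("ratio statistics must be positive", call. = FALSE)
  b <- length(s)
  score <- function(lp) {
    p2 <- exp(2 * lp)
    2 * mean(p2 * s / (1 + p2 * s)) - 1
  }
  r <- .root_logpsi(score)
  psi_hat <- exp(r$root)
  loglik <- function(psi) sum(2 * log(psi) - 2 * log(1 + psi^2 * s))
  h <- 1e-5 * psi_hat
  l2 <- (loglik(psi_hat + h) - 2 * loglik(psi_hat) + loglik(psi_hat - h)) / h^2
  se <- if (l2 < 0) sqrt(-1 / l2) else NA_real_
  zq <- stats::qnorm(1 - (1 - level) / 2)
  new_ft_fit(psi_hat, se, psi_hat + c(-1, 1) * zq * se,
             method = "marginal_mle_ratio", n_blocks = b,
             diagnostics = list(loglik = loglik(psi_hat),
                                score_at_opt = score(r$root), iter = r$iter))
}

#' Limiting value of the marginal score average
#'
#' Almost-sure limit of `(1/b) * sum(kappa^2 S_i / (1 + kappa^2 S_i))` when
#' the `S_i` are ratio statistics under true parameter `psi`:
#' `kappa^2 * ((kappa - psi)(kappa + psi) + 2 psi^2 (log psi - log kappa)) /
#' (kappa^2 - psi^2)^2`. The singularity at `kappa = psi` is removable with
#' limit 1/2, so that twice the function equals 1 exactly there; a series
#' expansion is used when `|kappa/psi - 1| < 1e-4` for numerical continuity.
#'
#' @param kappa Positive trial parameter value(s).
#' @param psi Positive true parameter value.
#' @return Limit value(s) in (0, 1).
#' @examples
#' marginal_limit(2, 1)           # (12 - 8*log(2))/9
#' 2 * marginal_limit(1.3, 1.3)   # exactly 1 at kappa = psi
#' @export
marginal_limit <- function(kappa, psi) {
  stopifnot(all(kappa > 0), psi > 0)
  x <- (kappa / psi)^2
  out <- numeric(length(x))
  near <- abs(kappa / psi - 1) < 1e-4
  u <- x[near] - 1
  out[near] <- x[near] * (1 / 2 - u / 3 + u^2 / 4 - u^3 / 5)
  xf <- x[!near]
  out[!near] <- xf * ((xf - 1) - log(xf)) / (xf - 1)^2
  out
}

#' Joint maximum likelihood for the hazard-ratio pair model
#'
#' Maximises the full likelihood in `psi` and all pair nuisances
#' `lambda_i`. After profiling, `psi_hat` is the root of
#' `sum((C_i/psi - T_i*psi) / (C_i/psi + T_i*psi)) = 0`, and the nuisance
#' estimates are the plug-ins `lambda_hat_i = 2 / (T_i psi_hat +
#' C_i / psi_hat)`. No analytic standard error is reported: the usual
#' information-based estimate is miscalibrated in this many-nuisance model,
#' so calibration has to come from simulation.
#'
#' @param pairs Paired sample (long data frame or wide matrix, arms T, C).
#' @return An `ft_fit`; `diagnostics$lambda_hat` holds the per-pair nuisance
#'   estimates.
#' @export
fit_joint_hazard_pair <- function(pairs) {
  m <- block_matrix(pairs)
  t_i <- m[, 1]; c_i <- m[, 2]
  if (any(t_i <= 0) || any(c_i <= 0))
    stop("outcomes must be positive", call. = FALSE)
  score <- function(lp) {
    psi <- exp(lp)
    sum((c_i / psi - t_i * psi) / (c_i / psi + t_i * psi))
  }
  r <- .root_logpsi(score)
  psi_hat <- exp(r$root)
  lambda_hat <- 2 / (t_i * psi_hat + c_i / psi_hat)
  new_ft_fit(psi_hat, NA_real_, c(NA, NA), method = "joint_mle_hazard_pair",
             n_blocks = length(t_i),
             diagnostics = list(lambda_hat = lambda_hat,
                                score_at_opt = score(r$root)))
}

#' Naive variance estimate for normal matched pairs
#'
#' The joint maximum likelihood estimator of the common variance with the
#' pair means profiled out: `sigma2_hat = sum((y_i1 - y_i2)^2) / (4b)`.
#' With one free mean per pair this converges to half the true variance --
#' the textbook incidental-parameters inconsistency.
#'
#' @param pairs Paired sample (long or wide, two arms).
#' @return Numeric variance estimate.
#' @examples
#' naive_variance_normal(rbind(c(0, 2), c(1, 1)))  # 0.5
#' @export
naive_variance_normal <- function(pairs) {
  m <- block_matrix(pairs)
  b <- nrow(m)
  if (b == 0) stop("no blocks", call. = FALSE)
  sum((m[, 1] - m[, 2])^2) / (4 * b)
}

# discordant-pair counts for binary matched pairs: n10 = (T=1, C=0)
.discordant_counts <- function(pairs) {
  m <- block_matrix(pairs)
  if (!all(m %in% c(0, 1))) stop("outcomes must be binary 0/1", call. = FALSE)
  list(n10 = sum(m[, 1] == 1 & m[, 2] == 0),
       n01 = sum(m[, 1] == 0 & m[, 2] == 1),
       b = nrow(m))
}

#' Profile (joint) maximum likelihood for binary matched pairs
#'
#' Maximises the full likelihood of the logistic pair model jointly in
#' `psi` and the per-pair log-odds. Concordant pairs push their nuisance
#' estimate to plus or minus infinity and contribute a `psi`-free constant;
#' each discordant pair profiles to `lambda_hat_i(psi) = -psi/2`, so the
#' profile estimator has the closed form `psi_hat = 2 * log(n10 / n01)` --
#' twice the conditional estimator, the classic inconsistency (the plim is
#' `2 psi`).
#'
#' @param pairs Binary paired sample.
#' @param level Confidence level.
#' @return An `ft_fit`; infinite estimates (a zero discordant count) are
#'   flagged via `converged = FALSE` with no interval.
#' @export
fit_profile_logistic <- function(pairs, level = 0.95) {
  cc <- .discordant_counts(pairs)
  if (cc$n10 == 0 || cc$n01 == 0) {
    est <- if (cc$n10 == 0 && cc$n01 == 0) NA_real_
           else if (cc$n10 == 0) -Inf else Inf
    return(new_ft_fit(est, NA_real_, c(NA, NA),
                      method = "profile_mle_logistic", converged = FALSE,
                      n_blocks = cc$b, diagnostics = cc))
  }
  psi_hat <- 2 * log(cc$n10 / cc$n01)
  se <- 2 * sqrt(1 / cc$n10 + 1 / cc$n01)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  new_ft_fit(psi_hat, se, psi_hat + c(-1, 1) * zq * se,
             method = "profile_mle_logistic", n_blocks = cc$b,
             diagnostics = cc)
}

#' Conditional maximum likelihood for binary matched pairs
#'
#' The conditional analysis given the pair totals: concordant pairs carry no
#' information, and among discordant pairs the treated success count is
#' binomial with success probability `e^psi / (1 + e^psi)`, giving
#' `psi_hat = log(n10 / n01)` with standard error
#' `sqrt(1/n10 + 1/n01)`. Consistent for `psi`, unlike the profile fit.
#'
#' @inheritParams fit_profile_logistic
#' @return An `ft_fit`.
#' @export
fit_conditional_logistic <- function(pairs, level = 0.95) {
  cc <- .discordant_counts(pairs)
  if (cc$n10 == 0 || cc$n01 == 0) {
    est <- if (cc$n10 == 0 && cc$n01 == 0) NA_real_
           else if (cc$n10 == 0) -Inf else Inf
    return(new_ft_fit(est, NA_real_, c(NA, NA),
                      method = "conditional_mle_logistic", converged = FALSE,
                      n_blocks = cc$b, diagnostics = cc))
  }
  psi_hat <- log(cc$n10 / cc$n01)
  se <- sqrt(1 / cc$n10 + 1 / cc$n01)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  new_ft_fit(psi_hat, se, psi_hat + c(-1, 1) * zq * se,
             method = "conditional_mle_logistic", n_blocks = cc$b,
             diagnostics = cc)
}

#' Moment estimator for the exponential mean-shift pair model
#'
#' Point estimator `psi_hat = sum(C_i - T_i) / (2b)`, whose expectation is
#' free of the pair nuisances, together with the consistent composite
#' variance estimate `sigma2_hat = sum(T_i C_i) / (2 b^2) + psi_hat^2 / b`
#' and the pivot `(psi_hat - psi0) / sigma_hat` for interval inversion.
#'
#' @param pairs Paired sample with positive outcomes (arms T, C).
#' @param level Confidence level.
#' @return An `ft_fit`; `diagnostics$sigma2_hat` is the variance estimate
#'   and `diagnostics$pivot` the callable pivot.
#' @export
fit_moment_shift <- function(pairs, level = 0.95) {
  m <- block_matrix(pairs)
  b <- nrow(m)
  if (b == 0) stop("no blocks", call. = FALSE)
  t_i <- m[, 1]; c_i <- m[, 2]
  psi_hat <- sum(c_i - t_i) / (2 * b)
  sigma2_hat <- sum(t_i * c_i) / (2 * b^2) + psi_hat^2 / b
  se <- sqrt(sigma2_hat)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  pivot <- function(psi0) (psi_hat - psi0) / se
  new_ft_fit(psi_hat, se, psi_hat + c(-1, 1) * zq * se,
             method = "moment_shift", n_blocks = b,
             diagnostics = list(sigma2_hat = sigma2_hat, pivot = pivot))
}

#' Confidence set by scanning a parameter-dependent transformation
#'
#' For each trial value `psi0` on a grid, computes the statistics
#' `s(t, c; psi0)`, standardises them by the probability integral transform
#' under their theoretical null distribution at `psi0`, and retains `psi0`
#' when a one-sample Kolmogorov-Smirnov test does not reject at the stated
#' level. The retained grid values form a confidence set. A pathology flag
#' is raised when the set is unbounded on the grid (both endpoints
#' retained), the signature of a statistic that carries information about a
#' parameter combination rather than `psi` alone.
#'
#' @param pairs Paired sample.
#' @param s_fun `function(t, c, psi0)` computing the statistic.
#' @param null_cdf `function(q, psi0)` (optionally with a third argument
#'   receiving the wide data matrix, for plug-in composites): theoretical
#'   CDF of the statistic when `psi0` is the truth.
#' @param psi_grid Trial values.
#' @param level Confidence level (KS test at `1 - level`).
#' @return List of class `ft_confset`: `set` (retained values),
#'   `pathological`, `degenerate`, and the per-point KS table.
#' @export
confidence_set_scan <- function(pairs, s_fun, null_cdf, psi_grid,
                                level = 0.95) {
  if (!length(psi_grid)) stop("empty grid", call. = FALSE)
  m <- block_matrix(pairs)
  if (nrow(m) == 0)
    return(structure(list(set = psi_grid, pathological = TRUE,
                          degenerate = TRUE, table = NULL),
                     class = "ft_confset"))
  alpha <- 1 - level
  use_data_arg <- length(formals(null_cdf)) >= 3
  pvals <- vapply(psi_grid, function(p0) {
    sv <- s_fun(m[, 1], m[, 2], p0)
    u <- if (use_data_arg) null_cdf(sv, p0, m) else null_cdf(sv, p0)
    suppressWarnings(stats::ks.test(u, "punif")$p.value)
  }, 0)
  keep <- pvals >= alpha
  set <- psi_grid[keep]
  pathological <- length(set) > 0 && keep[1] && keep[length(keep)]
  structure(list(set = set, pathological = pathological, degenerate = FALSE,
                 table = data.frame(psi0 = psi_grid, p_value = pvals,
                                    retained = keep)),
            class = "ft_confset")
}

#' @export
print.ft_confset <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<ft_confset> degenerate (no data): full grid returned\n")
    return(invisible(x))
  }
  cat("<ft_confset> ", length(x$set), " of ", nrow(x$table),
      " grid values retained", sep = "")
  if (length(x$set))
    cat("; range [", format(min(x$set)), ", ", format(max(x$set)), "]", sep = "")
  cat("\n")
  if (x$pathological)
    cat("  warning: set unbounded on the grid (statistic may be",
        "approximately ancillary for the interest parameter)\n")
  invisible(x)
}
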