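---
title: "Deriving factorisable transformations for matched comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving factorisable transformations for matched comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factrans)
```

## The inferential problem

A matched comparison in blocks of size $m$ observes, for $m = 2$, pairs
$(T_i, C_i)$, $i = 1, \dots, b$, independent across blocks, with a common
interest parameter $\psi$ and one nuisance parameter $\lambda_i$ per block.
The nuisances are treated as *fixed arbitrary constants*, not draws from a
distribution: a per-block free parameter is precisely what spares the
analyst from modelling block heterogeneity, and any distributional
assumption about it reintroduces a misspecification risk. The cost is the
incidental-parameters problem: with $O(b)$ parameters and $O(b)$
observations, profile maximum likelihood need not be consistent. The
package's `run_inconsistency_study()` exhibits the two canonical failures
(normal pairs, where $\hat\sigma^2 \to \sigma^2/2$; binary logistic pairs,
where the profiled log-odds estimate converges to twice the truth), and its
acceptance checks verify both limits by simulation.

The remedy implemented here is marginal-likelihood factorisation: find
$S_i = s(T_i, C_i)$ whose density depends on $\psi$ but on no $\lambda_i$,
and use $\prod_i f_S(s_i;\psi)$ as a partial likelihood. The package
provides the *constructive* route to $s$, its verification, and the
estimators that motivate and use it.

## The construction

**Factorisation condition.** The joint density must be expressible as
$\kappa\, w'(t)\, v'(c)\, g\{w(t;\psi,\lambda), v(c;\psi,\lambda);\psi\}$
with $\kappa > 0$ constant, $w, v$ bijective in their outcome, and $g$ free
of $\lambda$. `check_factorisation_form()` builds the right-hand side
symbolically (exact derivative of the forward maps, substitution of the
transformed coordinates into the base density) and certifies the identity
on a grid: the default is a $5 \times 5$ outcome grid at the support
quantiles 0.05–0.95 under five parameter settings per model, with a
relative tolerance of $10^{-8}$. Monotonicity of the maps is checked by
sign-constancy of their derivatives on the same grid. A base density that
retains the nuisance symbol fails immediately with a diagnostic.

**Characteristic field.** Under the condition above, requiring the Laplace
transform $T_\lambda(s, z) = E[e^{-z s(T,C)}]$ to be constant in $\lambda$,
identically in $z$ and $\psi$, reduces to the first-order homogeneous PDE
$a\, \partial s/\partial t + b\, \partial s/\partial c = 0$ with
$a = \partial t(w;\psi,\lambda)/\partial\lambda$ (forward map
back-substituted), likewise $b$. `characteristic_field()` computes $a, b$
by exact symbolic differentiation of the inverse maps; no simplification of
the resulting expressions is attempted, since all downstream decisions are
made by evaluation.

**Solving by characteristics.** Solutions are first integrals of
$dc/dt = b/a$. `solve_characteristics()` classifies the direction field by
structured numeric probes on the outcome-parameter grid, in this order:

1. *degenerate* ($a \equiv 0$ or $b \equiv 0$): the statistic is the free
   outcome itself;
2. *ratio-power*: $b/a = k\,c/t$ with $k$ constant in the outcomes. For
   $k = 1$ the canonical representative is $t/c$; otherwise $c/t^k$, with
   $k$ kept as an exact expression when it depends on the parameters (the
   exponential mean-shift pairs give
   $k = (1-\lambda\psi)/(1+\lambda\psi)$);
3. *constant direction*: $b/a = k$ free of the outcomes, representative
   $t - c/k$;
4. *separable fallback*: if $b/a = R_1(t) R_2(c)$ (tested by a cross-ratio
   identity), the first integral $\int dv/R_2 - \int R_1\,du$ is computed
   by adaptive quadrature from the grid midpoint and returned as a numeric
   transformation, flagged `method = "numeric"`.

Classification tolerances are $10^{-6}$ relative (structural tests) and
$10^{-8}$ for the verification that a derived statistic annihilates its
field (`pde_residual()`, exact symbolic partials evaluated on the grid and
scaled by the term magnitudes). Solutions form equivalence classes
$\{s^k : k \neq 0\}$; the canonical representative takes $k = 1$ and strips
outer numeric powers and constants (`canonicalise()`, idempotent). The
completion statistic defaults to the last outcome symbol, and bijectivity
of the completed map is confirmed by a non-vanishing Jacobian on the grid —
any completion with that property is equally valid.

**Blocks and multiple nuisances.** For product densities over $m > 2$
outcomes the pairwise equations against the last outcome give $m-1$
functionally independent integrals (`solve_characteristics_block()`). For
two simultaneous nuisances over the same pair, a common non-constant
solution exists iff the two characteristic directions coincide everywhere;
`joint_solvability()` implements this as the identical vanishing of
$a_1 b_2 - a_2 b_1$ (relative tolerance $10^{-8}$ on the grid). This
determinant criterion is exact for two outcomes; it is the package's
formalisation of an impossibility that is otherwise argued informally, and
when elimination of both is impossible the per-block nuisance is
recommended for elimination, since each block contributes a fresh copy of
it while a shared shape parameter is estimated from all $n = mb$
observations.

**Approximate factorisation.** When exact factorisation fails, the
right-hand side of the defining equation is relaxed from $0$ to a slowly
varying $h(\lambda)$, operationalised as its quadratic expansion
$\kappa + \varepsilon_1(\lambda-\lambda_0) +
\varepsilon_2(\lambda-\lambda_0)^2$ around a base point.
`solve_inhomogeneous()` returns the homogeneous integral plus the explicit
particular term $\kappa(\lambda-\lambda_0) +
\varepsilon_1(\lambda-\lambda_0)^2/2 +
\varepsilon_2(\lambda-\lambda_0)^3/3$; its defining property — the total
derivative along a characteristic parameterised by $\lambda$ equals
$h(\lambda)$ — is what the tests verify, holding the transformed
coordinates fixed through the inverse maps. The
$\varepsilon \to 0$, $\kappa = 0$ limit is the homogeneous solution by
construction and is checked numerically. For parameter-dependent solutions,
`taylor_simplify()` substitutes an expansion point into the exponent; the
limit is taken along a shrinking step with one Richardson extrapolation
when the unsimplified expression is $0/0$ at the point exactly, and the
result is accepted only if it is invariant (to $10^{-6}$) to the values of
the remaining symbols. For ratio-power families the crude data-based
plug-in (exponent estimated by the inverse outcome ratio) is returned
alongside.

## Verification machinery

No transform inversion is performed anywhere: the Laplace transform enters
only as a criterion. `laplace_transform_value()` computes
$E[e^{-zs}]$ by nested adaptive quadrature (relative tolerance $10^{-10}$)
over the exact support; `lambda_independence_check()` combines

* the supremum of the central finite-difference derivative
  $\partial T_\lambda/\partial\lambda$ (step $10^{-4}\lambda$, tolerance
  $10^{-5}$) over a $z \times \lambda \times \psi$ probe grid, and
* all pairwise two-sample Kolmogorov–Smirnov statistics between simulated
  statistic values across the $\lambda$ grid, at the asymptotic 1% critical
  value with the default $n_{\mathrm{mc}} = 20000$.

When the transform diverges (statistics unbounded below under heavy tails,
e.g. the Cauchy pair difference at $z > 0$), the verdict rests on the KS
table alone — this is also why KS backs the transform criterion in general:
the ratio statistics here have no moments, so a moment-matching check would
be vacuous. `marginal_density_check()` validates closed-form marginal
densities (normalisation by quadrature, then one-sample KS against the
candidate CDF obtained by incremental quadrature, per nuisance value).

## The synthetic-data generators

Every catalog model carries a seeded sampler; `sample_blocks()` treats the
nuisances as a fixed per-block vector (a generating rule, when given, is
applied once and the realised values recorded in the metadata — sampling
convenience, not a modelling assumption). Since no asymptotic statement
here fixes a nuisance distribution, the simulation studies use fixed
deterministic sequences — equally spaced quantiles of a standard normal
(log-odds scales) or of a log-normal with $\sigma = 0.5$ (positive rates) —
and record the rule in their output. The generators emulate exactly the
independence and distributional assumptions of the models: what they do
*not* emulate is any failure of those assumptions (non-constant treatment
effects across blocks, dependence within pairs, contaminated tails,
censoring), so passing tests certify the construction and the estimators
under the stated models, not robustness to their violation.

Study sizes are chosen for Monte-Carlo precision at desk scale: the
inconsistency studies use $b = 10^5$ (normal) and $b = 5\times10^4$
(logistic) with 20 replicates, so that three Monte-Carlo standard errors
are well below the distance between the true parameter and the defective
probability limit; interval calibration uses 500 replicates at $b = 400$;
the consistency sweep uses 200 replicates at $b \in \{10^2, 10^3, 10^4\}$;
the moment-estimator variance identity uses 2000 replicates at $b = 300$
with pair means fixed on $[2, 4]$.

## Estimators and their numerics

All positive scalar likelihood equations are solved on $\log\psi$ with
automatic bracket expansion (uniroot, tolerance $10^{-12}$); degenerate
data with no sign change raise an error rather than returning a boundary
value. Observed information for the marginal fit is computed by central
finite differences with step $10^{-5}\hat\psi$, so the same code serves
densities available only numerically. The limiting marginal score average
has a removable singularity at $\kappa = \psi$; the implementation switches
to a four-term series for $|\kappa/\psi - 1| < 10^{-4}$, making
`marginal_limit()` continuous through the singularity with value exactly
$1/2$ there.

Two facts the implementation surfaces explicitly:

* the marginal score equation for the hazard-ratio pairs is *algebraically
  identical* to the joint profile score (multiply each term by
  $C_i/\psi$), so the two point estimates coincide at every $b$; the routes
  differ in the variance assessment, and only the marginal fit carries an
  analytic standard error — the joint fit's usual information-based
  variance is miscalibrated in this many-nuisance setting and is therefore
  not reported;
* in the binary pair model, concordant pairs are dropped from the profile
  objective after verifying (by brute-force two-dimensional maximisation in
  the tests) that their profiled contribution is free of $\psi$ — their
  nuisance estimates diverge, and keeping them in a numeric optimiser is
  ill-posed. The profile estimator then has the closed form
  $2\log(n_{10}/n_{01})$ and the conditional estimator
  $\log(n_{10}/n_{01})$; a zero discordant count flags an infinite
  estimate with no interval.

The confidence-set scan standardises $s(t, c; \psi_0)$ by the probability
integral transform under its null distribution — the natural
parameter-free standardisation when no moments exist — and retains grid
values not rejected by a one-sample KS test at level $1-$`level`. A set
whose retained values include both grid endpoints is flagged pathological:
that is the signature of a statistic that is approximately ancillary for
the interest parameter, as with the mean-shift ratio $C/T$, whose
distribution is indexed by the product $\psi\lambda$ alone, so a plug-in
composite fitted under each null makes every trial value acceptable.

## Auxiliary constructions

The Gram–Schmidt pair orthogonalises $e^{-\lambda c/\psi}$ against
$e^{-\lambda\kappa c/\psi}$ on $(0, \infty)$; the closed-form inner
products and the orthogonality integral are verified by quadrature at
absolute accuracy $10^{-12}$ (the target of the orthogonality integral is
zero, so relative error control is meaningless there and deliberately not
enforced). Whether the printed $\phi_1^{(\kappa)}$ is unit-normalised is
not asserted anywhere — only orthogonality is, and only orthogonality is
tested. Using this family to *solve* the resulting integral equation for
$s$ is out of scope: the construction and its characterising identities
are provided as verified building blocks. The same holds for the Stein
operator of the exponential distribution,
$(\mathcal A f)(x) = (1-\rho x)f'(x) + x f''(x)$: `stein_expectation()`
evaluates $E[(\mathcal A f)(X)]$ with exact symbolic derivatives when the
test function is an expression, and demonstrates both the annihilation
under $\mathrm{Exp}(\rho)$ and the power of the characterisation under a
wrong law. The quantile-flow identity
$\partial y/\partial\theta = -(\partial F/\partial\theta)/f$ is a small
utility connecting sample and parameter spaces; its CDF derivative is
central-difference with step $10^{-6}\max(1,|\theta|)$ unless supplied.

## Known limitations

* The symbolic layer rests on R expression objects and exact
  differentiation; identities are certified by evaluation on grids rather
  than by algebraic simplification. A field whose structure changes
  between grid cells could in principle be misclassified; the tolerances
  above and the independent PDE-residual check guard against this for the
  families in scope.
* The joint-solvability criterion is specific to two outcomes; general
  integrability of overdetermined systems in more variables is out of
  scope.
* The separable numeric fallback requires single-signed characteristic
  coefficients on the working grid (quadrature through an interior zero of
  the direction field is not attempted).
* User-supplied models beyond the catalog are accepted by the numeric
  verification machinery but only best-effort by the symbolic modules.
* Censoring, Bayesian treatments and higher-order likelihood corrections
  are not implemented.
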