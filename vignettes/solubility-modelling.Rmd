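---
title: "Modelling drug solubility in supercritical CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug solubility in supercritical CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsolub)
```

## The problem

Supercritical CO₂ (critical point 304.13 K, 73.77 bar) is a widely used
green solvent for micronizing poorly water-soluble drugs. Process design
needs the equilibrium mole-fraction solubility $y(T, P)$ of the solute
over the operating window. Measurements are expensive, so the usual
practice is to measure a modest grid and interpolate with a model.
`scsolub` implements two complementary model families over the same
dataset abstraction: nonparametric regressors (GPR, KRR, a regression
tree) that treat $y(T, P)$ as a black-box surface, and density-based
semi-empirical correlations that encode the known physics — solubility
rises with solvent density and with solute vapor pressure.

The bundled dataset (`decitabine_dataset()`) holds 32 solubility
measurements of decitabine in SC-CO₂ on the full factorial grid of eight
pressures (120–400 bar) and four temperatures (308–338 K), spanning
$2.8\times10^{-5}$ to $1.07\times10^{-3}$ mole fraction. All conditions
are supercritical.

## Gaussian process regression

The GP places a zero-mean Gaussian prior over surfaces with the
squared-exponential covariance

$$k(x, x') = \sigma_f^2 \exp\!\Big(-\tfrac{1}{2}\sum_d
  \frac{(x_d - x'_d)^2}{l_d^2}\Big),$$

where $\sigma_f^2$ is the signal variance (the maximum attainable
covariance, and the prior variance of the surface at any point) and the
length scales $l_d$ set how fast correlation decays along each input.
Conditioning the joint Gaussian of training outputs $y$ and a test output
$y_*$ gives the posterior mean $K_* K^{-1} y$ and variance
$K_{**} - K_* K^{-1} K_*^T$; the variance is the model's own uncertainty
statement and collapses to zero at the data when the observation noise
$\sigma_n^2$ is zero.

Choices that matter, and why:

- **Input standardization.** Pressure (hundreds of bar) and temperature
  (hundreds of K, but spanning only 30 K) live on incommensurate scales,
  so inputs are standardized to zero mean and unit variance per dimension
  before kernel evaluation. Targets are left in raw mole fraction with a
  zero prior mean; the fitted $\sigma_f^2$ absorbs their scale.
- **Anisotropic length scales** (one per input) are the default, since
  there is no reason pressure and temperature should share a smoothness;
  an isotropic mode is available.
- **Noise variance defaults to zero**, making the GP an exact
  interpolator of the training data. This is appropriate for a smooth,
  low-noise equilibrium dataset and is exposed as a setting for noisier
  data.
- **Hyperparameters by ML-II.** The log marginal likelihood is maximized
  in log-hyperparameter space by Nelder-Mead from 8 seeded starts (one
  data-driven: $\sigma_f^2 = \mathrm{var}(y)$, unit length scales; the
  rest uniform perturbations of it). An exhaustive log-grid strategy
  (12 × 10 × 10 candidates by default) is also provided; both are
  deterministic given the seed.
- **Jitter policy.** The Gram matrix of a noise-free SE kernel can be
  numerically semidefinite; if the Cholesky factorization fails, a
  diagonal jitter of $10^{-10}\sigma_f^2$ is added, escalating tenfold up
  to $10^{-6}\sigma_f^2$ before giving up. Predictive variances are
  clipped at zero.

KRR shares the kernel machinery; its dual solution
$\alpha = (K + N\lambda I)^{-1} y$ makes the algebraic identity with the
GP posterior mean (take $N\lambda = \sigma_n^2$) a strong internal
cross-check, which the test suite exercises on random small datasets.

## Regression tree

The tree grows greedily: at each node every candidate split — each
feature crossed with every midpoint between consecutive sorted unique
values — is scored by the child-size-weighted impurity
$p_L\,s(t_L) + p_R\,s(t_R)$, with $s(t)$ the population standard
deviation of the node's targets, and the minimizer is taken. Scoring with
standard deviations (impurity in the units of $y$) is the default;
a `"variance"` criterion gives the classical CART mean-squared-error
reduction. Both orderings usually agree but need not; shipping both makes
the choice explicit. Ties are broken deterministically (pressure before
temperature, then the smaller threshold), and routing sends
`value <= threshold` left. Leaves predict their training mean, so
predictions are always within the training target range.

## CO₂ density and the semi-empirical correlations

The correlations need the solvent density. The Peng–Robinson cubic
equation of state provides it analytically from the CO₂ constants
($T_c = 304.13$ K, $P_c = 73.77$ bar, $\omega = 0.224$, $M = 44.01$
g/mol), using the standard 1976 $\kappa(\omega)$ and $\alpha(T)$
functions. Internally everything is SI with a bar↔Pa conversion at the
boundary. In the supercritical region the cubic has a single physical
root; below $T_c$ the stable root is chosen by comparing fugacity
coefficients (lower Gibbs energy). Every returned density is
re-substituted into $P(T, \rho)$ and must reproduce the input pressure to
$10^{-8}$ relative — a self-check that has no false positives because the
cubic is solved and verified through different expressions. A
`user_table` provider returns exactly the densities supplied to it, so
reference-quality values (e.g. from a multiparameter EoS) can be injected
without touching the fitting code; the PR EoS is accurate to a few
percent here, and since the correlation parameters are refit they absorb
any systematic density bias.

Two correlation forms ship built in:

- Kumar–Johnston: $\ln y = a_0 + a_1/T + a_2 \rho$ ($\rho$ in kg/m³);
- Bartle: $\ln(y P / P_\mathrm{ref}) = a_0 + a_1/T +
  a_2(\rho - \rho_\mathrm{ref})$ with the universal literature
  conventions $P_\mathrm{ref} = 1$ bar, $\rho_\mathrm{ref} = 700$ kg/m³.

Further forms (five- and six-parameter correlations exist in the
literature) are deliberately not hard-coded from memory: the registry
(`register_correlation_form()`) accepts any evaluator, and only equations
taken verbatim from their sources should be registered.

Fitting minimizes AARD% $= (100/n)\sum_i |y_{calc,i} - y_{exp,i}| /
y_{exp,i}$, the field's standard ranking criterion, by Nelder-Mead from
16 seeded starts around a coarse log-linear initialization (an `lm()` fit
in the form's own log space — for these two forms the model is exactly
linear in its parameters after taking logs, so the initialization is
already near-optimal and the multi-start is insurance against the
non-smooth AARD objective). A log-space least-squares objective is
offered as a better-conditioned alternative. The reported fit is never
worse than the initialization, and the best of all starts is kept.

## Metrics

The headline $R^2$ is the *squared Pearson correlation* between observed
and estimated values — invariant under affine transformation of either
argument and confined to $[0, 1]$. This is implemented exactly as such,
and deliberately kept distinct from the coefficient of determination
$1 - SS_{res}/SS_{tot}$, which penalizes bias and scale errors and is
available separately (`coefficient_of_determination()`) for diagnostics.
MAPE is reported as a dimensionless fraction and AARD% as $100\times$
MAPE. Headline evaluations are computed on full-data fits: the
interpolating GP makes train/test bookkeeping moot for it, and full-data
metrics are reproducible without committing to any particular random
split. Holdout and k-fold splits are available through `grid_search()`
and `split_dataset()` when generalization estimates are wanted.

## Optimum and crossover analysis

`find_optimum()` scans a grid over the (P, T) domain and refines the best
cell by bounded local ascent. The search domain defaults to the data's
bounding box: an interpolating model has no warrant outside its data
hull, and on the bundled data the optimum sits on the boundary corner
(400 bar, 338 K) anyway. `crossover_pressure()` locates where two
solubility isotherms intersect — below the crossover pressure heating
lowers solubility because the density loss dominates; above it heating
raises solubility because the vapor-pressure gain dominates. For a fitted
model the sign change of $y(T_2, P) - y(T_1, P)$ is bracketed by scanning
and polished by bisection; for a raw dataset only the bracketing pair of
measured pressures is reported, with no interpolation beyond the data.
On the bundled isotherms at 308 vs 338 K the crossover lies between 160
and 200 bar.

## Synthetic data and what it does (not) show

`synthetic_config()` + `generate_solubility()` produce datasets with
known truth: a correlation-form surface (default: Kumar–Johnston with
parameters 7.32, −7108.7, 0.00769 on the bundled 8 × 4 grid, which spans
the same $10^{-5}$–$10^{-3}$ mole-fraction range as the real data) or a
random smooth log-solubility surface drawn from a seeded GP prior, for
stress-testing the tree and KRR beyond correlation-shaped truths. Noise
is multiplicative lognormal, $y_i = y_{true,i}\,e^{\varepsilon_i}$ with
$\varepsilon_i \sim N(0, \sigma^2)$, the natural error model for strictly
positive quantities spanning orders of magnitude; the default
$\sigma = 0.10$ corresponds to a typical ~8% mean absolute relative
scatter ($E|e^\varepsilon - 1| \approx 0.08$ at $\sigma = 0.1$).
`recovery_study()` repeats generate-and-refit over fresh seeds and
summarizes per-parameter bias and RMSE and the fitted-AARD distribution;
at the default settings (50 replicates, 32 points, $\sigma = 0.10$) the
Kumar–Johnston parameters are recovered with well under 5% relative bias
and the mean fitted AARD sits near 8%.

What the generator does *not* emulate: heteroscedastic experimental
error, correlated errors within an isotherm, density uncertainty, or
solute-phase transitions. Passing recovery tests therefore demonstrates
the correctness and calibration of the estimators under a clean noise
model, not robustness to every pathology of real solubility
measurements.

## Problem sizes and numerical settings

All analyses in the tests and the acceptance script run on the 32-point
bundled grid or synthetic datasets of the same size — these are desk-scale
problems, and the dense Cholesky-based GP ($O(n^3)$, $n = 32$) is exact
and instantaneous at this scale. Default optimizer settings: Nelder-Mead,
relative tolerance $10^{-12}$, at most 5000 iterations per pass, two
passes per start for correlation fits; the property and recovery suites
use 50 random replicates. Known limitations: no sparse/approximate GP for
large $n$; no multiparameter reference EoS (the provider contract is the
extension point); correlation forms beyond Kumar–Johnston and Bartle must
be registered by the user with their exact published equations.
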