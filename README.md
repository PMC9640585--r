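# scsolub

Modelling of drug solubility in supercritical carbon dioxide (SC-CO₂) as a
function of pressure and temperature. SC-CO₂ is a green pharmaceutical
solvent used to micronize poorly water-soluble drugs, and the first design
question for any such process is how the equilibrium mole-fraction
solubility *y* of the solute varies over the operating window in pressure
*P* and temperature *T*. `scsolub` answers it two ways on the same data:

- **Nonparametric regressors**, written from scratch:
  - *Gaussian process regression* (GPR) with the squared-exponential
    kernel `k(x, x') = σ_f² exp(−‖x − x'‖²/(2l²))`, zero prior mean, ML-II
    (maximum marginal likelihood) hyperparameters, exact posterior mean
    `K_* K⁻¹ y` and predictive variance `K_** − K_* K⁻¹ K_*ᵀ`;
  - *kernel ridge regression* (KRR) via the regularized dual solution
    `α = (K + NλI)⁻¹ y`;
  - a *CART-style regression tree* whose splits minimize the
    child-size-weighted impurity `p_L·s(t_L) + p_R·s(t_R)`.
- **Density-based semi-empirical correlations** — Kumar–Johnston
  (`ln y = a₀ + a₁/T + a₂ρ`) and Bartle
  (`ln(yP/P_ref) = a₀ + a₁/T + a₂(ρ − ρ_ref)`) — fitted by AARD%
  minimization, with CO₂ density ρ(T, P) supplied by a built-in
  Peng–Robinson equation of state (or any user table of reference
  densities).

Evaluation utilities provide the standard metrics (squared-correlation R²,
MAE, MAPE, AARD%), exhaustive grid-search tuning, response surfaces,
optimum location and crossover-pressure analysis, plus a synthetic-data
generator with known ground truth for parameter-recovery studies.

The package ships a 32-point dataset of decitabine solubility in SC-CO₂ on
a full factorial grid (120–400 bar × 308–338 K).

## Worked example

```r
library(scsolub)

ds <- decitabine_dataset()
ds
#> <solubility_dataset> 'decitabine / SC-CO2': 32 records
#>   P: 120-400 bar, T: 308-338 K, y: 2.84e-05-0.00107

fit <- gpr_fit(ds, seed = 1)        # zero-noise GP, ML-II hyperparameters
evaluate_model(fit, ds)
#> <metrics_report> n = 32
#>   R2 = 1.0000  MAE = 2.873e-18  MAPE = 2.332e-14  AARD = 0.00%

predict(fit, data.frame(pressure_bar = 400, temperature_K = 338))
#>      mean variance
#> 1 0.00107        0

find_optimum(fit)
#> <optimum_result> P = 400.0 bar, T = 338.0 K, y = 0.00107

crossover_pressure(ds, 308, 338)
#> <crossover_result> T = 308 vs 338 K: crossover between 160 and 200 bar

kj <- fit_correlation(ds, "kumar_johnston", seed = 1)
bt <- fit_correlation(ds, "bartle", seed = 1)
correlation_report(list(kj, bt))
#>             form        a0        a1          a2 a3 a4 a5 aard_percent        r2
#> 1         bartle 23.526121 -8901.762 0.009770582 NA NA NA     7.982522 0.9863647
#> 2 kumar_johnston  7.769948 -6945.346 0.006531849 NA NA NA     8.779301 0.9871460
```

The zero-noise GP interpolates the 32 training points, so the training R²
is 1 and the errors are at numerical zero; its value at (400 bar, 338 K)
reproduces the measured maximum 1.07×10⁻³, which is also where the optimum
search lands. The two measured isotherms at 308 and 338 K cross between
160 and 200 bar — below that pressure range heating *reduces* solubility
(the CO₂ density loss dominates), above it heating increases solubility
(the solute vapor-pressure gain dominates). Both refit correlations land
under 9% AARD, with parameters close to the coarse log-linear
initialization.

## Vignette

`vignettes/solubility-modelling.Rmd` documents the models, their
assumptions, the numerical choices (standardization, jitter policy,
optimizer settings, tie-breaks) and the synthetic-data design.
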