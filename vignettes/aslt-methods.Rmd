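---
title: "Accelerated shelf-life testing with asltk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated shelf-life testing with asltk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asltk)
```

## The problem

Nutrients such as vitamin C degrade during storage, and the practical
question — how long does a juice keep 80 % of its initial vitamin C? — is
rarely answerable by storing product at its real shelf temperature and
waiting. Accelerated shelf-life testing (ASLT) stores the product at
several elevated temperatures, models the decay at each, models how the
decay rate depends on temperature, and extrapolates down to refrigeration
conditions. `asltk` implements this chain of inference for isothermal
concentration–time data.

## Primary models

At each storage temperature the package fits three candidate models:

* **Zero order**, $C(t) = C_0 - k_1 t$: ordinary least squares of
  concentration on time. Appropriate when the loss rate is independent of
  the remaining concentration.
* **First order**, $\ln C(t) = \ln C_0 - k_2 t$: OLS of log concentration
  on time. The classical exponential decay.
* **Weibull**, $Y(t) = C(t)/C_0 = \exp(-b\,t^{n})$: a survival-type decay
  on the *retention* scale $Y$. The scale parameter $b$ plays the role of
  a rate; the shape $n$ bends the curve ($n<1$: fast early loss that
  levels off, typical of oxygen-limited or diffusion-limited systems;
  $n=1$: exactly first order).

Model selection takes the fit with the highest $R^2$, each computed on its
own fitting scale (concentration, log concentration, retention) — the
convention used when these three models are compared in the food-kinetics
literature. Ties within $10^{-4}$ go to the simpler model, so noiseless
exponential data reports first-order kinetics rather than the
observationally equivalent Weibull fit with $n = 1$.

### Weibull fitting choices

The Weibull fit is a bounded nonlinear least-squares problem in $(b, n)$
with $b \in [10^{-8}, 10]$ and $n \in [0.01, 5]$, solved by
Levenberg–Marquardt (`minpack.lm::nls.lm`, cost tolerance $10^{-10}$).
$C_0$ is *not* a free parameter: the model statement forces $Y(0) = 1$, so
retention is computed against the measured day-0 concentration. The
optimizer starts from $b = k_2$ of a first-order pre-fit (floored at
$10^{-4}$) and $n = 1$; a $40 \times 40$ log-spaced grid over the bounded
box backs the local search, and the best grid cell is refined locally
whenever it beats the first start. On the smooth 8-point series this
design targets, the first start already reaches the optimum; the grid
exists for pathological inputs.

Because the $t = 0$ residual is structurally zero, including it would
inflate $R^2$ with a point the model cannot miss. The day-0 point is
therefore excluded from both the SSE and the total sum of squares: $R^2 =
1 - \mathrm{SSE}/\mathrm{SST}$ over the $t > 0$ retention points, and
$\mathrm{MSE} = \mathrm{SSE}/m$ with $m$ the number of fitted points (no
degrees-of-freedom correction — the convention that reproduces the
reference study's printed secondary-model MSEs, applied uniformly to all
nonlinear fits in the package).

Series that increase overall are flagged `non_degrading` rather than
rejected; degenerate inputs must not crash a pipeline that a report
depends on.

## Secondary models

The temperature dependence of the Weibull scale parameter $b(T)$ is
described two ways:

* **Arrhenius**: OLS of $\ln b$ on $1/(T + 273.15)$. The activation
  energy is $E_a = -\,\text{slope} \times R$ with
  $R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$, reported in kJ/mol. The slope's
  standard error follows the usual OLS formula (residual variance over
  $S_{xx}$, $n-2$ degrees of freedom) and is undefined — reported as
  `NA` — with only two temperatures.
* **Log-logistic** (Corradini–Peleg):
  $b(T) = \ln\!\big(1 + e^{k_3 (T - T_c)}\big)$, a smooth activation
  curve with characteristic temperature $T_c$, fitted by bounded
  nonlinear least squares ($k_3 \in [10^{-4}, 5]$, $T_c \in [-50, 300]$)
  from a $5 \times 9$ multi-start grid. The curve is evaluated through
  the softplus identity $x + \ln(1 + e^{-x})$ for $x > 0$, so arguments
  like $k_3(T - T_c) = 1000$ return $\approx 1000$ instead of
  overflowing.

Three temperatures is the realistic minimum for either secondary model,
and the fits report `n_points` so downstream consumers can flag the
low-confidence extrapolation that a 3-point regression implies. Neither
secondary model for $b(T)$ feeds the shelf-life extrapolation; they
characterize temperature sensitivity of the rate parameter itself.

## Shelf life

Under the Weibull model the time to reach retention $f$ is closed form:
$t_f = \big((-\ln f)/b\big)^{1/n}$, with $f = 0.80$ — the usual
nutritional acceptability threshold for vitamin C — as the default. The
per-temperature $t_{80}$ values are rounded
half-away-from-zero for reporting, but the Arrhenius regression
$\ln t_{80} = \ln A - (E_a/R)\,/(T + 273.15)$ is fitted on the
**unrounded** values: regressing the rounded integers shifts the slope by
about 1 % and no information is gained by discarding the fractional days.
Predictions at temperatures outside the fitted range carry an
`extrapolated` flag; a 3-point regression extrapolated 30 °C below its
data is an indicative estimate, not a guarantee.

```{r pipeline}
cfg  <- reference_study_config("camu_camu", noise_sd = 0, seed = 1)
pipe <- run_aslt_pipeline(simulate_study(cfg))
pipe$shelf_life
pipe$predictions
```

## The synthetic-data generator

`simulate_study()` forward-simulates the accelerated storage design the
package targets: per temperature, the chosen primary model's mean curve is
evaluated at the true parameters and each sampling time receives
`replicates` noisy measurements. `reference_study_config()` encodes the
two built-in reference matrices — their published Weibull parameter sets,
initial concentrations, and the 35 °C/21 d (every 3 d), 45 °C/14 d (every
2 d), 55 °C/7 d (daily) triplicate schedule.

Noise defaults to additive Gaussian on the retention scale with
sd 0.005. The reference study reports only small replicate standard
deviations relative to means (roughly 0.1–1 % of $C_0$), which an
additive-retention model with sd 0.005 matches in magnitude;
concentration-scale and proportional options cover the alternative
assumptions, and a per-temperature `noise_sd` vector supports
heteroscedastic designs. Replicate values are truncated at a floor of
$10^{-6} C_0$ to preserve positivity — simpler than rejection sampling,
with negligible bias at realistic noise. Seeds are mandatory and
simulation is bit-identical given (config, seed); the generator saves and
restores the caller's RNG state.

What the generator does **not** emulate: temperature fluctuation inside
incubators, autocatalytic or oxygen-depletion dynamics that would make
the true curve deviate from the assumed family, heteroscedasticity that
varies with time rather than temperature, and analytical drift in the
HPLC response. Passing recovery tests therefore demonstrate that the
estimation machinery is correct and well-conditioned under the stated
statistical assumptions — not that real juice follows a Weibull law; that
is an empirical claim the original study makes and this package only
operationalizes.

`recovery_experiment()` wraps the loop — simulate, refit, compare to
truth — reporting bias, relative RMSE, median relative absolute error,
and min–max coverage per parameter. At the reference design with
retention noise sd 0.01, median relative errors of $\hat b$ and $\hat n$
sit around 5 %; the package's tests run 100 such studies, a size chosen
to make the medians stable while keeping the whole suite fast.

## Analytical utilities

* `titratable_acidity()` converts an NaOH titration to g citric acid per
  100 mL via $V \times N \times 0.06404 \times 100 / V_s$. The citric
  acid factor is the milliequivalent weight (0.06404 g/meq): with $V$ in
  mL and $N$ in eq/L the frequently printed equivalent weight 64.04
  produces values 1000-fold too large, so the package uses the
  scale-consistent form.
* `fit_calibration()` / `quantify_from_area()` implement external-standard
  HPLC quantification, with LOD/LOQ from calibration residuals
  ($3.3\sigma/\text{slope}$, $10\sigma/\text{slope}$) by default or from a
  supplied baseline-noise sigma ($3\sigma_N/\text{slope}$,
  $10\sigma_N/\text{slope}$) — the literature uses both routes and rarely
  says which.
* `pearson_r()` screens co-variables against the analyte, with the
  conventional strong/moderate/weak bands at $|r| \ge 0.70$ and $0.40$.

## Design choices that were genuinely open

* **Means, not replicates.** Replicate measurements are averaged per
  sampling time before fitting. Reference studies in this area report
  mean ± SD and fit single curves per temperature; replicate-level
  fitting (or weighting by replicate SD) would change the implied error
  model without data to justify it.
* **$t=0$ exclusion** from the Weibull SSE/SST, argued above; printed
  reference values cannot distinguish the two conventions because raw
  time series are not published.
* **Rounding** is half-away-from-zero, which matches every rounded
  reference shelf-life integer; banker's rounding does not.
* **Threshold $f$ is a parameter** (default 0.80): other analytes and
  jurisdictions use different acceptability thresholds, and the closed
  form generalizes for free.

## Limitations

* Three-temperature designs give 1 residual degree of freedom in the
  secondary regressions; $E_a$ standard errors are wide and the package
  deliberately reports them alongside `n_points` rather than hiding them.
* Arrhenius extrapolation assumes the same degradation mechanism operates
  at 5 °C as at 55 °C; mechanism shifts (e.g. from oxidative to
  anaerobic pathways) break the line and cannot be detected from the
  accelerated data alone.
* Confidence bands on extrapolated shelf life are out of scope; the
  regression SE inputs are exposed for consumers who want to propagate
  them.

## Problem sizes used by the test suite

Unit and property tests run on the 8-point reference schedules; the
stochastic recovery check uses 100 simulated triplicate studies at
retention noise sd 0.01, and the replicate-convergence check uses a
single 10,000-replicate design. The whole suite completes in well under a
minute on one core.
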