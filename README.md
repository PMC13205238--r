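# asltk

Accelerated shelf-life testing (ASLT) kinetics for nutrient degradation in
liquid foods.

Vitamin C in fruit juices degrades during storage, faster at higher
temperatures. ASLT stores product at elevated temperatures (here 35, 45,
55 °C), fits a kinetic model to the observed decay at each temperature, and
extrapolates shelf life to refrigeration and ambient temperatures through a
secondary temperature-dependence model. `asltk` implements that whole
inference pipeline for analysts working with multi-temperature
concentration–time tables, and ships a synthetic study generator so every
stage is testable without laboratory data.

## The models

**Primary (isothermal) kinetics.** Per storage temperature, three models are
fitted and compared by R²:

- zero order: `C(t) = C0 − k1 t` (OLS of C on t)
- first order: `ln C(t) = ln C0 − k2 t` (OLS of ln C on t)
- Weibull: `Y(t) = C(t)/C0 = exp(−b tⁿ)` (bounded nonlinear least squares
  on the retention scale, C0 fixed to the measured day-0 value)

The Weibull scale parameter `b` acts as a temperature-dependent rate; the
shape `n` captures deviation from exponential decay (`n < 1`: an initially
fast loss that levels off; `n = 1` recovers first-order kinetics).

**Secondary (temperature) models** for `b(T)`:

- Arrhenius: `ln b(T) = ln b0 − (Ea/R)·1/(T + 273.15)`, giving the
  activation energy Ea (kJ/mol, R = 8.314 J/mol K) from the regression slope
- log-logistic (Corradini–Peleg): `b(T) = ln(1 + exp(k3 (T − Tc)))`

**Shelf life.** The time to fall to a retention threshold f (default 0.80)
is closed-form under the Weibull model:

```
t80 = ((−ln 0.80) / b)^(1/n)
```

A second Arrhenius regression, `ln t80 = ln A − (Ea/R)·1/(T + 273.15)`
fitted on the unrounded per-temperature t80 values, extrapolates shelf life
to unmeasured storage temperatures.

## Worked example

Two built-in reference configurations reproduce the accelerated storage
design of a published two-matrix tropical juice study (camu camu and
naranjilla): 35 °C/21 d sampled every 3 d, 45 °C/14 d every 2 d, 55 °C/7 d
daily, triplicate measurements.

```r
library(asltk)

cfg  <- reference_study_config("camu_camu", noise_sd = 0, seed = 1)
pipe <- run_aslt_pipeline(simulate_study(cfg))
pipe
#> <aslt_pipeline> 3 temperatures (35, 45, 55 degC), threshold f = 0.8
#>   Ea on b(T): 31.05 kJ/mol (R2 = 0.908)
#>   Ea on t80:  78.32 kJ/mol (R2 = 0.991)

pipe$shelf_life
#>    temperature_c       b       n t_threshold_days t_threshold_days_rounded
#> 35            35 0.07695 0.36305        18.775300                       19
#> 45            45 0.13770 0.22699         8.387079                        8
#> 55            55 0.16037 0.30987         2.903837                        3

pipe$predictions
#>   temperature_c    t_days t_days_rounded extrapolated
#> 1             5 533.98410            534         TRUE
#> 2            10 293.62589            294         TRUE
#> 3            15 164.84440            165         TRUE
#> 4            20  94.38581             94         TRUE
#> 5            25  55.06321             55         TRUE
#> 6            30  32.69917             33         TRUE
```

Reading the output: the fitted Weibull scale parameter rises from 0.077 to
0.160 between 35 and 55 °C — degradation accelerates with temperature — and
the shape parameter stays well below 1, so the loss is front-loaded rather
than exponential. At 35 °C the juice holds 80 % of its initial vitamin C for
about 19 days; the Arrhenius extrapolation predicts roughly a year and a
half (534 days) under refrigeration at 5 °C, flagged `extrapolated` because
5–30 °C lies outside the fitted 35–55 °C range and should be read as an
indicative estimate.

The same pipeline runs on your own data from a long-format CSV
(`temperature_C,time_days,replicate,concentration`):

```r
dataset <- read_study("study.csv")
pipe    <- run_aslt_pipeline(dataset, f = 0.80,
                             target_temperatures = c(5, 25))
```

or from the shell:

```sh
Rscript inst/cli/aslt.R simulate --matrix camu_camu --seed 7 --out study.csv
Rscript inst/cli/aslt.R run --input study.csv --threshold 0.80 --out report/
```

which writes one CSV per stage (`primary_fits.csv`, `secondary_fits.csv`,
`shelf_life.csv`, `predictions.csv`, ...), a JSON bundle, and a Markdown
report.

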