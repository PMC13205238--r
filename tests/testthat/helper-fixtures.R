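# Shared fixtures: the two reference parameter sets (tropical juice
# matrices from a three-temperature accelerated storage design) and
# small constructors for exact synthetic series.

ref_params <- list(
  camu_camu = list(
    temps = c(35, 45, 55),
    b = c(0.07695, 0.1377, 0.16037),
    n = c(0.36305, 0.22699, 0.30987),
    c0 = 1090.17,
    t80_rounded = c(19, 8, 3),
    ea_b = 31.05, r2_b = 0.908,
    ea_t80 = 78.3, slope_t80 = 9420.4,
    ll_mse = 0.000142, ll_rmse = 0.01190,
    pred_5c = 524),
  naranjilla = list(
    temps = c(35, 45, 55),
    b = c(0.00804, 0.04493, 0.13250),
    n = c(0.96644, 0.56064, 0.23923),
    c0 = 43.47,
    t80_rounded = c(31, 17, 9),
    ea_b = 117.8,
    ea_t80 = 52.9, slope_t80 = 6363.1,
    ll_mse = 1.07e-5, ll_r2 = 0.9961,
    pred_5c = 292))

# exact (noiseless) series from a Weibull retention curve
weibull_series <- function(b, n, times = seq(0, 21, by = 3),
                           c0 = 1000, temperature_c = 35) {
  degradation_series(temperature_c, times,
                     c0 * exp(-b * times^n))
}

# exact exponential (first-order) series
exponential_series <- function(k2, times = 0:7, c0 = 100,
                               temperature_c = 35) {
  degradation_series(temperature_c, times, c0 * exp(-k2 * times))
}

# independent closed-form OLS via normal equations (oracle for lm-based
# fits)
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * (sum(y^2) - sum(y)^2 / n))
  list(slope = slope, intercept = intercept, r2 = r^2)
}

# best single-parameter exponential fit exp(-k t) on retention points
# (independent 1-d golden-section oracle for the Weibull nesting bound)
best_exponential_sse <- function(t, y) {
  obj <- function(k) sum((y - exp(-k * t))^2)
  stats::optimize(obj, c(1e-8, 10), tol = 1e-12)$objective
}
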