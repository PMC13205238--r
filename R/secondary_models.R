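# Secondary models: temperature dependence of a kinetic quantity.
# Arrhenius (linearized, OLS on ln q vs 1/T_K) and the Corradini-Peleg
# log-logistic activation curve for the Weibull scale parameter b(T).

GAS_CONSTANT_J <- 8.314  # J/(mol K)

#' Fit an Arrhenius secondary model
#'
#' Ordinary least squares of ln(quantity) on reciprocal absolute
#' temperature 1/(T + 273.15). For a rate-like quantity (the Weibull
#' scale parameter b) the activation energy is Ea = -slope * R; for a
#' shelf-life quantity (t80, which decreases with temperature) the
#' orientation flips and Ea = +slope * R. Ea is reported in kJ/mol with
#' R = 8.314 J/(mol K).
#'
#' The standard error of Ea is the OLS slope standard error (residual
#' variance over Sxx, n - 2 degrees of freedom) scaled by R; with only
#' 2 points it is undefined and reported as `NA`.
#'
#' @param temperature_c Storage temperatures (degC), at least 2 distinct.
#' @param quantity Positive quantity at each temperature (same length).
#' @param orientation `"rate"` for quantities that increase with
#'   temperature on the Arrhenius line, `"shelf_life"` for quantities
#'   that decrease.
#' @return An object of class `arrhenius_fit` with fields `slope` (K),
#'   `intercept`, `ea_kj_mol`, `pre_exponential` (exp(intercept)), `r2`,
#'   `se_ea_kj_mol`, `n_points`, `orientation`, and the input points.
#' @export
fit_arrhenius <- function(temperature_c, quantity,
                          orientation = c("rate", "shelf_life")) {
  orientation <- match.arg(orientation)
  temperature_c <- as.numeric(temperature_c)
  quantity <- as.numeric(quantity)
  if (length(temperature_c) != length(quantity))
    stop("`temperature_c` and `quantity` must have equal length",
         call. = FALSE)
  if (length(temperature_c) < 2L)
    stop("Arrhenius fit needs at least 2 points", call. = FALSE)
  if (anyDuplicated(temperature_c))
    stop("temperatures must be distinct", call. = FALSE)
  if (any(!is.finite(quantity)) || any(quantity <= 0))
    stop("all quantities must be positive and finite", call. = FALSE)

  x <- 1 / (temperature_c + 273.15)
  y <- log(quantity)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  se_slope <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else NA_real_
  sign_ea <- if (orientation == "rate") -1 else 1
  structure(
    list(slope = slope, intercept = intercept,
         ea_kj_mol = sign_ea * slope * GAS_CONSTANT_J / 1000,
         pre_exponential = exp(intercept),
         r2 = r2,
         se_ea_kj_mol = if (is.na(se_slope)) NA_real_
                        else se_slope * GAS_CONSTANT_J / 1000,
         n_points = n, orientation = orientation,
         temperature_c = temperature_c, quantity = quantity),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> ln(q) = %.4g + %.6g / T_K over %d points (R2 = %.4f)\n  Ea = %.4g kJ/mol (%s orientation)%s\n",
    x$intercept, x$slope, x$n_points, x$r2, x$ea_kj_mol, x$orientation,
    if (is.na(x$se_ea_kj_mol)) "" else
      sprintf(", SE %.3g kJ/mol", x$se_ea_kj_mol)))
  invisible(x)
}

#' Evaluate an Arrhenius fit at new temperatures
#'
#' Returns the regression line's value exp(intercept + slope/(T+273.15));
#' at a fitted temperature this is the line, not the observed point.
#'
#' @param fit An [fit_arrhenius()] result.
#' @param temperature_c Temperatures (degC), vectorized.
#' @return Predicted quantity on the original scale.
#' @export
predict_arrhenius <- function(fit, temperature_c) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  exp(fit$intercept + fit$slope / (as.numeric(temperature_c) + 273.15))
}

#' Evaluate the log-logistic secondary model
#'
#' b(T) = ln(1 + exp(k3 (T - Tc))), computed through the overflow-safe
#' softplus identity x + ln(1 + exp(-x)) for large positive arguments.
#' At T = Tc the value is ln 2 for any k3; for k3 > 0 the curve is
#' strictly increasing in T.
#'
#' @param k3 Temperature-sensitivity constant (1/degC).
#' @param tc Characteristic temperature (degC).
#' @param temperature_c Temperatures (degC), vectorized.
#' @return Predicted scale parameter b.
#' @export
evaluate_log_logistic <- function(k3, tc, temperature_c) {
  x <- k3 * (as.numeric(temperature_c) - tc)
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

log_logistic_bounds <- list(k3 = c(1e-4, 5), tc = c(-50, 300))

ll_local_fit <- function(start, temps, b) {
  res <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p)
      b - evaluate_log_logistic(p[["k3"]], p[["tc"]], temps),
    lower = c(log_logistic_bounds$k3[1L], log_logistic_bounds$tc[1L]),
    upper = c(log_logistic_bounds$k3[2L], log_logistic_bounds$tc[2L]),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200L)),
    silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  p <- res$par
  sse <- sum((b - evaluate_log_logistic(p[["k3"]], p[["tc"]], temps))^2)
  list(k3 = p[["k3"]], tc = p[["tc"]], sse = sse)
}

#' Fit the log-logistic secondary model for b(T)
#'
#' Nonlinear least squares over (k3, Tc) minimizing the squared error of
#' b(T) = ln(1 + exp(k3 (T - Tc))) against observed Weibull scale
#' parameters, with bounds k3 in \[1e-4, 5\] and Tc in \[-50, 300\] and a
#' coarse multi-start grid over both parameters. MSE uses denominator =
#' number of points; R2 = 1 - SSE/SST about the mean of the observed b.
#'
#' @param temperature_c Temperatures (degC), at least 3.
#' @param b Weibull scale parameter at each temperature.
#' @return An object of class `log_logistic_fit` with fields `k3`, `tc`,
#'   and `metrics` (R2, MSE, RMSE on the b scale).
#' @export
fit_log_logistic <- function(temperature_c, b) {
  temps <- as.numeric(temperature_c)
  b <- as.numeric(b)
  if (length(temps) != length(b))
    stop("`temperature_c` and `b` must have equal length", call. = FALSE)
  if (length(temps) < 3L)
    stop("log-logistic fit needs at least 3 points (2 parameters)",
         call. = FALSE)

  starts <- expand.grid(
    k3 = c(0.01, 0.03, 0.1, 0.3, 1),
    tc = seq(-40, 280, by = 40))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    cand <- ll_local_fit(c(k3 = starts$k3[i], tc = starts$tc[i]),
                         temps, b)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse))
      best <- cand
  }
  if (is.null(best)) {
    err <- simpleError("log-logistic fit failed to converge")
    stop(err)
  }
  sst <- sum((b - mean(b))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else 1
  structure(
    list(k3 = best$k3, tc = best$tc,
         metrics = new_fit_metrics(r2, best$sse / length(b)),
         n_points = length(b),
         temperature_c = temps, b = b),
    class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<log_logistic_fit> k3 = %.5g 1/degC, Tc = %.4g degC (R2 = %.4f, MSE = %.3g)\n",
    x$k3, x$tc, x$metrics$r2, x$metrics$mse))
  invisible(x)
}
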