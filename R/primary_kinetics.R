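# Primary (isothermal) kinetic models: zero-order, first-order, Weibull.
# Linear models are fitted by OLS; the Weibull model by bounded nonlinear
# least squares on the retention scale.

new_fit_metrics <- function(r2, mse) {
  stopifnot(is.finite(mse), mse >= 0)
  list(r2 = r2, mse = mse, rmse = sqrt(mse))
}

# Goodness of fit for a linear fit: r2 as squared Pearson correlation of
# (x, y); MSE with denominator = number of fitted points.
linear_fit_metrics <- function(y, fitted) {
  resid <- y - fitted
  mse <- mean(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  new_fit_metrics(r2, mse)
}

new_primary_fit <- function(model, temperature_c, c0, metrics,
                            response_scale, params, n_points,
                            non_degrading = FALSE) {
  structure(
    c(list(model = model, temperature_c = temperature_c, c0 = c0,
           metrics = metrics, response_scale = response_scale,
           n_points = n_points, non_degrading = non_degrading),
      params),
    class = "primary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  par_str <- switch(x$model,
    zero = sprintf("k1 = %.5g mg/100 mL/day", x$k1),
    first = sprintf("k2 = %.5g 1/day", x$k2),
    weibull = sprintf("b = %.5g, n = %.5g", x$b, x$n))
  cat(sprintf("<primary_fit> %s model at %g degC: %s (R2 = %.4f)\n",
              x$model, x$temperature_c, par_str, x$metrics$r2))
  invisible(x)
}

check_trend <- function(series) {
  # degenerate inputs (overall increase) are flagged, never fatal
  n <- length(series$concentrations)
  series$concentrations[n] > series$concentrations[1L]
}

#' Fit a zero-order degradation model
#'
#' Ordinary least squares of concentration on time, C(t) = C0 - k1 t.
#' The rate constant k1 is the negative slope; metrics (R2, MSE, RMSE)
#' are computed on the concentration scale.
#'
#' @param series A [degradation_series()] with at least 3 time points.
#' @return A `primary_fit` with fields `k1` (mg/100 mL/day) and `c0`
#'   (the fitted intercept).
#' @export
fit_zero_order <- function(series) {
  stopifnot(inherits(series, "degradation_series"))
  t <- series$times; y <- series$concentrations
  if (length(unique(t)) < 2L)
    stop("singular design: all sampling times equal", call. = FALSE)
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  new_primary_fit(
    model = "zero", temperature_c = series$temperature_c,
    c0 = unname(stats::coef(fit)[1L]),
    metrics = linear_fit_metrics(y, stats::fitted(fit)),
    response_scale = "concentration",
    params = list(k1 = -slope, slope = slope,
                  intercept = unname(stats::coef(fit)[1L])),
    n_points = length(t), non_degrading = check_trend(series))
}

#' Fit a first-order degradation model
#'
#' Ordinary least squares of ln C on time: ln C(t) = ln C0 - k2 t.
#' The rate constant k2 is the negative slope; metrics are computed on
#' the log-concentration scale.
#'
#' @param series A [degradation_series()] with at least 3 time points and
#'   strictly positive concentrations.
#' @return A `primary_fit` with fields `k2` (1/day) and `c0`
#'   (exp of the fitted intercept).
#' @export
fit_first_order <- function(series) {
  stopifnot(inherits(series, "degradation_series"))
  t <- series$times; y <- log(series$concentrations)
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  new_primary_fit(
    model = "first", temperature_c = series$temperature_c,
    c0 = exp(intercept),
    metrics = linear_fit_metrics(y, stats::fitted(fit)),
    response_scale = "log-concentration",
    params = list(k2 = -slope, slope = slope, intercept = intercept),
    n_points = length(t), non_degrading = check_trend(series))
}

weibull_predict <- function(b, n, t) exp(-b * t^n)

# SSE of the Weibull retention model at (b, n) over the t > 0 points.
weibull_sse <- function(b, n, t, y) sum((y - weibull_predict(b, n, t))^2)

weibull_bounds <- list(b = c(1e-8, 10), n = c(0.01, 5))

# Coarse log-spaced multi-start grid used when the local optimizer fails
# or lands above a grid cell.
weibull_grid_search <- function(t, y) {
  bs <- exp(seq(log(weibull_bounds$b[1L]), log(weibull_bounds$b[2L]),
                length.out = 40L))
  ns <- exp(seq(log(weibull_bounds$n[1L]), log(weibull_bounds$n[2L]),
                length.out = 40L))
  grid <- expand.grid(b = bs, n = ns)
  sse <- mapply(weibull_sse, grid$b, grid$n,
                MoreArgs = list(t = t, y = y))
  best <- which.min(sse)
  list(b = grid$b[best], n = grid$n[best], sse = sse[best])
}

weibull_local_fit <- function(start, t, y) {
  res <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - weibull_predict(p[["b"]], p[["n"]], t),
    lower = c(weibull_bounds$b[1L], weibull_bounds$n[1L]),
    upper = c(weibull_bounds$b[2L], weibull_bounds$n[2L]),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200L)),
    silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  p <- res$par
  list(b = p[["b"]], n = p[["n"]],
       sse = weibull_sse(p[["b"]], p[["n"]], t, y))
}

#' Fit the Weibull degradation model on the retention scale
#'
#' Normalizes the series to retention Y(t) = C(t)/C0 (C0 fixed to the
#' measured day-0 concentration) and minimizes the sum of squared
#' residuals of Y(t) = exp(-b t^n) over the t > 0 points by bounded
#' nonlinear least squares (b in \[1e-8, 10\], n in \[0.01, 5\]).
#' The optimizer is initialized from a first-order pre-fit
#' (b = k2 floored at 1e-4, n = 1) and backed by a log-spaced multi-start
#' grid, which is refined locally whenever it beats the first start.
#'
#' Because the t = 0 residual is structurally zero (Y(0) = 1 by
#' construction), the day-0 point is excluded from both SSE and the total
#' sum of squares, so R2 = 1 - SSE/SST is computed over the t > 0
#' retention points only.
#'
#' @param series A [degradation_series()] with at least 3 points
#'   including t = 0 and strictly positive concentrations.
#' @return A `primary_fit` with fields `b` (scale, 1/day^n) and `n`
#'   (dimensionless shape); metrics on the retention scale.
#' @export
fit_weibull <- function(series) {
  stopifnot(inherits(series, "degradation_series"))
  ret <- normalize_retention(series)
  keep <- ret$times > 0
  t <- ret$times[keep]; y <- ret$retention[keep]
  if (length(t) < 2L)
    stop("Weibull fit needs at least 2 points after t = 0", call. = FALSE)

  first <- fit_first_order(series)
  b0 <- max(first$k2, 1e-4)
  b0 <- min(max(b0, weibull_bounds$b[1L]), weibull_bounds$b[2L])

  cand <- weibull_local_fit(c(b = b0, n = 1), t, y)
  grid <- weibull_grid_search(t, y)
  if (is.null(cand) || grid$sse < cand$sse) {
    refined <- weibull_local_fit(c(b = grid$b, n = grid$n), t, y)
    if (!is.null(refined) &&
        (is.null(cand) || refined$sse <= cand$sse)) cand <- refined
    if (is.null(cand)) cand <- grid
  }
  if (is.null(cand) || !is.finite(cand$sse)) {
    err <- simpleError("Weibull fit failed to converge after multi-start")
    err$best_candidate <- grid
    stop(err)
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - cand$sse / sst else 1
  mse <- cand$sse / length(t)
  new_primary_fit(
    model = "weibull", temperature_c = series$temperature_c,
    c0 = series$concentrations[1L],
    metrics = new_fit_metrics(r2, mse),
    response_scale = "retention",
    params = list(b = cand$b, n = cand$n),
    n_points = length(t), non_degrading = check_trend(series))
}

#' Fit all three primary models to one series
#'
#' @param series A [degradation_series()].
#' @return Named list with elements `zero`, `first`, `weibull`.
#' @export
fit_primary_models <- function(series) {
  list(zero = fit_zero_order(series),
       first = fit_first_order(series),
       weibull = fit_weibull(series))
}

# model complexity used for the tie rule (simpler model preferred)
primary_model_complexity <- c(zero = 1L, first = 2L, weibull = 3L)

#' Select the best primary model by R2
#'
#' Returns the fit with the highest coefficient of determination, each
#' metric taken on its own fitting scale (concentration, log
#' concentration, retention). Ties within 1e-4 are resolved toward the
#' simpler model (zero before first before Weibull).
#'
#' @param fits List of `primary_fit` objects for the same series.
#' @return The selected `primary_fit`.
#' @export
select_primary_model <- function(fits) {
  if (length(fits) == 0L)
    stop("`fits` must contain at least one primary_fit", call. = FALSE)
  ok <- vapply(fits, inherits, logical(1L), "primary_fit")
  if (!all(ok))
    stop("all elements must be primary_fit objects", call. = FALSE)
  r2 <- vapply(fits, function(f) f$metrics$r2, numeric(1L))
  best_r2 <- max(r2)
  tied <- which(r2 >= best_r2 - 1e-4)
  cx <- primary_model_complexity[
    vapply(fits[tied], `[[`, character(1L), "model")]
  fits[[tied[which.min(cx)]]]
}
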