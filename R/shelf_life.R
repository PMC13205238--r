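# Retention-threshold shelf life from Weibull parameters and its
# Arrhenius extrapolation to unmeasured storage temperatures.

#' Round half away from zero
#'
#' Commercial rounding to the nearest integer day (base `round()` uses
#' round-half-even); used for all rounded shelf-life columns.
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Time to reach a retention threshold under the Weibull model
#'
#' Inverts Y(t) = exp(-b t^n) at Y = f: t = ((-ln f)/b)^(1/n).
#' With f = 0.80 this is the t80 shelf life, the time for the analyte to
#' fall to 80 percent of its initial concentration.
#'
#' @param b Weibull scale parameter (> 0), vectorized.
#' @param n Weibull shape parameter (> 0), vectorized.
#' @param f Retention threshold fraction in (0, 1); default 0.80.
#' @return Time in days.
#' @export
retention_time <- function(b, n, f = 0.80) {
  b <- as.numeric(b); n <- as.numeric(n); f <- as.numeric(f)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("`b` must be positive", call. = FALSE)
  if (any(!is.finite(n)) || any(n <= 0))
    stop("`n` must be positive", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("`f` must lie strictly between 0 and 1", call. = FALSE)
  ((-log(f)) / b)^(1 / n)
}

#' Build a per-temperature shelf-life table from Weibull fits
#'
#' One row per storage temperature with the Weibull parameters, the
#' unrounded threshold time, and the nearest integer day
#' (round-half-away-from-zero).
#'
#' @param weibull_fits List of `primary_fit` objects with
#'   `model == "weibull"` at distinct temperatures.
#' @param f Retention threshold fraction; default 0.80 (t80).
#' @return A `shelf_life_table`: a data frame with columns
#'   `temperature_c`, `b`, `n`, `t_threshold_days`,
#'   `t_threshold_days_rounded` and attribute `threshold_fraction`.
#' @export
build_shelf_life_table <- function(weibull_fits, f = 0.80) {
  stopifnot(is.list(weibull_fits), length(weibull_fits) >= 1L)
  ok <- vapply(weibull_fits, function(x)
    inherits(x, "primary_fit") && x$model == "weibull", logical(1L))
  if (!all(ok))
    stop("all fits must be Weibull primary fits", call. = FALSE)
  temps <- vapply(weibull_fits, `[[`, numeric(1L), "temperature_c")
  if (anyDuplicated(temps))
    stop("duplicate temperatures in shelf-life table", call. = FALSE)
  o <- order(temps)
  b <- vapply(weibull_fits, `[[`, numeric(1L), "b")[o]
  n <- vapply(weibull_fits, `[[`, numeric(1L), "n")[o]
  t_days <- retention_time(b, n, f)
  out <- data.frame(temperature_c = temps[o], b = b, n = n,
                    t_threshold_days = t_days,
                    t_threshold_days_rounded = round_half_away(t_days))
  attr(out, "threshold_fraction") <- f
  class(out) <- c("shelf_life_table", "data.frame")
  out
}

#' Fit the Arrhenius regression on threshold shelf life
#'
#' Regresses ln(t80) on reciprocal absolute temperature using the
#' unrounded threshold times (shelf_life orientation: Ea = +slope * R).
#' The resulting line extrapolates shelf life to storage temperatures
#' outside the measured range.
#'
#' @param table A [build_shelf_life_table()] result with >= 2 rows.
#' @return A `shelf_life_prediction` with fields `arrhenius`
#'   (an `arrhenius_fit`) and `table` (the input table).
#' @export
fit_shelf_life_arrhenius <- function(table) {
  stopifnot(inherits(table, "shelf_life_table"))
  if (nrow(table) < 2L)
    stop("shelf-life Arrhenius fit needs >= 2 temperatures",
         call. = FALSE)
  fit <- fit_arrhenius(table$temperature_c, table$t_threshold_days,
                       orientation = "shelf_life")
  structure(list(arrhenius = fit, table = table),
            class = "shelf_life_prediction")
}

#' Predict shelf life at target storage temperatures
#'
#' Evaluates the fitted Arrhenius line t80(T) = exp(intercept +
#' slope/(T + 273.15)) at each requested temperature. Predictions at
#' temperatures outside the fitted range are flagged as extrapolations
#' and should be read as indicative estimates.
#'
#' @param pred A [fit_shelf_life_arrhenius()] result.
#' @param temperatures_c Target temperatures (degC).
#' @return Data frame with columns `temperature_c`, `t_days`,
#'   `t_days_rounded`, `extrapolated`.
#' @export
predict_shelf_life <- function(pred, temperatures_c) {
  stopifnot(inherits(pred, "shelf_life_prediction"))
  temps <- as.numeric(temperatures_c)
  t_days <- predict_arrhenius(pred$arrhenius, temps)
  rng <- range(pred$table$temperature_c)
  data.frame(temperature_c = temps,
             t_days = t_days,
             t_days_rounded = round_half_away(t_days),
             extrapolated = temps < rng[1L] | temps > rng[2L])
}

#' Run the full accelerated shelf-life testing pipeline
#'
#' Executes, per storage temperature: normalization to retention and
#' fitting of the zero-order, first-order, and Weibull primary models,
#' then selection of the best model by R2. The Weibull scale parameters
#' b(T) feed two secondary models (Arrhenius and log-logistic); the
#' Weibull (b, n) pairs give the per-temperature threshold shelf life,
#' whose own Arrhenius regression extrapolates shelf life to the target
#' temperatures.
#'
#' Stages that need more than one temperature (secondary models, shelf
#' life) fail softly when the dataset cannot support them: the error is
#' recorded under `$errors` keyed by stage name and the remaining stages
#' are skipped, while the primary fits are always returned.
#'
#' @param dataset A [storage_dataset()].
#' @param f Retention threshold fraction; default 0.80.
#' @param target_temperatures Temperatures (degC) at which to predict
#'   shelf life; default 5 to 30 degC in steps of 5.
#' @return An `aslt_pipeline` list with stages `primary_fits`,
#'   `selected_models`, `weibull_fits`, `arrhenius_b`, `log_logistic_b`,
#'   `shelf_life`, `arrhenius_t80`, `predictions`, and `errors`.
#' @export
run_aslt_pipeline <- function(dataset, f = 0.80,
                              target_temperatures = seq(5, 30, by = 5)) {
  stopifnot(inherits(dataset, "storage_dataset"))
  primary <- lapply(dataset$series, fit_primary_models)
  selected <- lapply(primary, select_primary_model)
  weibull <- lapply(primary, `[[`, "weibull")
  temps <- dataset_temperatures(dataset)
  b <- vapply(weibull, `[[`, numeric(1L), "b")
  n <- vapply(weibull, `[[`, numeric(1L), "n")

  errors <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
      errors[[stage]] <<- e
      NULL
    })
  }

  arrhenius_b <- run_stage("arrhenius_b",
    fit_arrhenius(temps, b, orientation = "rate"))
  log_logistic_b <- run_stage("log_logistic_b",
    fit_log_logistic(temps, b))
  shelf <- run_stage("shelf_life", {
    if (length(temps) < 2L)
      stop("shelf-life extrapolation needs >= 2 temperatures",
           call. = FALSE)
    build_shelf_life_table(weibull, f = f)
  })
  arr_t80 <- if (is.null(shelf)) NULL else
    run_stage("arrhenius_t80", fit_shelf_life_arrhenius(shelf))
  preds <- if (is.null(arr_t80)) NULL else
    run_stage("predictions",
              predict_shelf_life(arr_t80, target_temperatures))

  structure(
    list(primary_fits = primary,
         selected_models = selected,
         weibull_fits = weibull,
         arrhenius_b = arrhenius_b,
         log_logistic_b = log_logistic_b,
         shelf_life = shelf,
         arrhenius_t80 = arr_t80,
         predictions = preds,
         threshold_fraction = f,
         target_temperatures = as.numeric(target_temperatures),
         errors = errors),
    class = "aslt_pipeline")
}

#' @export
print.aslt_pipeline <- function(x, ...) {
  temps <- vapply(x$weibull_fits, `[[`, numeric(1L), "temperature_c")
  cat(sprintf("<aslt_pipeline> %d temperatures (%s degC), threshold f = %g\n",
              length(temps), paste(temps, collapse = ", "),
              x$threshold_fraction))
  if (!is.null(x$arrhenius_b))
    cat(sprintf("  Ea on b(T): %.4g kJ/mol (R2 = %.3f)\n",
                x$arrhenius_b$ea_kj_mol, x$arrhenius_b$r2))
  if (!is.null(x$arrhenius_t80))
    cat(sprintf("  Ea on t80:  %.4g kJ/mol (R2 = %.3f)\n",
                x$arrhenius_t80$arrhenius$ea_kj_mol,
                x$arrhenius_t80$arrhenius$r2))
  if (length(x$errors))
    cat(sprintf("  failed stages: %s\n",
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}
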