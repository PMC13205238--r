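#' Construct a single-temperature degradation series
#'
#' A degradation series holds one storage temperature's concentration-time
#' trajectory: sampling times in days (starting at day 0), the mean analyte
#' concentration at each time, and optionally the replicate standard
#' deviation per sampling point. The day-0 concentration is the initial
#' value C0 used to normalize the series to retention.
#'
#' @param temperature_c Storage temperature in degrees Celsius (scalar).
#' @param times Sampling times in days; non-negative, strictly increasing,
#'   first element must be 0.
#' @param concentrations Mean analyte concentration at each time
#'   (mg/100 mL); all values must be positive.
#' @param replicate_sd Optional per-time standard deviation across
#'   replicates (mg/100 mL).
#' @param analyte Free-text analyte label.
#' @return An object of class `degradation_series`.
#' @seealso [normalize_retention()], [read_study()]
#' @export
degradation_series <- function(temperature_c, times, concentrations,
                               replicate_sd = NULL,
                               analyte = "vitamin C") {
  stopifnot(is.numeric(temperature_c), length(temperature_c) == 1L)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("`times` and `concentrations` must have equal length",
         call. = FALSE)
  if (length(times) < 3L)
    stop("a degradation series needs at least 3 sampling times",
         call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(concentrations)))
    stop("times and concentrations must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (times[1L] != 0)
    stop("the first sampling time must be 0 (initial concentration C0 ",
         "is required for normalization)", call. = FALSE)
  bad <- which(concentrations <= 0)
  if (length(bad))
    stop(sprintf("non-positive concentration at row %d", bad[1L]),
         call. = FALSE)
  if (!is.null(replicate_sd)) {
    replicate_sd <- as.numeric(replicate_sd)
    stopifnot(length(replicate_sd) == length(times))
  }
  structure(
    list(temperature_c = as.numeric(temperature_c),
         times = times,
         concentrations = concentrations,
         replicate_sd = replicate_sd,
         analyte = analyte),
    class = "degradation_series")
}

#' @export
print.degradation_series <- function(x, ...) {
  cat(sprintf("<degradation_series> %s at %g degC: %d points over %g days, C0 = %g mg/100 mL\n",
              x$analyte, x$temperature_c, length(x$times),
              max(x$times), x$concentrations[1L]))
  invisible(x)
}

#' Normalize a degradation series to retention
#'
#' Retention is the dimensionless fraction Y(t) = C(t)/C0, the response
#' scale on which the Weibull primary model is defined. Y(0) is exactly 1.
#'
#' @param series A [degradation_series()].
#' @return An object of class `retention_series` with fields
#'   `temperature_c`, `times`, and `retention`.
#' @export
normalize_retention <- function(series) {
  stopifnot(inherits(series, "degradation_series"))
  c0 <- series$concentrations[1L]
  if (!is.finite(c0) || c0 <= 0)
    stop("initial concentration C0 must be positive", call. = FALSE)
  structure(
    list(temperature_c = series$temperature_c,
         times = series$times,
         retention = series$concentrations / c0),
    class = "retention_series")
}

#' Bundle degradation series at distinct temperatures into a storage dataset
#'
#' @param series List of [degradation_series()] objects at distinct
#'   temperatures. A secondary (temperature-dependence) fit needs at least
#'   2 distinct temperatures; accelerated storage designs typically use 3.
#' @param metadata Named list of free-form provenance notes (matrix name,
#'   units, source).
#' @return An object of class `storage_dataset`; the series are ordered by
#'   temperature.
#' @export
storage_dataset <- function(series, metadata = list()) {
  stopifnot(is.list(series), length(series) >= 1L)
  ok <- vapply(series, inherits, logical(1L), "degradation_series")
  if (!all(ok))
    stop("all elements of `series` must be degradation_series objects",
         call. = FALSE)
  temps <- vapply(series, `[[`, numeric(1L), "temperature_c")
  if (anyDuplicated(temps))
    stop("series temperatures must be distinct", call. = FALSE)
  series <- series[order(temps)]
  names(series) <- sprintf("%g", sort(temps))
  structure(list(series = series, metadata = metadata),
            class = "storage_dataset")
}

#' @export
print.storage_dataset <- function(x, ...) {
  temps <- vapply(x$series, `[[`, numeric(1L), "temperature_c")
  cat(sprintf("<storage_dataset> %d temperatures (%s degC)\n",
              length(temps), paste(temps, collapse = ", ")))
  invisible(x)
}

#' Temperatures present in a storage dataset
#' @param dataset A [storage_dataset()].
#' @return Numeric vector of storage temperatures (degC), ascending.
#' @export
dataset_temperatures <- function(dataset) {
  stopifnot(inherits(dataset, "storage_dataset"))
  unname(vapply(dataset$series, `[[`, numeric(1L), "temperature_c"))
}

study_required_cols <- c("temperature_C", "time_days", "concentration")

#' Read a multi-temperature degradation study from long-format CSV
#'
#' The expected layout is one row per measurement with columns
#' `temperature_C`, `time_days`, `concentration` and an optional
#' `replicate` column. Replicate rows sharing a (temperature, time) cell
#' are averaged into the per-time mean concentration, and the per-cell
#' standard deviation is recorded. Every temperature must include a row at
#' time 0 (the initial concentration).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param format Input format; only `"csv-long"` is supported.
#' @return A [storage_dataset()].
#' @export
read_study <- function(path, format = "csv-long") {
  format <- match.arg(format, "csv-long")
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(study_required_cols, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$concentration) | df$concentration <= 0)
  if (length(bad))
    stop(sprintf("non-positive concentration at CSV row %d", bad[1L]),
         call. = FALSE)
  series <- lapply(split(df, df$temperature_C), function(g) {
    temp <- g$temperature_C[1L]
    if (!any(g$time_days == 0))
      stop(sprintf("no time-0 row for temperature %g degC", temp),
           call. = FALSE)
    agg_mean <- stats::aggregate(concentration ~ time_days, g, mean)
    agg_n <- stats::aggregate(concentration ~ time_days, g, length)
    agg_sd <- stats::aggregate(concentration ~ time_days, g,
                               stats::sd)
    o <- order(agg_mean$time_days)
    rep_sd <- if (any(agg_n$concentration > 1L))
      agg_sd$concentration[o] else NULL
    degradation_series(temperature_c = temp,
                       times = agg_mean$time_days[o],
                       concentrations = agg_mean$concentration[o],
                       replicate_sd = rep_sd)
  })
  storage_dataset(unname(series),
                  metadata = list(source = path, format = format))
}

#' Write a storage dataset to long-format CSV
#'
#' Writes the long layout read back by [read_study()]. If the dataset
#' carries replicate-level data (as produced by [simulate_study()]) and
#' `replicates = TRUE`, individual replicate rows are written; otherwise
#' one row per (temperature, time) holds the mean concentration.
#'
#' @param dataset A [storage_dataset()].
#' @param path Output CSV path.
#' @param replicates Write replicate-level rows when available.
#' @return `path`, invisibly.
#' @export
write_study <- function(dataset, path, replicates = TRUE) {
  stopifnot(inherits(dataset, "storage_dataset"))
  long <- attr(dataset, "replicate_data")
  if (!replicates || is.null(long)) {
    long <- do.call(rbind, lapply(dataset$series, function(s) {
      data.frame(temperature_C = s$temperature_c,
                 time_days = s$times,
                 replicate = 1L,
                 concentration = s$concentrations)
    }))
  }
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a physicochemical co-variable series
#'
#' Holds pH, titratable acidity, and total soluble solids trajectories
#' measured alongside the analyte at one storage temperature.
#'
#' @param temperature_c Storage temperature (degC).
#' @param times Sampling times (days).
#' @param ph pH values (dimensionless).
#' @param acidity Titratable acidity (g citric acid/100 mL, non-negative).
#' @param brix Total soluble solids (degrees Brix, non-negative).
#' @return An object of class `physicochem_series`.
#' @export
physicochem_series <- function(temperature_c, times, ph = NULL,
                               acidity = NULL, brix = NULL) {
  times <- as.numeric(times)
  n <- length(times)
  chk <- function(x, name, lower = -Inf) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != n)
      stop(sprintf("`%s` must match length of `times`", name),
           call. = FALSE)
    if (any(!is.finite(x)) || any(x < lower))
      stop(sprintf("`%s` must be finite and >= %g", name, lower),
           call. = FALSE)
    x
  }
  structure(
    list(temperature_c = as.numeric(temperature_c), times = times,
         ph = chk(ph, "ph"),
         acidity = chk(acidity, "acidity", 0),
         brix = chk(brix, "brix", 0)),
    class = "physicochem_series")
}
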