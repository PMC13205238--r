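# Analytical utilities: NaOH titration, external-standard HPLC
# calibration with LOD/LOQ, and the Pearson correlation screen.

#' Titratable acidity from an NaOH titration
#'
#' Acidity expressed as g citric acid per 100 mL of sample:
#' V x N x 0.06404 x 100 / sample volume, where 0.06404 g/meq is the
#' milliequivalent weight of citric acid (the equivalent weight 64.04
#' g/eq divided by 1000 to match V in mL and N in eq/L). Linear in both
#' V and N.
#'
#' @param naoh_volume_ml Titrant volume V (mL, >= 0).
#' @param normality NaOH normality N (eq/L, > 0).
#' @param sample_volume_ml Sample volume (mL, > 0).
#' @param acid_factor Milliequivalent weight of the reference acid
#'   (g/meq); default 0.06404 for citric acid.
#' @return Acidity in g citric acid per 100 mL.
#' @export
titratable_acidity <- function(naoh_volume_ml, normality,
                               sample_volume_ml,
                               acid_factor = 0.06404) {
  if (any(!is.finite(sample_volume_ml)) || any(sample_volume_ml <= 0))
    stop("`sample_volume_ml` must be positive", call. = FALSE)
  if (any(naoh_volume_ml < 0) || any(normality <= 0) ||
      any(acid_factor <= 0))
    stop("titration record values must be positive", call. = FALSE)
  naoh_volume_ml * normality * acid_factor * 100 / sample_volume_ml
}

#' Fit an external-standard calibration curve
#'
#' OLS of detector peak area on standard concentration. Detection and
#' quantification limits default to the calibration-residual route
#' (3.3 sigma/slope and 10 sigma/slope, sigma = residual standard
#' deviation); when a measured baseline-noise standard deviation is
#' supplied, the signal-to-noise route (3 sigma_noise/slope and
#' 10 sigma_noise/slope) is used instead.
#'
#' @param concentration_mg_l Standard concentrations (mg/L), >= 3
#'   distinct values.
#' @param area Peak areas (detector units).
#' @param noise_sd Optional baseline-noise standard deviation in area
#'   units.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r2`, `lod_mg_l`, `loq_mg_l`, `concentration_range`.
#' @export
fit_calibration <- function(concentration_mg_l, area, noise_sd = NULL) {
  x <- as.numeric(concentration_mg_l); y <- as.numeric(area)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 calibration standards", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("singular design: all standard concentrations equal",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  resid_sd <- if (length(x) > 2L)
    sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2L)) else 0
  sigma <- if (is.null(noise_sd)) resid_sd else as.numeric(noise_sd)
  lod_mult <- if (is.null(noise_sd)) 3.3 else 3
  sst <- sum((y - mean(y))^2)
  structure(
    list(slope = slope, intercept = intercept,
         r2 = 1 - sum(stats::residuals(fit)^2) / sst,
         lod_mg_l = lod_mult * sigma / slope,
         loq_mg_l = 10 * sigma / slope,
         concentration_range = range(x),
         sigma_route = if (is.null(noise_sd)) "calibration-residual"
                       else "baseline-noise"),
    class = "calibration_curve")
}

#' Quantify analyte concentration from a peak area
#'
#' Inverts the calibration line, applies the dilution factor, and
#' converts mg/L to mg/100 mL (divide by 10). Areas outside the
#' calibrated response range trigger a warning, not an error;
#' non-positive back-calculated concentrations are flagged below-range.
#'
#' @param curve A [fit_calibration()] result.
#' @param area Measured peak area, vectorized.
#' @param dilution_factor Total dilution applied before injection
#'   (e.g. 4 for a 1:3 dilution); default 1.
#' @return Numeric vector of concentrations in mg/100 mL with attribute
#'   `below_range` (logical vector).
#' @export
quantify_from_area <- function(curve, area, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  area <- as.numeric(area)
  conc_mg_l <- (area - curve$intercept) / curve$slope
  rng <- curve$concentration_range
  outside <- conc_mg_l < rng[1L] | conc_mg_l > rng[2L]
  if (any(outside))
    warning(sprintf(
      "%d area value(s) back-calculate outside the calibrated range [%g, %g] mg/L",
      sum(outside), rng[1L], rng[2L]), call. = FALSE)
  out <- conc_mg_l * dilution_factor / 10
  # numerical slack: an area at the fitted intercept back-calculates to
  # zero only up to the line's floating-point error
  attr(out, "below_range") <-
    conc_mg_l <= sqrt(.Machine$double.eps) * rng[2L]
  out
}

#' Pearson correlation with strength classification
#'
#' Product-moment correlation between two series, classified as strong
#' (|r| >= 0.70), moderate (0.40 <= |r| < 0.70), or weak (|r| < 0.40).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return The correlation coefficient with attribute `strength`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  attr(r, "strength") <- classify_correlation(r)
  r
}

#' Classify correlation strength
#' @param r Correlation coefficient(s).
#' @return Character vector: `"strong"`, `"moderate"`, or `"weak"`.
#' @export
classify_correlation <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.70, "strong", ifelse(a >= 0.40, "moderate", "weak"))
}
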