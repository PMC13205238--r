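# Synthetic degradation-study generator: forward-simulates isothermal
# decay under a chosen primary model with replicate measurement noise,
# emulating a three-temperature accelerated storage design, plus a
# parameter-recovery harness for the full pipeline.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Configure a synthetic degradation study
#'
#' Defines the true kinetic model and parameters per storage
#' temperature, the sampling schedule, the replicate count, and the
#' measurement-noise model. The seed is mandatory: simulation is fully
#' deterministic given the configuration.
#'
#' @param model Primary model generating the mean curve: `"weibull"`
#'   (params `b`, `n`), `"zero"` (param `k1`), or `"first"` (param `k2`).
#' @param temperatures_c Storage temperatures (degC).
#' @param params Named list of per-temperature parameter vectors, each
#'   the same length as `temperatures_c`: `b` and `n` for Weibull, `k1`
#'   for zero-order, `k2` for first-order.
#' @param c0 True initial concentration (mg/100 mL).
#' @param schedule List of sampling-time vectors (days), one per
#'   temperature, each starting at 0.
#' @param replicates Replicates per sampling point (>= 1); default 3.
#' @param noise_model `"additive-retention"` (Gaussian sd on the Y
#'   scale), `"additive-concentration"` (sd in mg/100 mL), or
#'   `"proportional"` (sd as a fraction of the mean).
#' @param noise_sd Noise standard deviation on the chosen scale (>= 0).
#'   May be a vector (one value per temperature) for heteroscedastic
#'   designs.
#' @param seed Integer seed (mandatory).
#' @param physicochem Optional list describing co-variable coupling:
#'   baseline values `ph0`, `acidity0`, `brix0` and coupling rates
#'   `ph_rate`, `acidity_rate`, `brix_rate` applied per unit of lost
#'   retention (a positive acidity_rate makes acidity rise as the
#'   analyte degrades, giving a negative correlation with it).
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(model = c("weibull", "zero", "first"),
                              temperatures_c, params, c0, schedule,
                              replicates = 3L,
                              noise_model = c("additive-retention",
                                              "additive-concentration",
                                              "proportional"),
                              noise_sd = 0.005, seed,
                              physicochem = NULL) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  temperatures_c <- as.numeric(temperatures_c)
  nT <- length(temperatures_c)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is mandatory and must be a single integer",
         call. = FALSE)
  needed <- switch(model, weibull = c("b", "n"), zero = "k1",
                   first = "k2")
  if (!all(needed %in% names(params)))
    stop(sprintf("model '%s' needs params: %s", model,
                 paste(needed, collapse = ", ")), call. = FALSE)
  for (p in needed) {
    v <- as.numeric(params[[p]])
    if (length(v) != nT || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("`params$%s` must be %d positive values", p, nT),
           call. = FALSE)
    params[[p]] <- v
  }
  if (!is.list(schedule) || length(schedule) != nT)
    stop("`schedule` must be a list with one time vector per temperature",
         call. = FALSE)
  if (any(vapply(schedule, function(s) s[1L] != 0, logical(1L))))
    stop("every schedule must start at time 0", call. = FALSE)
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, nT)
  if (length(noise_sd) != nT || any(noise_sd < 0))
    stop("`noise_sd` must be a non-negative scalar or one value per temperature",
         call. = FALSE)
  if (replicates < 1L)
    stop("`replicates` must be >= 1", call. = FALSE)
  if (!is.finite(c0) || c0 <= 0)
    stop("`c0` must be positive", call. = FALSE)
  structure(
    list(model = model, temperatures_c = temperatures_c,
         params = params[needed], c0 = as.numeric(c0),
         schedule = schedule, replicates = as.integer(replicates),
         noise_model = noise_model, noise_sd = noise_sd,
         seed = as.integer(seed), physicochem = physicochem),
    class = "simulation_config")
}

# True mean concentration curve for one temperature of a config.
simulated_mean_curve <- function(config, i, times) {
  p <- config$params
  y <- switch(config$model,
    weibull = exp(-p$b[i] * ifelse(times > 0, times, 0)^p$n[i]),
    first = exp(-p$k2[i] * times),
    zero = pmax(1 - p$k1[i] * times / config$c0, 1e-12))
  config$c0 * y
}

#' Built-in reference study configurations
#'
#' Returns a [simulation_config()] reproducing the accelerated storage
#' design used for two tropical juice matrices: storage at 35 degC for
#' 21 days (sampling every 3 days), 45 degC for 14 days (every 2 days),
#' and 55 degC for 7 days (daily), triplicate measurements, with the
#' Weibull parameters and initial vitamin C concentrations estimated
#' for each matrix (camu camu: C0 = 1090.17 mg/100 mL; naranjilla:
#' C0 = 43.47 mg/100 mL). Default noise is additive on the retention
#' scale with sd 0.005, consistent with the small replicate standard
#' deviations reported for these matrices.
#'
#' @param matrix `"camu_camu"` or `"naranjilla"`.
#' @param noise_sd Noise standard deviation (retention scale).
#' @param seed Integer seed.
#' @param replicates Replicates per sampling point.
#' @return A `simulation_config`.
#' @export
reference_study_config <- function(matrix = c("camu_camu", "naranjilla"),
                                   noise_sd = 0.005, seed = 1L,
                                   replicates = 3L) {
  matrix <- match.arg(matrix)
  pars <- switch(matrix,
    camu_camu = list(b = c(0.07695, 0.1377, 0.16037),
                     n = c(0.36305, 0.22699, 0.30987),
                     c0 = 1090.17),
    naranjilla = list(b = c(0.00804, 0.04493, 0.13250),
                      n = c(0.96644, 0.56064, 0.23923),
                      c0 = 43.47))
  simulation_config(
    model = "weibull",
    temperatures_c = c(35, 45, 55),
    params = list(b = pars$b, n = pars$n),
    c0 = pars$c0,
    schedule = list(seq(0, 21, by = 3), seq(0, 14, by = 2), 0:7),
    replicates = replicates,
    noise_model = "additive-retention",
    noise_sd = noise_sd,
    seed = seed)
}

#' Simulate a degradation study
#'
#' For each temperature and sampling time, evaluates the true mean curve
#' and draws `replicates` noisy measurements under the configured noise
#' model. Concentrations are truncated at a floor of 1e-6 x C0 to
#' preserve positivity. Per-time replicate means and standard deviations
#' populate the returned dataset; the replicate-level long table is
#' attached as attribute `"replicate_data"` (and is what
#' [write_study()] emits by default). Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A [storage_dataset()]. When the config carries a
#'   `physicochem` coupling, a list of [physicochem_series()] is
#'   attached as attribute `"physicochem"`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    floor_c <- 1e-6 * config$c0
    rows <- list(); series <- list(); pchem <- list()
    for (i in seq_along(config$temperatures_c)) {
      times <- config$schedule[[i]]
      mean_c <- simulated_mean_curve(config, i, times)
      reps <- matrix(NA_real_, nrow = length(times),
                     ncol = config$replicates)
      for (j in seq_len(config$replicates)) {
        eps <- stats::rnorm(length(times))
        noisy <- switch(config$noise_model,
          "additive-retention" =
            mean_c + config$noise_sd[i] * config$c0 * eps,
          "additive-concentration" =
            mean_c + config$noise_sd[i] * eps,
          "proportional" =
            mean_c * (1 + config$noise_sd[i] * eps))
        reps[, j] <- pmax(noisy, floor_c)
      }
      conc <- rowMeans(reps)
      rep_sd <- if (config$replicates > 1L) apply(reps, 1L, stats::sd)
                else NULL
      series[[i]] <- degradation_series(
        temperature_c = config$temperatures_c[i],
        times = times, concentrations = conc, replicate_sd = rep_sd)
      rows[[i]] <- data.frame(
        temperature_C = config$temperatures_c[i],
        time_days = rep(times, config$replicates),
        replicate = rep(seq_len(config$replicates),
                        each = length(times)),
        concentration = as.vector(reps))
      if (!is.null(config$physicochem)) {
        pc <- config$physicochem
        lost <- 1 - mean_c / config$c0
        grab <- function(base, rate)
          if (is.null(base)) NULL
          else base + (if (is.null(rate)) 0 else rate) * lost
        pchem[[i]] <- physicochem_series(
          temperature_c = config$temperatures_c[i], times = times,
          ph = grab(pc$ph0, pc$ph_rate),
          acidity = grab(pc$acidity0, pc$acidity_rate),
          brix = grab(pc$brix0, pc$brix_rate))
      }
    }
    out <- storage_dataset(series,
      metadata = list(source = "simulate_study", model = config$model,
                      seed = config$seed))
    attr(out, "replicate_data") <- do.call(rbind, rows)
    if (length(pchem)) attr(out, "physicochem") <- pchem
    out
  })
}

# Truth values implied by a config: per-temperature (b, n), t80, and the
# Ea of the Arrhenius regression through the true b(T).
simulation_truth <- function(config, f = 0.80) {
  stopifnot(config$model == "weibull")
  b <- config$params$b; n <- config$params$n
  t80 <- retention_time(b, n, f)
  arr_b <- fit_arrhenius(config$temperatures_c, b, orientation = "rate")
  arr_t <- fit_arrhenius(config$temperatures_c, t80,
                         orientation = "shelf_life")
  list(b = b, n = n, t80 = t80,
       ea_b = arr_b$ea_kj_mol, ea_t80 = arr_t$ea_kj_mol)
}

#' Parameter-recovery experiment over repeated simulated studies
#'
#' Simulates `n_studies` independent studies from the same
#' configuration (seeds derived deterministically from `seed`), runs the
#' full pipeline on each, and summarizes how well the true Weibull
#' parameters, activation energy, and threshold times are recovered:
#' bias, relative RMSE, median relative absolute error, and whether the
#' min-max envelope across studies covers the truth. Pipeline failures
#' are counted, not fatal.
#'
#' @param config A Weibull [simulation_config()].
#' @param n_studies Number of simulated studies (>= 1).
#' @param seed Integer seed for the experiment.
#' @param f Retention threshold for t80 truth; default 0.80.
#' @return A `recovery_summary`: data frame with one row per recovered
#'   quantity and attribute `n_failures`.
#' @export
recovery_experiment <- function(config, n_studies, seed, f = 0.80) {
  stopifnot(inherits(config, "simulation_config"), n_studies >= 1L)
  truth <- simulation_truth(config, f)
  temps <- config$temperatures_c
  study_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, n_studies))
  ests <- vector("list", n_studies)
  failures <- 0L
  for (s in seq_len(n_studies)) {
    cfg <- config; cfg$seed <- study_seeds[s]
    est <- tryCatch({
      pipe <- run_aslt_pipeline(simulate_study(cfg), f = f)
      if (length(pipe$errors)) stop(names(pipe$errors)[1L])
      list(b = vapply(pipe$weibull_fits, `[[`, numeric(1L), "b"),
           n = vapply(pipe$weibull_fits, `[[`, numeric(1L), "n"),
           t80 = pipe$shelf_life$t_threshold_days,
           ea_b = pipe$arrhenius_b$ea_kj_mol,
           ea_t80 = pipe$arrhenius_t80$arrhenius$ea_kj_mol)
    }, error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else ests[[s]] <- est
  }
  ests <- ests[!vapply(ests, is.null, logical(1L))]
  if (!length(ests))
    stop("all simulated studies failed to fit", call. = FALSE)

  summarize <- function(name, temp, true_value, values) {
    rel <- values / true_value - 1
    data.frame(parameter = name, temperature_c = temp,
               truth = true_value, mean_estimate = mean(values),
               bias = mean(values) - true_value,
               rel_rmse = sqrt(mean(rel^2)),
               median_rel_abs_err = stats::median(abs(rel)),
               covered = min(values) <= true_value &
                         true_value <= max(values))
  }
  rows <- list()
  for (i in seq_along(temps)) {
    rows[[length(rows) + 1L]] <- summarize(
      "b", temps[i], truth$b[i],
      vapply(ests, function(e) e$b[i], numeric(1L)))
    rows[[length(rows) + 1L]] <- summarize(
      "n", temps[i], truth$n[i],
      vapply(ests, function(e) e$n[i], numeric(1L)))
    rows[[length(rows) + 1L]] <- summarize(
      "t80", temps[i], truth$t80[i],
      vapply(ests, function(e) e$t80[i], numeric(1L)))
  }
  rows[[length(rows) + 1L]] <- summarize(
    "ea_b", NA_real_, truth$ea_b,
    vapply(ests, `[[`, numeric(1L), "ea_b"))
  rows[[length(rows) + 1L]] <- summarize(
    "ea_t80", NA_real_, truth$ea_t80,
    vapply(ests, `[[`, numeric(1L), "ea_t80"))
  out <- do.call(rbind, rows)
  attr(out, "n_failures") <- failures
  attr(out, "n_studies") <- n_studies
  class(out) <- c("recovery_summary", "data.frame")
  out
}
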