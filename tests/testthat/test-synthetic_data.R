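test_that("simulation_config validates model parameters and the seed", {
  expect_error(
    simulation_config("weibull", c(35, 45), params = list(b = c(0.1, 0.2)),
                      c0 = 100, schedule = list(0:3, 0:3), seed = 1),
    "needs params")
  expect_error(
    simulation_config("weibull", c(35, 45),
                      params = list(b = 0.1, n = c(0.5, 0.6)),
                      c0 = 100, schedule = list(0:3, 0:3), seed = 1),
    "2 positive values")
  expect_error(
    simulation_config("first", 35, params = list(k2 = 0.1), c0 = 100,
                      schedule = list(1:3), seed = 1),
    "start at time 0")
  expect_error(
    simulation_config("first", 35, params = list(k2 = 0.1), c0 = 100,
                      schedule = list(0:3)),
    "seed")
})

test_that("reference configs carry the published design and parameters", {
  cc <- reference_study_config("camu_camu")
  expect_equal(cc$temperatures_c, c(35, 45, 55))
  expect_equal(cc$params$b, c(0.07695, 0.1377, 0.16037))
  expect_equal(cc$c0, 1090.17)
  expect_equal(lengths(cc$schedule), c(8L, 8L, 8L))
  expect_true(all(vapply(cc$schedule, `[`, numeric(1), 1) == 0))

  na <- reference_study_config("naranjilla")
  expect_equal(na$params$n, c(0.96644, 0.56064, 0.23923))
  expect_equal(na$c0, 43.47)
  expect_error(reference_study_config("papaya"), "arg")
})

test_that("simulation is bit-identical for identical config and seed", {
  cfg <- reference_study_config("camu_camu", noise_sd = 0.01, seed = 99)
  d1 <- simulate_study(cfg); d2 <- simulate_study(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_study(reference_study_config("camu_camu",
                                              noise_sd = 0.01,
                                              seed = 100))
  expect_false(identical(d1$series[[1]]$concentrations,
                         d3$series[[1]]$concentrations))
})

test_that("simulate_study does not disturb the caller's RNG stream", {
  set.seed(1234)
  a <- runif(1)
  set.seed(1234)
  invisible(simulate_study(reference_study_config("camu_camu",
                                                  seed = 5)))
  expect_identical(runif(1), a)
})

test_that("noiseless simulation reproduces the analytic decay curves", {
  cfg <- reference_study_config("camu_camu", noise_sd = 0, seed = 1)
  d <- simulate_study(cfg)
  s35 <- d$series[["35"]]
  expect_equal(s35$concentrations[1], 1090.17)
  # model value at day 21 sits within measurement error of the reported
  # endpoint 863.54 mg/100 mL
  day21 <- s35$concentrations[s35$times == 21]
  expect_equal(day21, 1090.17 * exp(-0.07695 * 21^0.36305),
               tolerance = 1e-12)
  expect_lt(abs(day21 - 863.54), 0.7)
  # retention at t = 0 is exactly 1 before noise
  expect_equal(normalize_retention(s35)$retention[1], 1)

  exp_cfg <- simulation_config(
    "first", 35, params = list(k2 = 0.1), c0 = 100,
    schedule = list(0:7), replicates = 1, noise_sd = 0, seed = 2)
  s <- simulate_study(exp_cfg)$series[[1]]
  expect_equal(s$concentrations, 100 * exp(-0.1 * (0:7)),
               tolerance = 1e-12)
})

test_that("replicate means converge to the true curve as replicates grow", {
  cfg <- reference_study_config("camu_camu", noise_sd = 0.01, seed = 31,
                                replicates = 10000L)
  d <- simulate_study(cfg)
  s <- d$series[["35"]]
  truth <- 1090.17 * exp(-0.07695 * s$times^0.36305)
  se <- 0.01 * 1090.17 / sqrt(10000)
  expect_true(all(abs(s$concentrations - truth) < 3 * se))
})

test_that("noise truncation preserves positivity", {
  cfg <- simulation_config(
    "weibull", 35, params = list(b = 0.5, n = 1), c0 = 1,
    schedule = list(seq(0, 21, 3)), replicates = 5,
    noise_model = "additive-concentration", noise_sd = 2, seed = 11)
  d <- simulate_study(cfg)
  expect_true(all(d$series[[1]]$concentrations > 0))
  expect_true(all(attr(d, "replicate_data")$concentration > 0))
})

test_that("all three noise models produce the requested spread", {
  for (nm in c("additive-retention", "additive-concentration",
               "proportional")) {
    cfg <- simulation_config(
      "weibull", 35, params = list(b = 0.05, n = 0.5), c0 = 200,
      schedule = list(seq(0, 21, 3)), replicates = 500,
      noise_model = nm, noise_sd = 0.01, seed = 13)
    s <- simulate_study(cfg)$series[[1]]
    expected_sd <- switch(nm,
      "additive-retention" = rep(0.01 * 200, length(s$times)),
      "additive-concentration" = rep(0.01, length(s$times)),
      "proportional" = 0.01 * s$concentrations)
    expect_equal(s$replicate_sd, expected_sd, tolerance = 0.15)
  }
})

test_that("simulated studies round-trip through the CSV layer", {
  cfg <- reference_study_config("naranjilla", noise_sd = 0.005,
                                seed = 17)
  d <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(d, path)
  back <- read_study(path)
  for (k in 1:3) {
    expect_equal(back$series[[k]]$concentrations,
                 d$series[[k]]$concentrations, tolerance = 1e-10)
    expect_equal(back$series[[k]]$replicate_sd,
                 d$series[[k]]$replicate_sd, tolerance = 1e-10)
  }
})

test_that("recovery_experiment reports zero bias on noiseless studies", {
  cfg <- reference_study_config("camu_camu", noise_sd = 0, seed = 1)
  rec <- recovery_experiment(cfg, n_studies = 2, seed = 3)
  expect_s3_class(rec, "recovery_summary")
  expect_true(all(abs(rec$bias[rec$parameter %in% c("b", "n")]) < 1e-6))
  expect_true(all(abs(rec$bias[rec$parameter == "ea_b"]) < 1e-3))
  expect_identical(attr(rec, "n_failures"), 0L)
})

test_that("recovery error does not improve when noise doubles", {
  base <- reference_study_config("camu_camu", noise_sd = 0.005)
  loud <- reference_study_config("camu_camu", noise_sd = 0.02)
  r1 <- recovery_experiment(base, n_studies = 15, seed = 7)
  r2 <- recovery_experiment(loud, n_studies = 15, seed = 7)
  e1 <- median(r1$median_rel_abs_err[r1$parameter == "b"])
  e2 <- median(r2$median_rel_abs_err[r2$parameter == "b"])
  expect_gte(e2, e1)
})
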