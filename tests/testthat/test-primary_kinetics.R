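test_that("fit_zero_order recovers exact lines and flags degenerate input", {
  s <- degradation_series(35, 0:5, 100 - 2 * (0:5))
  f <- fit_zero_order(s)
  expect_equal(f$k1, 2, tolerance = 1e-12)
  expect_equal(f$c0, 100, tolerance = 1e-12)
  expect_equal(f$metrics$r2, 1, tolerance = 1e-12)

  const <- degradation_series(35, 0:5, rep(50, 6))
  expect_equal(fit_zero_order(const)$k1, 0, tolerance = 1e-12)

  # reported zero-order regression line, self-generated exactly
  t <- seq(0, 21, by = 3)
  s2 <- degradation_series(35, t, -8.8722 * t + 1024.5)
  f2 <- fit_zero_order(s2)
  expect_equal(f2$slope, -8.8722, tolerance = 1e-9)
  expect_equal(f2$intercept, 1024.5, tolerance = 1e-9)
})

test_that("fit_first_order recovers exact exponentials on the log scale", {
  s <- exponential_series(0.1, times = 0:6)
  f <- fit_first_order(s)
  expect_equal(f$k2, 0.1, tolerance = 1e-12)
  expect_equal(f$metrics$r2, 1, tolerance = 1e-12)
  expect_identical(f$response_scale, "log-concentration")

  const <- degradation_series(35, 0:5, rep(50, 6))
  expect_equal(fit_first_order(const)$k2, 0, tolerance = 1e-12)

  # reported first-order line ln C = 6.9313 - 0.0093 t, self-generated
  t <- seq(0, 21, by = 3)
  s2 <- degradation_series(35, t, exp(6.9313 - 0.0093 * t))
  f2 <- fit_first_order(s2)
  expect_equal(f2$slope, -0.0093, tolerance = 1e-9)
  expect_equal(f2$intercept, 6.9313, tolerance = 1e-9)
})

test_that("linear-fit r2 equals the squared Pearson correlation oracle", {
  set.seed(11)
  for (i in 1:10) {
    t <- 0:7
    conc <- pmax(100 - 5 * t + rnorm(8, sd = 4), 1)
    s <- degradation_series(35, t, conc)
    f0 <- fit_zero_order(s)
    expect_equal(f0$metrics$r2, cor(t, conc)^2, tolerance = 1e-10)
    f1 <- fit_first_order(s)
    expect_equal(f1$metrics$r2, cor(t, log(conc))^2, tolerance = 1e-10)
  }
})

test_that("fit_weibull recovers noiseless parameters and the n = 1 identity", {
  # reference 35 degC parameter pair, noiseless
  s <- weibull_series(0.07695, 0.36305)
  f <- fit_weibull(s)
  expect_equal(f$b, 0.07695, tolerance = 1e-6)
  expect_equal(f$n, 0.36305, tolerance = 1e-6)
  expect_gt(f$metrics$r2, 1 - 1e-10)

  # exp(-t) is the Weibull family member with b = n = 1
  s1 <- degradation_series(35, 0:5, 100 * exp(-(0:5)))
  f1 <- fit_weibull(s1)
  expect_equal(f1$b, 1, tolerance = 1e-6)
  expect_equal(f1$n, 1, tolerance = 1e-6)

  # fitted curve at day 21 vs the measured endpoint retention
  expect_equal(exp(-0.07695 * 21^0.36305), 863.54 / 1090.17,
               tolerance = 0.001)
})

test_that("fit_weibull depends only on retention (scale invariance)", {
  set.seed(21)
  t <- seq(0, 21, by = 3)
  conc <- 1000 * exp(-0.08 * t^0.4) + c(0, rnorm(7, sd = 5))
  s1 <- degradation_series(35, t, conc)
  s2 <- degradation_series(35, t, conc * 123.4)
  f1 <- fit_weibull(s1); f2 <- fit_weibull(s2)
  # equal up to optimizer tolerance: the objective depends only on Y(t)
  expect_equal(f1$b, f2$b, tolerance = 1e-6)
  expect_equal(f1$n, f2$n, tolerance = 1e-6)
})

test_that("Weibull SSE is bounded by the best exponential fit (nesting)", {
  set.seed(31)
  for (i in 1:50) {
    b <- runif(1, 0.01, 0.5); n <- runif(1, 0.2, 1.5)
    t <- seq(0, 21, by = 3)
    y <- exp(-b * t^n) + c(0, rnorm(7, sd = 0.01))
    y <- pmax(y, 1e-4)
    s <- degradation_series(35, t, 500 * y)
    f <- fit_weibull(s)
    ret <- normalize_retention(s)
    sse_w <- sum((ret$retention[-1] -
                    exp(-f$b * ret$times[-1]^f$n))^2)
    sse_e <- best_exponential_sse(ret$times[-1], ret$retention[-1])
    expect_lte(sse_w, sse_e + 1e-10)
  }
})

test_that("noisy parameter recovery stays within 10% median relative error", {
  # per-temperature schedules of the reference design: triplicate
  # measurements with retention noise sd 0.01, fitted on per-time means,
  # 100 series per configuration
  set.seed(41)
  cfgs <- list(list(b = 0.07695, n = 0.36305, t = seq(0, 21, 3)),
               list(b = 0.1377, n = 0.22699, t = seq(0, 14, 2)),
               list(b = 0.16037, n = 0.30987, t = 0:7))
  for (cf in cfgs) {
    rel_b <- rel_n <- numeric(100)
    for (i in 1:100) {
      mu <- exp(-cf$b * cf$t^cf$n)
      reps <- replicate(3, mu + c(0, rnorm(length(cf$t) - 1,
                                           sd = 0.01)))
      s <- degradation_series(35, cf$t,
                              100 * pmax(rowMeans(reps), 1e-4))
      f <- fit_weibull(s)
      rel_b[i] <- abs(f$b / cf$b - 1)
      rel_n[i] <- abs(f$n / cf$n - 1)
    }
    expect_lt(median(rel_b), 0.10)
    expect_lt(median(rel_n), 0.10)
  }
})

test_that("select_primary_model takes the highest r2 with a simplicity tie rule", {
  mk <- function(model, r2) structure(
    list(model = model, metrics = list(r2 = r2)), class = "primary_fit")
  fits <- list(mk("zero", 0.78), mk("first", 0.81), mk("weibull", 0.99))
  expect_identical(select_primary_model(fits)$model, "weibull")

  # the reference 35 degC r2 triple selects the Weibull model
  fits2 <- list(mk("zero", 0.7803), mk("first", 0.8051),
                mk("weibull", 0.9895))
  expect_identical(select_primary_model(fits2)$model, "weibull")

  # exact tie resolves toward the simpler model
  tie <- list(mk("weibull", 0.95), mk("first", 0.95))
  expect_identical(select_primary_model(tie)$model, "first")
  near_tie <- list(mk("first", 0.95), mk("weibull", 0.95 + 5e-5))
  expect_identical(select_primary_model(near_tie)$model, "first")

  expect_error(select_primary_model(list()), "at least one")
})

test_that("metric invariants hold on a representative fit", {
  f <- fit_weibull(weibull_series(0.1, 0.5))
  expect_lte(f$metrics$r2, 1)
  expect_gte(f$metrics$mse, 0)
  expect_equal(f$metrics$rmse, sqrt(f$metrics$mse), tolerance = 1e-12)
})

test_that("increasing series are flagged non-degrading, not fatal", {
  s <- degradation_series(35, 0:4, c(10, 11, 12, 13, 14))
  expect_true(fit_zero_order(s)$non_degrading)
  expect_true(fit_first_order(s)$non_degrading)
})
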