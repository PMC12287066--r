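# analytic magnitude response of a digital (bilinear-transform, prewarped)
# order-n Butterworth low-pass; zero-phase filtering squares the magnitude
butter_gain <- function(f, cutoff, fs, order, zero_phase = TRUE) {
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  g <- 1 / sqrt(1 + ratio^(2 * order))
  if (zero_phase) g^2 else g
}

test_that("low-pass filter passes DC exactly and matches the analytic response", {
  fs <- 120
  t <- (0:(10 * fs - 1)) / fs
  expect_equal(lowpass_filter(rep(7, 600), fs), rep(7, 600), tolerance = 1e-12)

  for (f0 in c(1, 50)) {
    x <- sin(2 * pi * f0 * t)
    y <- lowpass_filter(x, fs, cutoff = 10, order = 2, zero_phase = TRUE)
    measured <- max(abs(y[seq(fs, length(y) - fs)]))
    expected <- butter_gain(f0, 10, fs, 2)
    expect_equal(measured, expected, tolerance = 0.02)
  }
  # contract bounds on the steady-state tone amplitude (edges excluded:
  # reflection padding leaves a short settling stretch at each end)
  mid <- seq(fs, length(t) - fs)
  x1 <- sin(2 * pi * 1 * t)
  expect_gte(max(abs(lowpass_filter(x1, fs)[mid])), 0.99)
  x50 <- sin(2 * pi * 50 * t)
  expect_lte(max(abs(lowpass_filter(x50, fs)[mid])), 0.01)
})

test_that("zero-phase filtering does not displace a symmetric pulse", {
  fs <- 100
  x <- exp(-((1:1000) - 500)^2 / (2 * 15^2))
  y <- lowpass_filter(x, fs, cutoff = 5)
  expect_equal(which.max(y), which.max(x))
  # single-pass filtering lags the pulse
  y1 <- lowpass_filter(x, fs, cutoff = 5, zero_phase = FALSE)
  expect_gt(which.max(y1), which.max(x))
})

test_that("filter is idempotent in the passband", {
  fs <- 100
  t <- (0:2999) / fs
  x <- sin(2 * pi * 0.5 * t) + 0.5 * cos(2 * pi * 1 * t)
  once <- lowpass_filter(x, fs)
  twice <- lowpass_filter(once, fs)
  expect_lt(sqrt(mean((twice - once)^2)) / sqrt(mean(once^2)), 0.01)
})

test_that("filter rejects invalid cutoffs and too-short traces", {
  expect_error(lowpass_filter(rnorm(100), 100, cutoff = 50),
               class = "fipho_parameter_error")
  expect_error(lowpass_filter(rnorm(6), 100, order = 2),
               class = "fipho_parameter_error")
})

test_that("isosbestic regression equals the closed-form least squares", {
  set.seed(11)
  iso <- 1.5 + 0.1 * rnorm(500)
  # identity case
  fit0 <- fit_isosbestic(iso, iso)
  expect_equal(fit0$a, 1, tolerance = 1e-9)
  expect_equal(fit0$b, 0, tolerance = 1e-9)
  expect_equal(max(abs(fit0$residuals)), 0, tolerance = 1e-9)
  # exact affine relation
  fit1 <- fit_isosbestic(2 * iso + 3, iso)
  expect_equal(fit1$a, 2, tolerance = 1e-9)
  expect_equal(fit1$b, 3, tolerance = 1e-9)
  # closed-form oracle on noisy data
  y <- 0.7 * iso + 0.2 + rnorm(500, sd = 0.05)
  fit2 <- fit_isosbestic(y, iso)
  oracle <- ols_closed_form(y, iso)
  expect_equal(fit2$a, unname(oracle["a"]), tolerance = 1e-9)
  expect_equal(fit2$b, unname(oracle["b"]), tolerance = 1e-9)
})

test_that("regression slope on uncorrelated noise is within OLS standard error", {
  set.seed(7)
  n <- 2000
  iso <- 1.5 + 0.1 * rnorm(n)
  y <- 2 + 0.05 * rnorm(n) # independent of iso
  fit <- fit_isosbestic(y, iso)
  se <- 0.05 / (sd(iso) * sqrt(n - 1))
  expect_lt(abs(fit$a), 4 * se)
})

test_that("degenerate regressions are typed errors", {
  expect_error(fit_isosbestic(rnorm(10), rep(1, 10)),
               class = "fipho_validation_error")
  expect_error(fit_isosbestic(rnorm(10), rnorm(9)),
               class = "fipho_parameter_error")
})

test_that("DF/F is exact cancellation, arithmetic identity and scale invariant", {
  fitted <- c(1, 1, 1, 1)
  expect_equal(compute_dff(fitted, fitted), rep(0, 4))
  expect_equal(compute_dff(c(1.1, 1, 1, 1), fitted)[1], 0.1, tolerance = 1e-12)
  set.seed(3)
  f <- 2 + rnorm(200, sd = 0.1)
  base <- 1.8 + 0.05 * rnorm(200)
  for (c_scale in c(0.5, 3, 1000)) {
    expect_equal(compute_dff(c_scale * f, c_scale * base), compute_dff(f, base),
                 tolerance = 1e-12)
  }
})

test_that("DF/F guards against a vanishing baseline, reporting the first index", {
  base <- c(1, 1, 0, 1)
  expect_error(compute_dff(rep(1, 4), base, floor = 1e-6), "sample 3",
               class = "fipho_validation_error")
})

test_that("z-scoring uses the population sd and normalizes exactly", {
  z <- zscore_trace(c(0, 2))
  expect_equal(z$zscore, c(-1, 1)) # population sd = 1
  expect_equal(z$mu, 1)
  expect_equal(z$sigma, 1)

  set.seed(5)
  x <- rnorm(1000, 3, 2)
  zf <- zscore_trace(x)
  expect_lt(abs(mean(zf$zscore)), 1e-9)
  expect_lt(abs(sqrt(mean((zf$zscore - mean(zf$zscore))^2)) - 1), 1e-9)

  expect_error(zscore_trace(rep(1, 10)), class = "fipho_validation_error")
  expect_error(zscore_trace(x, window = c(2000, 3000), time = seq_along(x) / 100),
               class = "fipho_parameter_error")
})

test_that("baseline-window z-scoring applies window statistics to the whole trace", {
  t <- (0:999) / 100
  x <- c(rnorm(500, 0, 1), rnorm(500, 5, 1))
  set.seed(9)
  z <- zscore_trace(x, window = c(0, 4.99), time = t)
  expect_equal(z$mu, mean(x[1:500]))
  expect_equal(length(z$zscore), 1000)
  expect_gt(mean(z$zscore[501:1000]), 2) # post-window shift survives
})

test_that("preprocess_recording processes both sensors against one isosbestic", {
  sim <- simulate_session(small_config(), seed = 21)
  proc <- preprocess_recording(sim$recording)
  expect_named(proc, c("sensor_465", "sensor_565"))
  for (ch in proc) {
    expect_equal(ch$dff, (ch$filtered - ch$fitted) / ch$fitted, tolerance = 1e-12)
    z <- ch$zscore
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  }
  # both channels were fitted against the same filtered isosbestic
  iso <- attr(proc, "isosbestic_filtered")
  g <- glance(proc)
  for (i in 1:2) {
    expect_equal(proc[[i]]$fitted, g$a[i] * iso + g$b[i], tolerance = 1e-9)
  }
})

test_that("preprocessing requires an isosbestic and at least one sensor", {
  t <- (0:199) / 100
  only_iso <- ph_recording(t, list(isosbestic_405 = rnorm(200, 1.5)))
  expect_error(preprocess_recording(only_iso), class = "fipho_validation_error")
  no_iso <- ph_recording(t, list(sensor_465 = rnorm(200, 2)))
  expect_error(preprocess_recording(no_iso), class = "fipho_validation_error")
})

test_that("isosbestic regression removes a shared motion artifact", {
  sim <- simulate_session(small_config(artifact_sd = 0.08), seed = 33)
  proc <- preprocess_recording(sim$recording)
  artifact <- sim$ground_truth$artifact
  expect_gt(abs(cor(sim$recording$sensor_465, artifact)), 0.5)
  expect_lt(abs(cor(proc$sensor_465$dff, artifact)), 0.1)
})

test_that("the pipeline is deterministic for identical input and config", {
  sim <- simulate_session(small_config(), seed = 4)
  p1 <- preprocess_recording(sim$recording)
  p2 <- preprocess_recording(sim$recording)
  expect_identical(p1$sensor_465$zscore, p2$sensor_465$zscore)
})
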