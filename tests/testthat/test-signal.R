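test_that("the envelope chain passes its analytic oracles", {
  fs <- 1000
  t <- seq(1 / fs, 10, 1 / fs)
  mid <- (2 * fs):(8 * fs)
  # a 50 Hz carrier is passed: steady-state envelope near the rectified
  # mean 2/pi
  e50 <- emg_envelope(sin(2 * pi * 50 * t), fs)
  expect_equal(mean(e50[mid]), 2 / pi, tolerance = 0.02)
  # DC is removed by the high-pass
  edc <- emg_envelope(rep(1, length(t)), fs)
  expect_lt(max(abs(edc[mid])), 1e-3)
  # a 1 Hz tone (1/20 of the high-pass cutoff) is strongly attenuated
  e1 <- emg_envelope(sin(2 * pi * t), fs)
  expect_lt(max(abs(e1[mid])), 0.01)
})

test_that("the envelope operator is positively homogeneous", {
  fs <- 1000
  withr::with_seed(51L, x <- rnorm(6000))
  for (a in c(0.5, 3, 20)) {
    expect_equal(emg_envelope(a * x, fs), a * emg_envelope(x, fs),
                 tolerance = 1e-10)
  }
})

test_that("envelope input validation and causal mode behave", {
  expect_error(emg_envelope(rnorm(100), fs = 1000), "too short")
  expect_error(emg_envelope(rnorm(1000), fs = 30))
  fs <- 1000
  t <- seq(1 / fs, 5, 1 / fs)
  ec <- emg_envelope(sin(2 * pi * 50 * t), fs, causal = TRUE)
  # single-pass attenuation is milder but still near the rectified mean
  expect_equal(mean(ec[(2 * fs):(4 * fs)]), 2 / pi, tolerance = 0.05)
  eclamped <- emg_envelope(sin(2 * pi * 50 * t), fs, clamp = TRUE)
  expect_true(all(eclamped >= 0))
})

test_that("calibration regression recovers a known line", {
  withr::with_seed(52L, env <- runif(500))
  m <- suppressWarnings(fit_calibration(env, 3 * env + 0.1))
  expect_equal(m$slope, 3, tolerance = 1e-10)
  expect_equal(m$intercept, 0.1, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_calibration(rep(0.2, 500), rnorm(500)), "zero variance")
  expect_error(fit_calibration(runif(50), runif(50)), "at least 100")
  expect_error(fit_calibration(runif(200), runif(100)), "equal length")
})

test_that("noisy calibration slopes stay within 3 SE of truth", {
  withr::with_seed(53L, {
    hits <- replicate(200, {
      env <- runif(300)
      tq <- 2.5 * env + 0.05 + rnorm(300, 0, 0.1)
      fit <- lm(tq ~ env)
      se <- summary(fit)$coefficients[2, 2]
      m <- fit_calibration(env, tq)
      abs(m$slope - 2.5) <= 3 * se
    })
  })
  expect_gt(mean(hits), 0.99)
})

test_that("torque reconstruction applies the calibration per channel", {
  n <- 2000
  withr::with_seed(54L, {
    emg <- tibble::tibble(
      time_s = seq_len(n) / 1000,
      emg_lf_v = runif(n), emg_le_v = runif(n),
      emg_rf_v = runif(n), emg_re_v = runif(n))
  })
  identity_models <- tibble::tibble(
    muscle = c("left_flexor", "left_extensor", "right_flexor",
               "right_extensor"),
    slope = 1, intercept = 0)
  rec <- reconstruct_torques(emg, identity_models, envelope = FALSE)
  expect_equal(rec$tau_lf_nm, emg$emg_lf_v)
  expect_equal(rec$tau_re_nm, emg$emg_re_v)
  zero <- dplyr::mutate(emg, dplyr::across(-time_s, ~0))
  expect_true(all(reconstruct_torques(zero, identity_models,
                                      envelope = FALSE)$tau_lf_nm == 0))
  expect_error(reconstruct_torques(emg[, -2], identity_models), "missing")
  expect_error(reconstruct_torques(emg, identity_models[-1, ]), "missing")
})

test_that("calibration then reconstruction is the identity on fitted values", {
  withr::with_seed(55L, {
    env <- runif(300)
    tq <- 1.7 * env + 0.02 + rnorm(300, 0, 0.05)
  })
  m <- fit_calibration(env, tq)
  expect_equal(m$slope * env + m$intercept,
               unname(fitted(lm(tq ~ env))), tolerance = 1e-12)
})

test_that("EMG-derived torques track the commanded ground truth", {
  p <- default_profile()
  cfg <- cohort_config(sensor_noise_sd = 0, noise_base = 0,
                       motor_noise_l = 0, motor_noise_r = 0,
                       motor_noise_sd = 0)
  cal <- simulate_isometric_calibration(p, cfg, seed = 56L)
  models <- calibrate_muscles(cal)
  tr <- simulate_trial(p, "center", "medium_hard", 0, cfg, seed = 57L)
  rec <- reconstruct_torques(tr$emg, models)
  i <- tr$torques$time_s > 1
  for (cn in c("tau_lf_nm", "tau_le_nm", "tau_rf_nm", "tau_re_nm")) {
    rel <- sqrt(mean((rec[[cn]][i] - tr$torques[[cn]][i])^2)) /
      mean(abs(tr$torques[[cn]][i]))
    # residual carrier ripple and filter lag bound the agreement
    expect_lt(rel, 0.15)
  }
})
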