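test_that("participant profiles are reproducible and validated", {
  cfg <- cohort_config()
  withr::with_seed(9L, p1 <- generate_participant(cfg))
  withr::with_seed(9L, p2 <- generate_participant(cfg))
  expect_identical(p1, p2)
  expect_gt(p1$lq, 70)
  expect_error(cohort_config(atypical_prob = 1.2), "probability")
  expect_error(cohort_config(noise_base = -1), "non-negative")
  # degenerate draw: probability 0 gives an all-typical cohort
  withr::with_seed(10L, {
    ph <- replicate(50,
      generate_participant(cohort_config(atypical_prob = 0))$phenotype)
  })
  expect_true(all(ph == "typical"))
})

test_that("atypical phenotype frequency matches its binomial rate", {
  p <- 4 / 18
  cfg <- cohort_config(atypical_prob = p)
  withr::with_seed(11L, {
    ph <- replicate(4000, generate_participant(cfg)$phenotype)
  })
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(ph == "atypical") - p), 3 * se)
})

test_that("simulated trials carry the protocol's grids and are seeded", {
  p <- default_profile()
  tr <- simulate_trial(p, "center", "compliant", t0 = 4.156, seed = 31L)
  expect_identical(nrow(tr$angles), 2500L)
  expect_identical(nrow(tr$emg), 25000L)
  expect_identical(nrow(tr$torques), 25000L)
  tr2 <- simulate_trial(p, "center", "compliant", t0 = 4.156, seed = 31L)
  expect_identical(tr, tr2)
  # rigid bar: hands identical sample for sample, all weightings alike
  trr <- simulate_trial(p, "left", "rigid", t0 = 0, seed = 32L)
  expect_identical(trr$angles$q_l_deg, trr$angles$q_r_deg)
})

test_that("the wrist plant flags unstable integrations", {
  p <- default_profile()
  p$kp_l <- -60  # positive feedback blows the left plant up
  expect_error(simulate_trial(p, "left", "not_connected", seed = 33L),
               class = "bt_unstable")
})

test_that("noise-free control tracks better than the default noise level", {
  p <- default_profile()
  quiet <- cohort_config(noise_base = 0, motor_noise_l = 0,
                         motor_noise_r = 0, motor_noise_sd = 0,
                         sensor_noise_sd = 0)
  hi <- p
  hi$kp_l <- 4 * p$kp_l; hi$kp_r <- 4 * p$kp_r
  hi$kd_l <- 2 * p$kd_l; hi$kd_r <- 2 * p$kd_r
  m0 <- trial_metrics(simulate_trial(hi, "center", "not_connected", 0,
                                     quiet, seed = 34L, emg = FALSE))
  noisy <- sapply(1:7, function(s) {
    trial_metrics(simulate_trial(p, "center", "not_connected", 0,
                                 seed = 34L + s, emg = FALSE))$rms_error
  })
  expect_lt(m0$rms_error, median(noisy))
})

test_that("isometric calibration covers the task range and recovers gains", {
  p <- default_profile()
  noiseless <- cohort_config(sensor_noise_sd = 0)
  cal <- simulate_isometric_calibration(p, noiseless, seed = 35L)
  expect_setequal(unique(cal$muscle),
                  c("left_flexor", "left_extensor", "right_flexor",
                    "right_extensor"))
  models <- calibrate_muscles(cal)
  truth <- c(left_flexor = p$gain_lf, left_extensor = p$gain_le,
             right_flexor = p$gain_rf, right_extensor = p$gain_re)
  rel <- abs(1 / models$slope - truth[models$muscle]) / truth[models$muscle]
  expect_lt(max(rel), 1e-10)
  # default sensor noise: gain recovered within 5% over repeated recordings
  withr::with_seed(36L, {
    errs <- replicate(40, {
      cal <- simulate_isometric_calibration(p)
      m <- calibrate_muscles(cal)
      max(abs(1 / m$slope - truth[m$muscle]) / truth[m$muscle])
    })
  })
  expect_lt(max(errs), 0.05)
})

test_that("experiment protocols produce the printed trial structure", {
  m1 <- generate_cohort("experiment1", seed = 21L, simulate = FALSE)
  expect_identical(nrow(m1$participants), 18L)
  expect_identical(nrow(m1$trials), 1080L)
  counts <- dplyr::count(cohort_manifest(m1), participant, weighting,
                         connection)
  expect_true(all(counts$n == 10L))
  expect_identical(nrow(counts), 18L * 6L)
  expect_setequal(unique(m1$trials$connection),
                  c("not_connected", "medium_hard"))
  # connection order counterbalanced across the two sequences
  expect_setequal(unique(m1$participants$sequence), c("A", "B"))

  m2 <- generate_cohort("experiment2", seed = 22L, simulate = FALSE)
  expect_identical(nrow(m2$participants), 40L)
  expect_identical(nrow(m2$trials), 1200L)
  per_part <- dplyr::count(cohort_manifest(m2), participant)
  expect_true(all(per_part$n == 30L))
  expect_identical(
    sort(unique(cohort_manifest(m2)$group)), sort(connection_levels()))
  # one connection level per participant
  cpp <- dplyr::distinct(cohort_manifest(m2), participant, connection)
  expect_identical(nrow(cpp), 40L)
  # all start times are admissible target zeros
  expect_true(all(abs(sapply(m2$trials$t0, function(t0)
    target_position(0, t0))) < 1e-6))
})

test_that("cohorts are byte-identical under a fixed master seed", {
  a <- generate_cohort("experiment1", cohort_config(atypical_prob = 0),
                       seed = 23L, n = 2, emg = FALSE)
  b <- generate_cohort("experiment1", cohort_config(atypical_prob = 0),
                       seed = 23L, n = 2, emg = FALSE)
  expect_identical(cohort_manifest(a), cohort_manifest(b))
  expect_identical(a$trials$trial[[7]], b$trials$trial[[7]])
  expect_error(generate_cohort("experiment1", seed = 1, n = 1), "At least 2")
})

test_that("imbalance cohorts realise the requested linear structure", {
  withr::with_seed(24L, {
    d <- simulate_imbalance_cohort(500, slope = -0.15, intercept = 0.05,
                                   sd_subject = 0, sd_resid = 1e-12)
  })
  fit <- lm(imbalance ~ weighting_code, d)
  expect_equal(unname(coef(fit)), c(0.05, -0.15), tolerance = 1e-9)
  expect_identical(nrow(d), 1500L)
})
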