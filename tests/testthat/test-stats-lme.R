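test_that("weighting codes are symmetric around center", {
  expect_identical(code_weighting(c("left", "center", "right")),
                   c(-1, 0, 1))
  expect_error(code_weighting("middle"), "Unknown")
})

test_that("noise-free data are recovered exactly", {
  d <- tidyr::crossing(participant = sprintf("P%02d", 1:8),
                       x = c(-1, 0, 1))
  offs <- seq(-0.2, 0.15, length.out = 8)
  offs <- offs - mean(offs)  # centered so the intercept is identifiable
  d$y <- 0.4 * d$x - 0.07 + offs[match(d$participant,
                                       sprintf("P%02d", 1:8))]
  m <- suppressWarnings(suppressMessages(
    lme_slope(d, "y", "x", "participant")))
  expect_equal(m$slope, 0.4, tolerance = 1e-8)
  expect_equal(m$intercept, -0.07, tolerance = 1e-8)
})

test_that("the model is shift- and scale-equivariant", {
  withr::with_seed(81L, d <- simulate_imbalance_cohort(12))
  m0 <- lme_slope(d, "imbalance", "weighting_code", "participant")
  d$shift <- d$imbalance + 5
  m1 <- lme_slope(d, "shift", "weighting_code", "participant")
  expect_equal(m1$slope, m0$slope, tolerance = 1e-6)
  expect_equal(m1$intercept, m0$intercept + 5, tolerance = 1e-6)
  d$scaled <- 3 * d$imbalance
  m2 <- lme_slope(d, "scaled", "weighting_code", "participant")
  expect_equal(m2$slope, 3 * m0$slope, tolerance = 1e-6)
  expect_equal(m2$intercept, 3 * m0$intercept, tolerance = 1e-6)
})

test_that("one observation per subject falls back to ordinary regression", {
  withr::with_seed(82L, {
    d <- data.frame(participant = sprintf("P%02d", 1:20),
                    x = rnorm(20))
    d$y <- 0.3 * d$x + rnorm(20, 0, 0.2)
  })
  expect_warning(m <- lme_slope(d, "y", "x", "participant"),
                 "falling back")
  expect_identical(m$df_method, "residual")
  expect_equal(m$slope, unname(coef(lm(y ~ x, d))[2]), tolerance = 1e-12)
})

test_that("tidy and glance expose the fixed effects and fit metadata", {
  withr::with_seed(83L, d <- simulate_imbalance_cohort(15))
  m <- lme_slope(d, "imbalance", "weighting_code", "participant")
  td <- tidy(m, conf.int = TRUE)
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(all(c("estimate", "std.error", "df", "statistic", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$df > 0))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(m)
  expect_identical(gl$n_obs, 45L)
  expect_identical(gl$n_subjects, 15L)
  expect_identical(gl$df_method, "satterthwaite_approx")
})

test_that("trial trends distinguish plateaued from improving blocks", {
  base <- tidyr::crossing(participant = sprintf("P%02d", 1:15),
                          trial_index = 1:10)
  withr::with_seed(84L, {
    plateau_p <- replicate(20, {
      d <- base
      d$rms_error <- 2 + rnorm(15, 0, 0.3)[match(d$participant,
                                                 unique(d$participant))] +
        rnorm(nrow(d), 0, 0.2)
      trial_trend(d, "rms_error", "last5")$slope_p
    })
  })
  expect_gte(mean(plateau_p > 0.05), 0.9)
  withr::with_seed(85L, {
    d <- base
    d$rms_error <- 3 - 0.2 * d$trial_index + rnorm(nrow(d), 0, 0.1)
  })
  m <- trial_trend(d, "rms_error", "first5")
  expect_lt(m$slope, 0)
  expect_lt(m$slope_p, 0.001)
  # constant response: slope exactly zero via the ordinary-regression route
  d$rms_error <- 1.5
  m0 <- suppressWarnings(trial_trend(d, "rms_error", "first5"))
  expect_identical(m0$slope, 0)
})

test_that("per-connection imbalance slopes are fitted separately", {
  withr::with_seed(86L, {
    d <- dplyr::bind_rows(
      dplyr::mutate(simulate_imbalance_cohort(10, slope = -0.15),
                    connection = "not_connected"),
      dplyr::mutate(simulate_imbalance_cohort(10, slope = 0),
                    connection = "rigid"))
  })
  res <- suppressWarnings(imbalance_slopes(d, "imbalance"))
  expect_identical(sort(res$connection), c("not_connected", "rigid"))
  expect_true(all(c("slope", "slope_t", "slope_df", "slope_p",
                    "intercept", "df_method") %in% names(res)))
})

test_that("the normality screen is calibrated and flags degenerate cells", {
  screen_one <- function(v) {
    shapiro_screen(data.frame(g = "a", v = v), "v", "g")$p_raw
  }
  withr::with_seed(87L, {
    rej_norm <- mean(replicate(500, screen_one(rnorm(50)) < 0.05))
    rej_exp <- mean(replicate(150, screen_one(rexp(50)) < 0.05))
  })
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rej_norm - 0.05), 3 * se)
  expect_gt(rej_exp, 0.5)
  d <- data.frame(g = rep(c("a", "b"), each = 10), v = rnorm(20))
  out <- shapiro_screen(d, "v", "g")
  expect_identical(nrow(out), 2L)
  expect_true(all(out$statistic_name == "W_shapiro"))
  expect_error(shapiro_screen(data.frame(g = "a", v = 1:2), "v", "g"),
               "3-5000")
  expect_error(shapiro_screen(data.frame(g = "a", v = rep(1, 10)), "v", "g"),
               "constant")
})
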