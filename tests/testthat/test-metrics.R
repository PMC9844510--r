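test_that("normalized arc length is the ratio of path lengths", {
  t <- seq(0, 24, by = 0.01)
  q <- target_position(t, 0)
  expect_equal(normalized_arc_length(q, q), 1)
  expect_equal(normalized_arc_length(rep(3, length(q)), q), 0)
  expect_equal(normalized_arc_length(2 * q, q), 2)
  expect_error(normalized_arc_length(q, rep(1, length(q))), "Constant target")
})

test_that("RA/CC decompose antagonist torques as max-minus-min and min", {
  expect_equal(reciprocal_activation(1.5, 0.5)$series, 1.0)
  expect_equal(reciprocal_activation(0.5, 0.5)$series, 0)
  expect_equal(reciprocal_activation(-2.0, 0.5)$series, 1.5)
  expect_equal(co_contraction(1.5, 0.5)$series, 0.5)
  expect_equal(co_contraction(0, 3)$series, 0)
  # the trial scalar is the time mean
  tf <- c(1, 2, 3); te <- c(0.5, 2.5, 1)
  expect_equal(reciprocal_activation(tf, te)$mean,
               mean(pmax(abs(tf), abs(te)) - pmin(abs(tf), abs(te))))
})

test_that("u_ra + 2 u_cc recovers |tau_f| + |tau_e| pointwise", {
  withr::with_seed(61L, {
    tf <- rnorm(1e6, 0, 2)
    te <- rnorm(1e6, 0, 2)
  })
  lhs <- reciprocal_activation(tf, te)$series +
    2 * co_contraction(tf, te)$series
  expect_lt(max(abs(lhs - (abs(tf) + abs(te)))), 1e-12)
})

test_that("RMS error matches its closed forms", {
  t <- seq(0, 24, by = 0.01)
  q <- target_position(t, 3)
  expect_equal(rms_error(q, q), 0)
  expect_equal(rms_error(q + 1.7, q), 1.7)
  # sinusoidal disturbance over whole periods: RMS = A / sqrt(2)
  tt <- seq(0, 2, length.out = 2001)[-2001]
  expect_equal(rms_error(q[1:2000] + 0.8 * sin(2 * pi * tt), q[1:2000]),
               0.8 / sqrt(2), tolerance = 1e-6)
})

test_that("hand correlation is a Spearman rank correlation", {
  withr::with_seed(62L, x <- rnorm(500))
  expect_identical(hand_correlation(x, x), 1)
  expect_equal(hand_correlation(x, -x), -1, tolerance = 1e-12)
  # invariant under monotone transforms
  expect_equal(hand_correlation(x, exp(x)), 1, tolerance = 1e-12)
  expect_warning(r <- hand_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(r))
})

test_that("trial metrics trim the first second on both grids", {
  tr <- small_exp1_cohort()$trials$trial[[1]]
  m <- trial_metrics(tr)
  expect_identical(nrow(m), 1L)
  # 1 s at 100 Hz leaves 2400 angle samples in the analysis window
  expect_identical(sum(tr$angles$time_s > 1 + 1e-9), 2400L)
  expect_identical(sum(tr$torques$time_s > 1 + 1e-9), 24000L)
  # imbalances are exactly left minus right
  expect_identical(m$nal_imb, m$nal_l - m$nal_r)
  expect_identical(m$ra_imb, m$ra_l - m$ra_r)
  expect_identical(m$cc_imb, m$cc_l - m$cc_r)
})

test_that("swapping hand labels negates imbalances and keeps error and |rho|", {
  co <- small_exp1_cohort()
  tr <- co$trials$trial[[which(co$trials$weighting == "center")[1]]]
  swapped <- tr
  swapped$angles$q_l_deg <- tr$angles$q_r_deg
  swapped$angles$q_r_deg <- tr$angles$q_l_deg
  swapped$torques$tau_lf_nm <- tr$torques$tau_rf_nm
  swapped$torques$tau_le_nm <- tr$torques$tau_re_nm
  swapped$torques$tau_rf_nm <- tr$torques$tau_lf_nm
  swapped$torques$tau_re_nm <- tr$torques$tau_le_nm
  stopifnot(tr$weighting == "center")  # symmetric cursor mapping
  m1 <- trial_metrics(tr)
  m2 <- trial_metrics(swapped)
  expect_equal(m2$nal_imb, -m1$nal_imb)
  expect_equal(m2$ra_imb, -m1$ra_imb)
  expect_equal(m2$cc_imb, -m1$cc_imb)
  expect_equal(m2$rms_error, m1$rms_error)
  expect_equal(abs(m2$rho), abs(m1$rho))
})

test_that("averaging the hands cannot increase arc length", {
  withr::with_seed(63L, {
    for (i in 1:10) {
      t <- seq(0, 24, by = 0.01)
      ql <- target_position(t, 2) + cumsum(rnorm(length(t), 0, 0.05))
      qr <- target_position(t, 2) + cumsum(rnorm(length(t), 0, 0.05))
      qt <- target_position(t, 2)
      nal_c <- normalized_arc_length((ql + qr) / 2, qt)
      expect_lte(nal_c, (normalized_arc_length(ql, qt) +
                           normalized_arc_length(qr, qt)) / 2 + 1e-12)
    }
  })
})

test_that("aggregation keeps the last five trials and needs full blocks", {
  met <- compute_metrics(small_exp1_cohort(), use_emg = FALSE)
  agg <- trim_and_aggregate(met)
  expect_identical(nrow(agg), 2L * 6L)
  # hand-check one cell against the raw trials
  cell <- met[met$participant == met$participant[1] &
                met$weighting == met$weighting[1] &
                met$connection == met$connection[1] &
                met$trial_index >= 6, ]
  row <- agg[agg$participant == met$participant[1] &
               agg$weighting == met$weighting[1] &
               agg$connection == met$connection[1], ]
  expect_equal(row$rms_error, mean(cell$rms_error))
  expect_equal(row$nal_imb, mean(cell$nal_imb))
  # idempotent on constant blocks
  const <- met
  for (cn in c("rms_error", "nal_l")) const[[cn]] <- 1.25
  aggc <- trim_and_aggregate(const)
  expect_true(all(aggc$rms_error == 1.25))
  expect_error(trim_and_aggregate(met[met$trial_index <= 9, ]),
               "Incomplete block")
})

test_that("per-hand long format pairs each metric with a hand factor", {
  met <- compute_metrics(small_exp1_cohort(), use_emg = FALSE)
  long <- metrics_by_hand(trim_and_aggregate(met))
  expect_setequal(unique(long$hand), c("left", "right"))
  expect_identical(nrow(long), 2L * nrow(trim_and_aggregate(met)))
  expect_true(all(c("nal", "ra", "cc") %in% names(long)))
})
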