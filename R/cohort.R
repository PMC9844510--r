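# Synthetic two-wrist cohorts: participant profiles, trial simulation with
# EMG synthesis, isometric calibration recordings, and the block/condition
# structure of the two experiments (six within-subject conditions for
# experiment 1; four stiffness groups x three cursor weightings for
# experiment 2).

#' Cohort simulator configuration
#'
#' Collects every free parameter of the synthetic cohort in one list.
#' Protocol constants (trial count per block, sampling rates, durations,
#' stiffness levels) are fixed by the task; the remaining values are the
#' simulator's documented defaults: a right-handed population (laterality
#' quotient > 70, noisier nondominant left hand), proportional-derivative
#' tracking with signal-dependent motor noise, tonic co-contraction, and
#' per-muscle EMG gains with additive sensor noise.
#'
#' @param n_participants Participants for experiment 1 (default 18).
#' @param n_per_group Participants per stiffness group for experiment 2
#'   (default 10).
#' @param atypical_prob Probability that a participant moves both hands even
#'   when only one can affect the cursor (default 4/18).
#' @param lq_mean,lq_sd Laterality-quotient distribution, truncated to
#'   (70, 100].
#' @param motor_noise_l,motor_noise_r Mean signal-dependent noise
#'   multipliers per hand (dimensionless; left >= right by default).
#' @param motor_noise_sd Between-participant SD of the multipliers.
#' @param noise_base Signal-independent torque noise floor, Nm.
#' @param cc_mean,cc_sd Tonic co-contraction torque distribution, Nm.
#' @param kp_mean,kp_sd Proportional gain distribution, Nm/rad.
#' @param kd_mean,kd_sd Derivative gain distribution, Nm s/rad.
#' @param effort_share_mean,effort_share_sd Preferred left-hand share of the
#'   total corrective command, in (0, 1).
#' @param emg_gain_meanlog,emg_gain_sdlog Log-normal per-muscle EMG gain,
#'   V/Nm.
#' @param sensor_noise_sd Additive EMG sensor noise SD, volts.
#' @param inertia,viscosity Wrist plant inertia (kg m^2) and viscosity
#'   (Nm s/rad).
#' @param coupling_damping Parallel damping of the virtual spring, Nm s/rad.
#' @param ramp_trials Optional early-block ramp-down (in trials) of the
#'   task-irrelevant hand's command for typical participants; 0 disables it
#'   and is the default (steady-state behavior).
#' @param calib_levels,calib_level_duration,calib_max_torque Isometric
#'   calibration staircase: number of torque levels, seconds per level, and
#'   peak torque (Nm).
#' @return A named list of class `bt_config`.
#' @export
cohort_config <- function(n_participants = 18,
                          n_per_group = 10,
                          atypical_prob = 4 / 18,
                          lq_mean = 98, lq_sd = 6,
                          motor_noise_l = 0.10, motor_noise_r = 0.07,
                          motor_noise_sd = 0.02,
                          noise_base = 0.002,
                          cc_mean = 0.10, cc_sd = 0.03,
                          kp_mean = 2.0, kp_sd = 0.3,
                          kd_mean = 0.15, kd_sd = 0.02,
                          effort_share_mean = 0.5, effort_share_sd = 0.05,
                          emg_gain_meanlog = 0, emg_gain_sdlog = 0.3,
                          sensor_noise_sd = 0.005,
                          inertia = 0.003, viscosity = 0.02,
                          coupling_damping = 0.05,
                          ramp_trials = 0,
                          calib_levels = 10,
                          calib_level_duration = 2,
                          calib_max_torque = 0.5) {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$atypical_prob) || cfg$atypical_prob < 0 ||
      cfg$atypical_prob > 1) {
    abort("`atypical_prob` must be a probability in [0, 1].")
  }
  for (nm in c("motor_noise_l", "motor_noise_r", "motor_noise_sd",
               "noise_base", "sensor_noise_sd", "cc_mean")) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be non-negative.", nm))
  }
  structure(cfg, class = "bt_config")
}

# one truncated-normal draw per element via inverse-CDF (no rejection loop,
# so the RNG stream advances by exactly n)
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  stats::qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic participant profile
#'
#' Draws one participant from the cohort configuration's distributions using
#' R's random number stream (seed with `set.seed()` or let
#' [generate_cohort()] manage seeding). The left (nondominant) hand is on
#' average noisier than the right.
#'
#' @param config A [cohort_config()] list.
#' @param id Participant identifier token.
#' @return A one-row tibble: id, laterality quotient, phenotype, per-hand
#'   noise multipliers, tonic co-contraction, controller gains, preferred
#'   left effort share, and per-muscle EMG gains.
#' @export
generate_participant <- function(config = cohort_config(), id = "P01") {
  stopifnot(inherits(config, "bt_config"))
  tibble::tibble(
    id = id,
    lq = .rtruncnorm(1, config$lq_mean, config$lq_sd, 70, 100),
    phenotype = if (runif(1) < config$atypical_prob) "atypical" else "typical",
    motor_noise_l = .rtruncnorm(1, config$motor_noise_l,
                                config$motor_noise_sd, 0.01, Inf),
    motor_noise_r = .rtruncnorm(1, config$motor_noise_r,
                                config$motor_noise_sd, 0.01, Inf),
    cc_baseline_l = .rtruncnorm(1, config$cc_mean, config$cc_sd, 0.02, Inf),
    cc_baseline_r = .rtruncnorm(1, config$cc_mean, config$cc_sd, 0.02, Inf),
    kp_l = .rtruncnorm(1, config$kp_mean, config$kp_sd, 0.8, Inf),
    kd_l = .rtruncnorm(1, config$kd_mean, config$kd_sd, 0.05, Inf),
    kp_r = .rtruncnorm(1, config$kp_mean, config$kp_sd, 0.8, Inf),
    kd_r = .rtruncnorm(1, config$kd_mean, config$kd_sd, 0.05, Inf),
    effort_share = .rtruncnorm(1, config$effort_share_mean,
                               config$effort_share_sd, 0.2, 0.8),
    gain_lf = stats::rlnorm(1, config$emg_gain_meanlog, config$emg_gain_sdlog),
    gain_le = stats::rlnorm(1, config$emg_gain_meanlog, config$emg_gain_sdlog),
    gain_rf = stats::rlnorm(1, config$emg_gain_meanlog, config$emg_gain_sdlog),
    gain_re = stats::rlnorm(1, config$emg_gain_meanlog, config$emg_gain_sdlog)
  )
}

# band-limited carrier, normalized by its own envelope so an
# amplitude-modulated copy reproduces the modulation after envelope
# extraction
.emg_carrier <- function(n, fs) {
  bp <- signal::butter(2, c(30, 300) / (fs / 2), type = "pass")
  carrier <- .filtfilt_pad(bp, rnorm(n), ceiling(0.1 * fs))
  env <- emg_envelope(carrier, fs)
  carrier / pmax(env, 0.25 * median(env))
}

#' Simulate one 25-s tracking trial
#'
#' Integrates two second-order wrist plants (inertia, viscosity) at 1000 Hz
#' (semi-implicit Euler), driven by per-hand proportional-derivative
#' feedback on cursor-target error split by the participant's preferred
#' effort share, with signal-dependent Gaussian torque noise and the
#' condition's coupling torque. Typical participants zero the command to a
#' hand whose motion cannot affect the cursor (uncoupled unequal
#' weighting); atypical participants mirror the task-relevant hand's
#' command instead. The rigid bar is the kinematic constraint
#' `q_l == q_r` on a single plant with summed inertias.
#'
#' EMG is synthesized per muscle as gain x activation (positive part of the
#' commanded net torque for the flexor, negative part for the extensor,
#' plus the tonic co-contraction baseline on both) amplitude-modulating a
#' band-limited 30-300 Hz carrier, plus additive sensor noise - so the
#' 20 Hz / 5 Hz envelope chain is genuinely exercised downstream.
#'
#' @param profile One-row tibble from [generate_participant()].
#' @param weighting Cursor weighting token.
#' @param connection Connection token.
#' @param t0 Trial start offset, seconds (see [sample_start_time()]).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed for this trial.
#' @param trial_index Trial number within its block (1-10), carried as
#'   metadata.
#' @param irrelevant_scale Scaling of the task-irrelevant hand's command for
#'   typical participants in uncoupled unequal-weighting trials (used by the
#'   optional early-block exploration ramp; 0, the default, means the
#'   irrelevant hand receives no command).
#' @return A `bt_trial` object: `$angles` (100 Hz tibble: `time_s`,
#'   `q_l_deg`, `q_r_deg`, `q_target_deg`), `$emg` (1000 Hz tibble with the
#'   four channels `emg_lf_v`, `emg_le_v`, `emg_rf_v`, `emg_re_v`),
#'   `$torques` (1000 Hz ground-truth commanded muscle torques), and the
#'   trial metadata.
#' @export
simulate_trial <- function(profile, weighting, connection, t0 = 0,
                           config = cohort_config(), seed = NULL,
                           trial_index = NA_integer_,
                           irrelevant_scale = 0, emg = TRUE) {
  stopifnot(weighting %in% cursor_weightings(),
            connection %in% connection_levels())
  if (!is.null(seed)) set.seed(seed)

  fs <- 1000L
  dt <- 1 / fs
  n <- fs * trial_duration()
  t_emg <- dt * seq_len(n)
  d2r <- pi / 180

  qt <- target_position(t_emg, t0) * d2r
  qdt <- target_velocity(t_emg, t0) * d2r

  coupled <- connection != "not_connected"
  share_l <- 2 * profile$effort_share
  share_r <- 2 * (1 - profile$effort_share)
  mirror <- 0L
  if (!coupled && weighting != "center") {
    if (weighting == "left") {
      share_l <- 1
      share_r <- if (profile$phenotype == "typical") 0 else share_r
      mirror <- if (profile$phenotype == "atypical") 2L else 0L
      if (profile$phenotype == "typical" && irrelevant_scale > 0) {
        share_r <- irrelevant_scale * 2 * (1 - profile$effort_share)
      }
    } else {
      share_r <- 1
      share_l <- if (profile$phenotype == "typical") 0 else share_l
      mirror <- if (profile$phenotype == "atypical") 1L else 0L
      if (profile$phenotype == "typical" && irrelevant_scale > 0) {
        share_l <- irrelevant_scale * 2 * profile$effort_share
      }
    }
  }

  k <- connection_stiffness(connection)
  rigid <- is.infinite(k)
  sim <- .simulate_plant_cpp(
    qt, qdt, dt,
    weighting = match(weighting, cursor_weightings()) - 1L,
    rigid = rigid, stiffness = if (rigid) 0 else k,
    coupling_damping = if (coupled && !rigid) config$coupling_damping else 0,
    inertia_l = config$inertia, inertia_r = config$inertia,
    viscosity_l = config$viscosity, viscosity_r = config$viscosity,
    kp_l = profile$kp_l, kd_l = profile$kd_l,
    kp_r = profile$kp_r, kd_r = profile$kd_r,
    share_l = share_l, share_r = share_r, mirror = mirror,
    noise_base = config$noise_base,
    noise_mult_l = profile$motor_noise_l,
    noise_mult_r = profile$motor_noise_r,
    cc_l = profile$cc_baseline_l, cc_r = profile$cc_baseline_r,
    eps_l = rnorm(n), eps_r = rnorm(n))

  if (sim$unstable > 0L) {
    abort(sprintf(
      "Unstable trial: |q| exceeded 180 deg at t = %.3f s (participant %s, %s / %s).",
      sim$unstable * dt, profile$id, weighting, connection),
      class = "bt_unstable")
  }

  # ground-truth muscle decomposition of the commanded net torque
  torques <- tibble::tibble(
    time_s = t_emg,
    tau_lf_nm = pmax(sim$u_l, 0) + profile$cc_baseline_l,
    tau_le_nm = pmax(-sim$u_l, 0) + profile$cc_baseline_l,
    tau_rf_nm = pmax(sim$u_r, 0) + profile$cc_baseline_r,
    tau_re_nm = pmax(-sim$u_r, 0) + profile$cc_baseline_r)

  emg_tbl <- NULL
  if (emg) {
    gains <- c(profile$gain_lf, profile$gain_le, profile$gain_rf,
               profile$gain_re)
    act <- cbind(torques$tau_lf_nm, torques$tau_le_nm, torques$tau_rf_nm,
                 torques$tau_re_nm)
    emg_tbl <- tibble::tibble(time_s = t_emg)
    ch <- c("emg_lf_v", "emg_le_v", "emg_rf_v", "emg_re_v")
    for (j in seq_along(ch)) {
      emg_tbl[[ch[j]]] <- gains[j] * act[, j] * .emg_carrier(n, fs) +
        rnorm(n, 0, config$sensor_noise_sd)
    }
  }

  idx100 <- seq(10L, n, by = 10L)
  angles <- tibble::tibble(
    time_s = t_emg[idx100],
    q_l_deg = sim$q_l[idx100] / d2r,
    q_r_deg = sim$q_r[idx100] / d2r,
    q_target_deg = qt[idx100] / d2r)

  structure(
    list(angles = angles, emg = emg_tbl, torques = torques,
         participant = profile$id, phenotype = profile$phenotype,
         weighting = weighting, connection = connection,
         trial_index = trial_index, t0 = t0, seed = seed),
    class = "bt_trial")
}

#' @export
print.bt_trial <- function(x, ...) {
  cat(sprintf(
    "<bt_trial> %s | %s weighting, %s | t0 = %.3f s | %d angle samples @100 Hz, %d EMG samples @1000 Hz\n",
    x$participant, x$weighting, x$connection, x$t0,
    nrow(x$angles), if (is.null(x$emg)) 0L else nrow(x$emg)))
  invisible(x)
}

#' Simulate an isometric calibration recording
#'
#' Produces, for each of the four muscles, a staircase of isometric torque
#' levels (covering the task's commanded torque range) together with the
#' muscle's preprocessed EMG level, `voltage = gain * torque + sensor
#' noise`. Feeding the result to [calibrate_muscles()] recovers each
#' muscle's Nm/V calibration.
#'
#' @param profile One-row tibble from [generate_participant()].
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @param fs Sampling rate, Hz.
#' @return A tibble `muscle`, `time_s`, `torque_nm`, `voltage_v` (muscles:
#'   `left_flexor`, `left_extensor`, `right_flexor`, `right_extensor`).
#' @export
simulate_isometric_calibration <- function(profile, config = cohort_config(),
                                           seed = NULL, fs = 1000) {
  if (!is.null(seed)) set.seed(seed)
  levels <- seq(0, config$calib_max_torque, length.out = config$calib_levels)
  n_per <- round(config$calib_level_duration * fs)
  torque <- rep(levels, each = n_per)
  t_s <- seq_along(torque) / fs
  gains <- c(left_flexor = profile$gain_lf, left_extensor = profile$gain_le,
             right_flexor = profile$gain_rf, right_extensor = profile$gain_re)
  purrr::map_dfr(names(gains), function(m) {
    tibble::tibble(
      muscle = m, time_s = t_s, torque_nm = torque,
      voltage_v = gains[[m]] * torque +
        rnorm(length(torque), 0, config$sensor_noise_sd))
  })
}

# block layout for one participant under each protocol
.exp1_blocks <- function(sequence) {
  conns <- if (sequence == "A") c("not_connected", "medium_hard") else
    c("medium_hard", "not_connected")
  purrr::map_dfr(conns, function(cn) {
    tibble::tibble(weighting = sample(cursor_weightings()), connection = cn)
  })
}

#' Generate a full synthetic cohort
#'
#' Builds the complete dataset of either protocol. Experiment 1:
#' `n` participants each perform all six conditions (three cursor
#' weightings x not-connected / medium-hard spring) in counterbalanced
#' connection order, ten trials per block. Experiment 2: four groups of
#' `n` participants, one connection level per group (not-connected,
#' compliant, medium-hard, rigid), each performing the three cursor
#' weightings for ten trials. Cursor order is pseudo-randomized per
#' participant; every trial starts at a randomly selected target zero and
#' carries its own derived seed, so a cohort is byte-identical under a
#' fixed master seed.
#'
#' @param scenario `"experiment1"` or `"experiment2"`.
#' @param config A [cohort_config()].
#' @param seed Master seed (integer).
#' @param n Participants (experiment 1) or participants per group
#'   (experiment 2); defaults from `config`.
#' @param emg Synthesize EMG channels (default). `FALSE` skips them for
#'   analyses that only need kinematics.
#' @param simulate Integrate the trials (default). `FALSE` builds the
#'   manifest and participant profiles only - useful for protocol-structure
#'   checks.
#' @return A `bt_cohort` object: `$participants` (profiles plus a
#'   `calibration` list-column of isometric recordings) and `$trials`
#'   (manifest columns `participant`, `group`, `sequence`, `weighting`,
#'   `connection`, `block`, `trial_index`, `t0`, `seed`, plus the
#'   `trial` list-column of [simulate_trial()] results).
#' @export
generate_cohort <- function(scenario = c("experiment1", "experiment2"),
                            config = cohort_config(), seed = 1L, n = NULL,
                            emg = TRUE, simulate = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "bt_config"))
  set.seed(seed)
  if (is.null(n)) {
    n <- if (scenario == "experiment1") config$n_participants else
      config$n_per_group
  }
  if (n < 2) {
    abort("At least 2 participants per cell are required for the downstream statistics.")
  }
  zeros <- start_time_zeros()

  layout <- if (scenario == "experiment1") {
    purrr::map_dfr(seq_len(n), function(i) {
      sequence <- c("A", "B")[(i - 1L) %% 2L + 1L]
      dplyr::mutate(.exp1_blocks(sequence),
                    participant = sprintf("P%02d", i),
                    group = "within", sequence = sequence)
    })
  } else {
    groups <- connection_levels()
    purrr::map_dfr(seq_along(groups), function(g) {
      purrr::map_dfr(seq_len(n), function(i) {
        tibble::tibble(
          weighting = sample(cursor_weightings()),
          connection = groups[g],
          participant = sprintf("G%d_P%02d", g, i),
          group = groups[g], sequence = NA_character_)
      })
    })
  }
  layout <- dplyr::mutate(layout, block = dplyr::row_number(),
                          .by = "participant")

  ids <- unique(layout$participant)
  participants <- purrr::map_dfr(ids, function(id) {
    prof <- generate_participant(config, id)
    prof$calibration <- list(simulate_isometric_calibration(prof, config))
    prof$group <- layout$group[match(id, layout$participant)]
    prof$sequence <- layout$sequence[match(id, layout$participant)]
    prof
  })

  trials <- tidyr::crossing(layout, trial_index = 1:10) %>%
    dplyr::arrange(.data$participant, .data$block, .data$trial_index) %>%
    dplyr::mutate(t0 = sample_start_time(dplyr::n(), zeros),
                  seed = sample.int(.Machine$integer.max - 1L, dplyr::n()))

  if (simulate) {
    trials$trial <- purrr::pmap(
      list(trials$participant, trials$weighting, trials$connection,
           trials$trial_index, trials$t0, trials$seed),
      function(id, w, cn, ti, t0, s) {
        prof <- participants[participants$id == id, ]
        scale <- if (config$ramp_trials > 0) {
          max(0, 1 - (ti - 1) / config$ramp_trials)
        } else 0
        simulate_trial(prof, w, cn, t0, config, seed = s, trial_index = ti,
                       irrelevant_scale = scale, emg = emg)
      })
  }

  structure(list(scenario = scenario, participants = participants,
                 trials = trials, config = config, seed = seed),
            class = "bt_cohort")
}

#' @export
print.bt_cohort <- function(x, ...) {
  cat(sprintf("<bt_cohort> %s: %d participants, %d trials (master seed %d)\n",
              x$scenario, nrow(x$participants), nrow(x$trials), x$seed))
  invisible(x)
}

#' Simulate a participant-level imbalance table
#'
#' Direct generator for the aggregated effort-imbalance layout (one row per
#' participant and cursor weighting) used in slope-recovery studies:
#' `y = slope * code + intercept + subject offset + residual`, with the
#' weighting coded left -1, center 0, right +1. Defaults reproduce the
#' effect size of a clearly weighting-dependent imbalance at n = 20
#' (slope -0.15 Nm with |t| ~ 4).
#'
#' @param n_subjects Number of participants.
#' @param slope True per-step change of the imbalance, Nm.
#' @param intercept True imbalance at center weighting, Nm.
#' @param sd_subject Between-participant SD of the random intercept, Nm.
#' @param sd_resid Residual SD, Nm.
#' @return Tibble: `participant`, `weighting`, `weighting_code`, `imbalance`.
#' @export
simulate_imbalance_cohort <- function(n_subjects = 20, slope = -0.15,
                                      intercept = 0, sd_subject = 0.10,
                                      sd_resid = 0.24) {
  ids <- sprintf("P%02d", seq_len(n_subjects))
  offs <- rnorm(n_subjects, 0, sd_subject)
  tidyr::crossing(participant = ids, weighting = cursor_weightings()) %>%
    dplyr::mutate(
      weighting_code = code_weighting(.data$weighting),
      imbalance = slope * .data$weighting_code + intercept +
        offs[match(.data$participant, ids)] +
        rnorm(dplyr::n(), 0, sd_resid))
}

#' Manifest table of a cohort
#'
#' The per-trial metadata of a [generate_cohort()] dataset, without the
#' embedded time series.
#'
#' @param cohort A `bt_cohort`.
#' @return A tibble: participant, group, sequence, weighting, connection,
#'   block, trial_index, t0, seed.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "bt_cohort"))
  dplyr::select(cohort$trials, "participant", "group", "sequence",
                "weighting", "connection", "block", "trial_index",
                "t0", "seed")
}
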