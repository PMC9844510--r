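# Per-trial behavioral and effort metrics: normalized arc length, reciprocal
# activation, co-contraction, their left-minus-right imbalances, RMS
# tracking error and the Spearman correlation between the wrists, plus the
# trimming and aggregation rules (drop the first second of every trial,
# average the last five trials of each block per participant).

#' Normalized arc length of a wrist trajectory
#'
#' Arc length of the hand's path divided by the target's, computed on the
#' raw 100 Hz samples: `sum(|diff(q_hand)|) / sum(|diff(q_target)|)`.
#' A value near 1 means the hand moved about as much as the target; near 0,
#' the hand barely moved.
#'
#' @param q_hand,q_target Equal-length angle series, degrees.
#' @return Dimensionless scalar >= 0.
#' @export
normalized_arc_length <- function(q_hand, q_target) {
  stopifnot(length(q_hand) == length(q_target), length(q_hand) > 1L)
  denom <- sum(abs(diff(q_target)))
  if (denom <= .Machine$double.eps) {
    abort("Constant target trajectory: arc-length denominator is zero.")
  }
  sum(abs(diff(q_hand))) / denom
}

#' Reciprocal activation and co-contraction of an antagonist pair
#'
#' Decomposes the flexor/extensor torque pair pointwise:
#' reciprocal activation `u_ra(t) = max(|tau_f|, |tau_e|) -
#' min(|tau_f|, |tau_e|)` is the net effort contributing to motion;
#' co-contraction `u_cc(t) = min(|tau_f|, |tau_e|)` is the overlapping
#' antagonist activation that stiffens the joint without moving it. The
#' two satisfy `u_ra + 2 u_cc = |tau_f| + |tau_e|` identically. The trial
#' scalar is the time mean over the analysis window (duration-independent).
#'
#' @param tau_f,tau_e Flexor and extensor torque series, Nm (equal length).
#' @return A list with `series` (Nm) and `mean` (Nm).
#' @export
reciprocal_activation <- function(tau_f, tau_e) {
  stopifnot(length(tau_f) == length(tau_e))
  s <- pmax(abs(tau_f), abs(tau_e)) - pmin(abs(tau_f), abs(tau_e))
  list(series = s, mean = mean(s))
}

#' @rdname reciprocal_activation
#' @export
co_contraction <- function(tau_f, tau_e) {
  stopifnot(length(tau_f) == length(tau_e))
  s <- pmin(abs(tau_f), abs(tau_e))
  list(series = s, mean = mean(s))
}

#' RMS tracking error
#'
#' Root-mean-squared error between the controlled cursor and the target.
#'
#' @param q_cursor,q_target Equal-length angle series, degrees.
#' @return Degrees.
#' @export
rms_error <- function(q_cursor, q_target) {
  stopifnot(length(q_cursor) == length(q_target))
  sqrt(mean((q_cursor - q_target)^2))
}

#' Spearman correlation between the wrists
#'
#' Rank correlation (average ranks on ties) of the two wrists' angle
#' series; a constant series makes the correlation undefined and returns
#' `NA` with a warning.
#'
#' @param q_l,q_r Equal-length angle series, degrees.
#' @return Correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
hand_correlation <- function(q_l, q_r) {
  stopifnot(length(q_l) == length(q_r), length(q_l) > 1L)
  if (length(unique(q_l)) < 2L || length(unique(q_r)) < 2L) {
    warn("Hand correlation undefined: a wrist series is constant.")
    return(NA_real_)
  }
  rl <- rank(q_l)
  rr <- rank(q_r)
  # identical rank vectors (e.g. the rigid-bar constraint) are exactly 1;
  # the Pearson route would lose that to floating point
  if (identical(rl, rr)) return(1)
  cor(rl, rr)
}

#' Compute the full metric set for one trial
#'
#' Removes the first `trim` seconds of every series (reaction-time window),
#' reconstructs per-muscle torques from the trial EMG through the
#' participant's calibration models, and computes all per-trial metrics.
#' Angle metrics use the native 100 Hz grid and torque metrics the native
#' 1000 Hz grid; no cross-rate resampling is involved. When `models` is
#' `NULL` the simulator's ground-truth commanded torques are used instead
#' of the EMG route.
#'
#' @param trial A `bt_trial`.
#' @param models Calibration table from [calibrate_muscles()], or `NULL`.
#' @param trim Seconds discarded from the start of the trial (default 1).
#' @return One-row tibble: keys (`participant`, `weighting`, `connection`,
#'   `trial_index`), `nal_l`, `nal_r`, `ra_l`, `ra_r`, `cc_l`, `cc_r`,
#'   `nal_imb`, `ra_imb`, `cc_imb` (left minus right), `rms_error`
#'   (degrees) and `rho` (Spearman).
#' @export
trial_metrics <- function(trial, models = NULL, trim = 1) {
  stopifnot(inherits(trial, "bt_trial"))
  ang <- trial$angles[trial$angles$time_s > trim + 1e-9, ]
  tau <- if (is.null(models)) {
    trial$torques
  } else {
    if (is.null(trial$emg)) {
      abort("Trial carries no EMG; simulate with `emg = TRUE` or pass `models = NULL`.")
    }
    reconstruct_torques(trial$emg, models)
  }
  tau <- tau[tau$time_s > trim + 1e-9, ]

  nal_l <- normalized_arc_length(ang$q_l_deg, ang$q_target_deg)
  nal_r <- normalized_arc_length(ang$q_r_deg, ang$q_target_deg)
  ra_l <- reciprocal_activation(tau$tau_lf_nm, tau$tau_le_nm)$mean
  ra_r <- reciprocal_activation(tau$tau_rf_nm, tau$tau_re_nm)$mean
  cc_l <- co_contraction(tau$tau_lf_nm, tau$tau_le_nm)$mean
  cc_r <- co_contraction(tau$tau_rf_nm, tau$tau_re_nm)$mean
  q_c <- cursor_position(ang$q_l_deg, ang$q_r_deg, trial$weighting)

  tibble::tibble(
    participant = trial$participant,
    weighting = trial$weighting,
    connection = trial$connection,
    trial_index = trial$trial_index,
    nal_l = nal_l, nal_r = nal_r,
    ra_l = ra_l, ra_r = ra_r,
    cc_l = cc_l, cc_r = cc_r,
    nal_imb = nal_l - nal_r,
    ra_imb = ra_l - ra_r,
    cc_imb = cc_l - cc_r,
    rms_error = rms_error(q_c, ang$q_target_deg),
    rho = hand_correlation(ang$q_l_deg, ang$q_r_deg))
}

#' Per-trial metrics for a whole cohort
#'
#' Calibrates each participant's muscles from their isometric recording and
#' maps [trial_metrics()] over every trial.
#'
#' @param cohort A `bt_cohort`.
#' @param use_emg Reconstruct torques from EMG through the calibration
#'   (default); `FALSE` uses the simulator's ground-truth torques.
#' @param trim Seconds discarded from the start of each trial.
#' @return A tibble, one row per trial, with manifest keys (`group`,
#'   `sequence`, `block` included) and all metric columns.
#' @export
compute_metrics <- function(cohort, use_emg = TRUE, trim = 1) {
  stopifnot(inherits(cohort, "bt_cohort"))
  models <- if (use_emg) {
    setNames(
      purrr::map(cohort$participants$calibration, calibrate_muscles),
      cohort$participants$id)
  }
  meta <- dplyr::select(cohort$trials, "participant", "group", "sequence",
                       "block", "trial_index")
  res <- purrr::map2_dfr(cohort$trials$trial, cohort$trials$participant,
                         function(tr, id) {
                           trial_metrics(tr, models[[id]], trim = trim)
                         })
  dplyr::bind_cols(dplyr::select(meta, -"trial_index", -"participant"), res) %>%
    dplyr::relocate("participant", "group", "sequence", "weighting",
                    "connection", "block", "trial_index")
}

#' Aggregate trial metrics to participant level
#'
#' The steady-state summary used for inference: keep only trials 6-10 of
#' each ten-trial block and average them per participant and condition.
#' Blocks with fewer than `trials_per_block` trials are rejected.
#'
#' @param metrics Per-trial metrics table from [compute_metrics()].
#' @param last_n Number of final trials to keep (default 5).
#' @param trials_per_block Expected block length (default 10).
#' @return One row per participant x condition, metric columns averaged.
#' @export
trim_and_aggregate <- function(metrics, last_n = 5, trials_per_block = 10) {
  keys <- intersect(c("participant", "group", "sequence", "weighting",
                      "connection", "block"), names(metrics))
  counts <- dplyr::count(metrics, dplyr::across(dplyr::all_of(keys)))
  if (any(counts$n < trials_per_block)) {
    abort(sprintf(
      "Incomplete block(s): expected %d trials, found as few as %d.",
      trials_per_block, min(counts$n)))
  }
  metrics %>%
    dplyr::filter(.data$trial_index > trials_per_block - last_n) %>%
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("trial_index"), mean),
                     .by = dplyr::all_of(keys)) %>%
    dplyr::select(-dplyr::any_of("trial_index"))
}

#' Pivot per-hand metrics to long format
#'
#' Reshapes a metrics table so that NAL, RA and CC appear once per hand,
#' with a `hand` factor - the layout needed by the three-way factorial
#' analysis (cursor weighting x connection x hand).
#'
#' @param metrics A per-trial or aggregated metrics table.
#' @return Long tibble with columns `hand` (`"left"`/`"right"`), `nal`,
#'   `ra`, `cc` replacing the per-hand pairs.
#' @export
metrics_by_hand <- function(metrics) {
  tidyr::pivot_longer(metrics,
                      cols = c("nal_l", "nal_r", "ra_l", "ra_r",
                               "cc_l", "cc_r"),
                      names_to = c(".value", "hand"),
                      names_pattern = "(nal|ra|cc)_(l|r)") %>%
    dplyr::mutate(hand = dplyr::if_else(.data$hand == "l", "left", "right"))
}
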