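# EMG preprocessing: 20 Hz high-pass, full-wave rectification, 5 Hz low-pass
# (second-order Butterworth throughout), then linear EMG-to-torque
# calibration against isometric recordings.

# Zero-phase filtering with odd-reflection edge padding. `filt` is an Arma
# filter from signal::butter.
.filtfilt_pad <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- signal::filter(filt, xe)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1L):(pad + n)]
}

.causal_filter_pad <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  y <- signal::filter(filt, c(head_pad, x))
  y[(pad + 1L):(pad + n)]
}

# Cutoff correction so that a forward-backward pass of an order-`ord`
# Butterworth is -3 dB at the nominal cutoff: each pass must be -1.5 dB
# there, which moves the design cutoff by (sqrt(2) - 1)^(1/(2 ord)).
.zp_cutoff_factor <- function(ord = 2) (sqrt(2) - 1)^(1 / (2 * ord))

#' EMG linear envelope
#'
#' Standard surface-EMG envelope: second-order Butterworth high-pass at
#' 20 Hz, full-wave rectification, second-order Butterworth low-pass at
#' 5 Hz. Filtering is zero-phase (forward-backward) by default, appropriate
#' for offline metrics; the design cutoffs are corrected so the combined
#' two-pass response is -3 dB at the nominal cutoffs. A causal single-pass
#' mode is available for streaming-style processing. Edges are handled by
#' odd-reflection padding. Small negative excursions from low-pass ringing
#' are kept by default so the operator stays positively homogeneous
#' (`envelope(a * x) = a * envelope(x)` for `a > 0`).
#'
#' @param x Raw EMG, volts.
#' @param fs Sampling rate, Hz (> 40).
#' @param hp_cutoff,lp_cutoff High-/low-pass cutoffs, Hz.
#' @param causal Use single-pass causal filtering instead of zero-phase.
#' @param clamp Clamp negative ringing to zero (off by default).
#' @return Envelope, volts, same length as `x`.
#' @export
emg_envelope <- function(x, fs, hp_cutoff = 20, lp_cutoff = 5,
                         causal = FALSE, clamp = FALSE) {
  stopifnot(is.numeric(x), is.numeric(fs), fs > 40)
  settle_n <- ceiling(0.1 * fs)  # ~3 time constants of the 5 Hz stage
  if (length(x) < 3L * settle_n) {
    abort(sprintf("EMG series too short: %d samples < 3 x settle length (%d).",
                  length(x), settle_n))
  }
  corr <- if (causal) 1 else .zp_cutoff_factor(2)
  hp <- signal::butter(2, (hp_cutoff * corr) / (fs / 2), type = "high")
  lp <- signal::butter(2, (lp_cutoff / corr) / (fs / 2), type = "low")
  pad <- min(length(x) - 1L, ceiling(0.5 * fs))
  run <- if (causal) .causal_filter_pad else .filtfilt_pad
  y <- run(hp, x, pad)
  y <- abs(y)
  y <- run(lp, y, pad)
  if (clamp) y <- pmax(y, 0)
  y
}

#' Fit an EMG-to-torque calibration model
#'
#' Ordinary least squares of joint torque on the muscle's EMG envelope,
#' fitted on isometric-contraction recordings: `torque = slope * envelope +
#' intercept`. The slope is in Nm/V, so applying the model to task EMG
#' yields torque in Nm.
#'
#' @param envelope EMG envelope, volts.
#' @param torque Isometric torque, Nm (same length, >= 100 samples).
#' @return A `bt_calibration` object with `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n`.
#' @export
fit_calibration <- function(envelope, torque) {
  stopifnot(is.numeric(envelope), is.numeric(torque))
  if (length(envelope) != length(torque)) {
    abort("`envelope` and `torque` must have equal length.")
  }
  if (length(envelope) < 100L) {
    abort("Calibration needs at least 100 samples.")
  }
  if (var(envelope) <= .Machine$double.eps) {
    abort("Calibration rejected: EMG envelope has zero variance (degenerate regressor).")
  }
  fit <- lm(torque ~ envelope)
  s <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = s$r.squared,
         residual_sd = s$sigma,
         n = length(torque)),
    class = "bt_calibration")
}

#' @export
print.bt_calibration <- function(x, ...) {
  cat(sprintf(
    "EMG-torque calibration: slope %.4g Nm/V, intercept %.4g Nm (R^2 %.3f, n %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.bt_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.bt_calibration <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, residual_sd = x$residual_sd,
                 n = x$n)
}

#' Calibrate all four muscles of a participant
#'
#' Applies [fit_calibration()] to each muscle of an isometric calibration
#' recording (see [simulate_isometric_calibration()]).
#'
#' @param calibration A tibble with columns `muscle`, `voltage_v`,
#'   `torque_nm`.
#' @return A tibble with one row per muscle: `muscle`, `slope`,
#'   `intercept`, `r_squared`, `residual_sd`.
#' @export
calibrate_muscles <- function(calibration) {
  stopifnot(all(c("muscle", "voltage_v", "torque_nm") %in% names(calibration)))
  calibration %>%
    dplyr::group_by(.data$muscle) %>%
    dplyr::group_modify(function(d, key) {
      m <- fit_calibration(d$voltage_v, d$torque_nm)
      tibble::tibble(slope = m$slope, intercept = m$intercept,
                     r_squared = m$r_squared, residual_sd = m$residual_sd)
    }) %>%
    dplyr::ungroup()
}

# muscle token <-> EMG column lookup
.muscle_channels <- function() {
  c(left_flexor = "emg_lf_v", left_extensor = "emg_le_v",
    right_flexor = "emg_rf_v", right_extensor = "emg_re_v")
}

#' Reconstruct muscle torques from task EMG
#'
#' Extracts the envelope of each of the four EMG channels and applies that
#' muscle's calibration model, giving flexor and extensor torque series per
#' hand on the native 1000 Hz grid.
#'
#' @param emg A tibble with columns `time_s`, `emg_lf_v`, `emg_le_v`,
#'   `emg_rf_v`, `emg_re_v` (a trial's EMG block).
#' @param models Calibration table from [calibrate_muscles()]; must contain
#'   all four muscles.
#' @param fs Sampling rate, Hz.
#' @param envelope Set to `FALSE` if `emg` already holds envelopes.
#' @return A tibble `time_s`, `tau_lf_nm`, `tau_le_nm`, `tau_rf_nm`,
#'   `tau_re_nm`.
#' @export
reconstruct_torques <- function(emg, models, fs = 1000, envelope = TRUE) {
  chans <- .muscle_channels()
  missing_ch <- setdiff(unname(chans), names(emg))
  if (length(missing_ch)) {
    abort(paste0("EMG channel(s) missing: ", paste(missing_ch, collapse = ", ")))
  }
  missing_m <- setdiff(names(chans), models$muscle)
  if (length(missing_m)) {
    abort(paste0("Calibration model(s) missing for: ",
                 paste(missing_m, collapse = ", ")))
  }
  out <- tibble::tibble(time_s = emg$time_s)
  tau_cols <- c(left_flexor = "tau_lf_nm", left_extensor = "tau_le_nm",
                right_flexor = "tau_rf_nm", right_extensor = "tau_re_nm")
  for (m in names(chans)) {
    v <- emg[[chans[[m]]]]
    if (envelope) v <- emg_envelope(v, fs)
    row <- models[models$muscle == m, ]
    out[[tau_cols[[m]]]] <- row$slope * v + row$intercept
  }
  out
}
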