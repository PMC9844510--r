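# Multisine target, cursor mappings and coupling physics for the
# one-degree-of-freedom bimanual wrist-tracking task. Angles are kept in
# degrees throughout; conversion to radians happens only inside the spring
# law, whose stiffness is expressed in Nm/rad.

# target multisine coefficients: q*(t) = sum a_i sin(w_i (t + t0)), degrees
.target_amp  <- c(-7.8, 1.6, 9.4, -10.6)
.target_freq <- c(0.48, 1.12, 1.48, 2.56)   # rad/s; all multiples of 0.04

#' Trial duration of the tracking task
#'
#' Every trial lasts 25 s; wrist angles are recorded at 100 Hz and EMG /
#' commanded torque at 1000 Hz.
#' @return Duration in seconds.
#' @export
trial_duration <- function() 25

#' Fundamental period of the target trajectory
#'
#' The four angular frequencies of the multisine are all integer multiples of
#' 0.04 rad/s, so the trajectory repeats every `2 * pi / 0.04` ~ 157.1 s.
#' @return Period in seconds.
#' @export
target_period <- function() 2 * pi / 0.04

#' Target position of the tracking task
#'
#' Evaluates the multisine reference trajectory
#' \deqn{q^*(t) = -7.8 \sin(0.48 t^*) + 1.6 \sin(1.12 t^*) +
#'       9.4 \sin(1.48 t^*) - 10.6 \sin(2.56 t^*), \quad t^* = t + t_0,}
#' in degrees. `t` must lie within the 25-s trial; the start offset `t0`
#' shifts the phase so that different trials sample different stretches of
#' the same underlying signal.
#'
#' @param t Time within the trial, seconds, in `[0, trial_duration()]`.
#'   Vectorised.
#' @param t0 Start offset, seconds (scalar).
#' @return Target angle(s), degrees.
#' @export
#' @examples
#' target_position(0, 0)          # 0: all sine terms vanish
#' target_position(seq(0, 1, 0.1), t0 = 4.156)
target_position <- function(t, t0 = 0) {
  stopifnot(is.numeric(t), is.numeric(t0), length(t0) == 1L)
  if (any(t < -1e-12 | t > trial_duration() + 1e-12)) {
    abort("`t` must lie within [0, 25] s (one trial).")
  }
  ts <- outer(t + t0, .target_freq)
  drop(sin(ts) %*% .target_amp)
}

#' @rdname target_position
#' @details `target_velocity()` is the analytic time derivative, in deg/s;
#'   the simulator uses it for derivative feedback.
#' @export
target_velocity <- function(t, t0 = 0) {
  stopifnot(is.numeric(t), is.numeric(t0), length(t0) == 1L)
  ts <- outer(t + t0, .target_freq)
  drop(cos(ts) %*% (.target_amp * .target_freq))
}

# unrestricted evaluation over any t*, used for range/zero searches
.target_raw <- function(tstar) {
  drop(sin(outer(tstar, .target_freq)) %*% .target_amp)
}

#' Extremes of the target trajectory
#'
#' Minimum and maximum of the multisine, found by a dense grid scan with
#' local refinement (`stats::optimize`). Two domains are supported:
#' `"period"` scans one fundamental period (~157.1 s); `"visualized"` scans
#' the part of the signal a participant can actually see, `t* in [0, 50]`
#' (trial time up to 25 s plus a start offset up to 25 s).
#'
#' Because the multisine is odd and periodic, the full-period extremes are
#' symmetric (+/- 28.196 deg); the visualized domain is narrower on the
#' positive side (+25.270 deg).
#'
#' @param domain `"period"` or `"visualized"`.
#' @param grid_step Scan step, seconds (default 1e-3, i.e. 1 kHz).
#' @return A tibble with columns `min_deg` and `max_deg`.
#' @export
target_range <- function(domain = c("period", "visualized"), grid_step = 1e-3) {
  domain <- match.arg(domain)
  upper <- if (domain == "period") target_period() else 2 * trial_duration()
  tg <- seq(0, upper, by = grid_step)
  v <- .target_raw(tg)
  refine <- function(i, maximum) {
    lo <- tg[max(1L, i - 2L)]
    hi <- tg[min(length(tg), i + 2L)]
    stats::optimize(.target_raw, c(lo, hi), maximum = maximum,
                    tol = .Machine$double.eps^0.5)
  }
  mn <- refine(which.min(v), FALSE)$objective
  mx <- refine(which.max(v), TRUE)$maximum
  mx <- .target_raw(mx)
  tibble::tibble(min_deg = mn, max_deg = mx)
}

#' Admissible trial start times
#'
#' A trial may start at any offset `t0` in `[0, 25]` s at which the target
#' passes through zero, so the cursor and target coincide at trial onset.
#' Zeros are located by a sign-change scan at `scan_step` resolution followed
#' by bisection (`stats::uniroot`) until `|q*(t0)| < tol` degrees.
#'
#' @param scan_step Scan resolution, seconds (default 1 ms).
#' @param tol Zero tolerance, degrees (default 1e-6).
#' @return Sorted numeric vector of admissible start times (always includes 0).
#' @export
start_time_zeros <- function(scan_step = 1e-3, tol = 1e-6) {
  g <- seq(0, trial_duration(), by = scan_step)
  v <- .target_raw(g)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(.target_raw, c(g[i], g[i + 1L]),
                   tol = .Machine$double.eps^0.5)$root
  }, numeric(1))
  # exact grid zeros (e.g. t0 = 0) are admissible as well
  roots <- sort(unique(c(g[abs(v) < tol], roots)))
  roots <- roots[abs(.target_raw(roots)) < tol]
  # collapse duplicates closer than the scan step
  keep <- c(TRUE, diff(roots) > scan_step / 2)
  roots[keep]
}

#' Sample a random admissible start time
#'
#' Draws uniformly from the finite set of target-trajectory zeros in
#' `[0, 25]` s (see [start_time_zeros()]), using R's random number stream.
#'
#' @param n Number of draws.
#' @param zeros Optional precomputed zero set (avoids re-scanning).
#' @return Numeric vector of length `n`; each satisfies
#'   `|target_position(0, t0)| < 1e-6` degrees.
#' @export
sample_start_time <- function(n = 1, zeros = NULL) {
  if (is.null(zeros)) zeros <- start_time_zeros()
  zeros[sample.int(length(zeros), n, replace = TRUE)]
}

## ---- conditions -----------------------------------------------------------

#' Condition vocabulary and stiffness lookup
#'
#' Conditions are the crossing of a cursor weighting (`"left"`, `"center"`,
#' `"right"`) with a connection level (`"not_connected"`, `"compliant"`,
#' `"medium_hard"`, `"rigid"`). The connection level uniquely determines the
#' spring stiffness: 0, 0.63, 2.86 Nm/rad, or `Inf` as the rigid-bar
#' sentinel (the rigid bar is simulated as the kinematic constraint
#' `q_l == q_r`, never as a very stiff spring).
#'
#' @return `cursor_weightings()` and `connection_levels()` return the token
#'   vectors used in every table; `connection_stiffness()` maps connection
#'   tokens to stiffness in Nm/rad.
#' @export
cursor_weightings <- function() c("left", "center", "right")

#' @rdname cursor_weightings
#' @export
connection_levels <- function() {
  c("not_connected", "compliant", "medium_hard", "rigid")
}

#' @rdname cursor_weightings
#' @param connection Character vector of connection tokens.
#' @export
connection_stiffness <- function(connection) {
  map <- c(not_connected = 0, compliant = 0.63, medium_hard = 2.86,
           rigid = Inf)
  bad <- setdiff(unique(connection), names(map))
  if (length(bad)) {
    abort(paste0("Unknown connection token(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(map[connection])
}

#' Cursor position under a given weighting
#'
#' Maps the two wrist angles to the single displayed cursor: the left hand's
#' angle, the right hand's, or their average.
#'
#' @param q_l,q_r Wrist angles, degrees (vectorised, equal length).
#' @param weighting One of `"left"`, `"center"`, `"right"`.
#' @return Cursor angle(s), degrees.
#' @export
#' @examples
#' cursor_position(10, 20, "center")  # 15
cursor_position <- function(q_l, q_r, weighting) {
  stopifnot(is.numeric(q_l), is.numeric(q_r), length(q_l) == length(q_r))
  if (!is.character(weighting) || length(weighting) != 1L ||
      !weighting %in% cursor_weightings()) {
    abort("`weighting` must be one of \"left\", \"center\", \"right\".")
  }
  switch(weighting,
         left = q_l,
         right = q_r,
         center = (q_l + q_r) / 2)
}

#' Virtual-spring coupling torque
#'
#' Torque exerted on each wrist by the virtual spring (stiffness `K` in
#' Nm/rad, plus a small parallel damping term used for simulation
#' stability). The torque on the left wrist is
#' `K * (q_r - q_l) * pi/180 + damping * (dq_r - dq_l) * pi/180`; the right
#' wrist receives its negation, so the pair always sums to zero. The rigid
#' bar is not a torque law: it is handled upstream as the kinematic
#' constraint `q_l == q_r` with summed inertias, and is rejected here.
#'
#' @param q_l,q_r Wrist angles, degrees (vectorised).
#' @param dq_l,dq_r Wrist velocities, deg/s.
#' @param connection Connection token (`"not_connected"`, `"compliant"`,
#'   `"medium_hard"`).
#' @param damping Parallel damping, Nm s/rad (default 0.05; not part of the
#'   published spring specification).
#' @return A tibble with columns `left` and `right`, Nm.
#' @export
coupling_torque <- function(q_l, q_r, dq_l = 0, dq_r = 0, connection,
                            damping = 0.05) {
  if (identical(connection, "rigid")) {
    abort("Rigid coupling is a kinematic constraint; use the constrained plant, not a torque law.")
  }
  k <- connection_stiffness(connection)
  d2r <- pi / 180
  left <- k * (q_r - q_l) * d2r + damping * (dq_r - dq_l) * d2r
  tibble::tibble(left = left, right = -left)
}
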