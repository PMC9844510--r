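# Config-driven orchestration: simulate -> calibrate -> metrics -> stats ->
# report, with full seed provenance. Every stage consumes and produces the
# documented table schemas, so each is independently testable; the whole
# run is byte-identical under a fixed master seed.

#' Pipeline configuration
#'
#' @param scenario `"experiment1"` or `"experiment2"`.
#' @param n Participants (experiment 1) or per group (experiment 2);
#'   `NULL` uses the protocol defaults (18, and 10 per group).
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir Output directory for tables and the report; `NULL` keeps
#'   everything in memory.
#' @param use_emg Route effort metrics through EMG envelope extraction and
#'   calibration (default) rather than the simulator's ground truth.
#' @param write_timeseries Also write one columnar time-series file per
#'   trial (see [write_dataset()]); off by default.
#' @param run_stats Run the inferential stage.
#' @param cohort A [cohort_config()].
#' @return A list of class `bt_pipeline_config`.
#' @export
pipeline_config <- function(scenario = "experiment1", n = NULL, seed = 1L,
                            out_dir = NULL, use_emg = TRUE,
                            write_timeseries = FALSE, run_stats = TRUE,
                            cohort = cohort_config()) {
  stopifnot(scenario %in% c("experiment1", "experiment2"),
            inherits(cohort, "bt_config"))
  structure(as.list(environment()), class = "bt_pipeline_config")
}

# normality screen only where every cell is large enough for the test
.maybe_shapiro <- function(aggregated, dv, by) {
  n_min <- min(dplyr::count(aggregated,
                            dplyr::across(dplyr::all_of(by)))$n)
  if (n_min < 3L) return(NULL)
  dplyr::mutate(shapiro_screen(aggregated, dv, by),
                analysis = "shapiro", dv = dv, .before = 1L)
}

.exp1_stats <- function(metrics, aggregated) {
  by_hand <- metrics_by_hand(aggregated)
  art2 <- purrr::map_dfr(c("rms_error", "rho"), function(dv) {
    dplyr::mutate(art_anova(aggregated, dv,
                            within = c("weighting", "connection"),
                            subject = "participant"),
                  analysis = "art_anova_2way", dv = dv, .before = 1L)
  })
  art3 <- purrr::map_dfr(c("nal", "ra", "cc"), function(dv) {
    dplyr::mutate(art_anova(by_hand, dv,
                            within = c("weighting", "connection", "hand"),
                            subject = "participant"),
                  analysis = "art_anova_3way", dv = dv, .before = 1L)
  })
  pw <- dplyr::bind_rows(
    dplyr::mutate(pairwise_family(aggregated, "rms_error", "within_cursor"),
                  dv = "rms_error"),
    dplyr::mutate(pairwise_family(aggregated, "rms_error",
                                  "across_connection", paired = TRUE),
                  dv = "rms_error"),
    purrr::map_dfr(c("nal", "ra", "cc"), function(dv) {
      dplyr::mutate(pairwise_family(aggregated, dv, "left_vs_right"),
                    dv = dv)
    }))
  norm <- .maybe_shapiro(aggregated, "rms_error",
                         c("weighting", "connection"))
  trends <- purrr::map_dfr(c("first5", "last5"), function(w) {
    m <- suppressWarnings(trial_trend(metrics, "rms_error", w))
    dplyr::mutate(tidy(m), analysis = paste0("trend_", w),
                  dv = "rms_error", .before = 1L)
  })
  list(results = dplyr::bind_rows(art2, art3, pw, norm),
       trends = trends, slopes = NULL)
}

.exp2_stats <- function(metrics, aggregated) {
  art <- purrr::map_dfr(c("rms_error", "rho"), function(dv) {
    dplyr::mutate(art_anova(aggregated, dv, within = "weighting",
                            between = "connection",
                            subject = "participant"),
                  analysis = "art_anova_mixed", dv = dv, .before = 1L)
  })
  slopes <- purrr::map_dfr(c("nal_imb", "ra_imb", "cc_imb"), function(dv) {
    suppressWarnings(imbalance_slopes(aggregated, dv))
  })
  pw <- dplyr::bind_rows(
    dplyr::mutate(pairwise_family(aggregated, "rms_error", "within_cursor"),
                  dv = "rms_error"),
    dplyr::mutate(pairwise_family(aggregated, "rms_error",
                                  "across_connection", paired = FALSE),
                  dv = "rms_error"),
    dplyr::mutate(pairwise_family(aggregated, "nal", "left_vs_right"),
                  dv = "nal"))
  norm <- .maybe_shapiro(aggregated, "rms_error",
                         c("weighting", "connection"))
  list(results = dplyr::bind_rows(art, pw, norm), trends = NULL,
       slopes = slopes)
}

.pipeline_report <- function(config, cohort, aggregated, stats) {
  lines <- c(
    "# Bimanual tracking pipeline report", "",
    sprintf("- scenario: %s (master seed %d)", config$scenario, config$seed),
    sprintf("- participants: %d; trials: %d", nrow(cohort$participants),
            nrow(cohort$trials)), "")

  unc <- dplyr::filter(aggregated, .data$connection == "not_connected",
                       .data$weighting != "center")
  if (nrow(unc)) {
    rel <- mean(ifelse(unc$weighting == "left", unc$nal_l, unc$nal_r))
    irr <- mean(ifelse(unc$weighting == "left", unc$nal_r, unc$nal_l))
    lines <- c(lines, sprintf(
      "- uncoupled unequal weighting: task-relevant hand NAL %.2f, task-irrelevant %.2f",
      rel, irr))
  }
  coup <- dplyr::filter(aggregated, .data$connection != "not_connected")
  if (nrow(coup)) {
    lines <- c(lines, sprintf(
      "- coupled conditions: minimum per-condition mean NAL %.2f (both hands active)",
      min(c(coup$nal_l, coup$nal_r))))
    imb <- dplyr::summarise(coup, ra = mean(.data$ra_imb),
                            cc = mean(.data$cc_imb))
    lines <- c(lines, sprintf(
      "- coupled effort imbalances (left - right): RA %.3f Nm, CC %.3f Nm",
      imb$ra, imb$cc))
  }
  rho_med <- aggregated %>%
    dplyr::summarise(median_rho = median(.data$rho), .by = "connection")
  lines <- c(lines, "- median hand correlation by connection:",
             sprintf("    - %s: %.3f", rho_med$connection,
                     rho_med$median_rho))
  if (!is.null(stats)) {
    sig <- dplyr::filter(stats$results, !is.na(.data$p_raw),
                         .data$p_raw < 0.05)
    lines <- c(lines, "",
               sprintf("- inferential results: %d rows, %d with raw p < 0.05",
                       nrow(stats$results), nrow(sig)))
  }
  paste(lines, collapse = "\n")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, calibrates every participant's muscles, computes
#' per-trial and participant-level metrics, runs the scenario's
#' inferential battery, and assembles a text report. With `out_dir` set,
#' writes `manifest.csv`, `calibrations.csv`, `metrics_trials.csv`,
#' `metrics_participants.csv`, `stats_results.csv` (plus `lme_slopes.csv`
#' or `trends.csv`) and `report.md`.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a `bt_pipeline` list: `cohort`, `calibrations`,
#'   `metrics`, `aggregated`, `stats` (with `$results`, `$trends`,
#'   `$slopes`), `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "bt_pipeline_config"))
  cohort <- generate_cohort(config$scenario, config$cohort,
                            seed = config$seed, n = config$n)
  calibrations <- purrr::map2_dfr(
    cohort$participants$calibration, cohort$participants$id,
    function(cal, id) {
      dplyr::mutate(calibrate_muscles(cal), participant = id, .before = 1L)
    })
  metrics <- compute_metrics(cohort, use_emg = config$use_emg)
  aggregated <- trim_and_aggregate(metrics)

  stats <- if (config$run_stats) {
    if (config$scenario == "experiment1") {
      .exp1_stats(metrics, aggregated)
    } else {
      .exp2_stats(metrics, aggregated)
    }
  }
  report <- .pipeline_report(config, cohort, aggregated, stats)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.csv(
      x, file.path(config$out_dir, f), row.names = FALSE)
    w(cohort_manifest(cohort), "manifest.csv")
    w(calibrations, "calibrations.csv")
    w(metrics, "metrics_trials.csv")
    w(aggregated, "metrics_participants.csv")
    if (!is.null(stats)) {
      w(stats$results, "stats_results.csv")
      if (!is.null(stats$slopes)) w(stats$slopes, "lme_slopes.csv")
      if (!is.null(stats$trends)) w(stats$trends, "trends.csv")
    }
    writeLines(report, file.path(config$out_dir, "report.md"))
    if (config$write_timeseries) {
      write_dataset(cohort, file.path(config$out_dir, "dataset"))
    }
  }

  invisible(structure(
    list(config = config, cohort = cohort, calibrations = calibrations,
         metrics = metrics, aggregated = aggregated, stats = stats,
         report = report),
    class = "bt_pipeline"))
}

#' @export
print.bt_pipeline <- function(x, ...) {
  cat(x$report, "\n")
  invisible(x)
}

# file name for one trial's time series
.trial_file <- function(participant, block, trial_index) {
  sprintf("trial_%s_b%02d_t%02d.csv", participant, block, trial_index)
}

#' Write a cohort as a columnar dataset
#'
#' One CSV per trial on the 1000 Hz grid (EMG channels every row; the
#' 100 Hz angle columns filled on their native samples and `NA` between
#' them), plus `manifest.csv` naming every trial file with its condition
#' tokens, start time and seed.
#'
#' @param cohort A `bt_cohort`.
#' @param dir Output directory.
#' @return (Invisibly) the manifest with a `file` column.
#' @export
write_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort_manifest(cohort)
  manifest$file <- .trial_file(manifest$participant, manifest$block,
                               manifest$trial_index)
  for (i in seq_len(nrow(manifest))) {
    tr <- cohort$trials$trial[[i]]
    out <- tr$emg
    for (cn in c("q_l_deg", "q_r_deg", "q_target_deg")) {
      v <- rep(NA_real_, nrow(out))
      v[match(round(tr$angles$time_s, 6), round(out$time_s, 6))] <-
        tr$angles[[cn]]
      out[[cn]] <- v
    }
    out <- out[, c("time_s", "q_l_deg", "q_r_deg", "q_target_deg",
                   "emg_lf_v", "emg_le_v", "emg_rf_v", "emg_re_v")]
    utils::write.csv(out, file.path(dir, manifest$file[i]),
                     row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

.issue <- function(issue, trial, detail) {
  tibble::tibble(issue = issue, trial = trial, detail = detail)
}

#' Validate a dataset
#'
#' Diagnostic checks of a written dataset directory (or an in-memory
#' cohort): expected sample counts per grid (25,000 at 1000 Hz, 2,500 at
#' 100 Hz), strictly increasing time stamps, required columns, and the
#' condition-token vocabulary. Returns a machine-readable issue list and
#' never throws.
#'
#' @param x Dataset directory written by [write_dataset()], or a
#'   `bt_cohort`.
#' @return A tibble `issue`, `trial`, `detail`; zero rows for a pristine
#'   dataset.
#' @export
validate_dataset <- function(x) {
  issues <- list()
  push <- function(i) issues[[length(issues) + 1L]] <<- i

  check_tokens <- function(manifest) {
    bad_w <- setdiff(unique(manifest$weighting), cursor_weightings())
    bad_c <- setdiff(unique(manifest$connection), connection_levels())
    for (b in bad_w) push(.issue("vocabulary", NA_character_,
                                 paste("unknown weighting token:", b)))
    for (b in bad_c) push(.issue("vocabulary", NA_character_,
                                 paste("unknown connection token:", b)))
  }

  if (inherits(x, "bt_cohort")) {
    check_tokens(cohort_manifest(x))
    for (i in seq_len(nrow(x$trials))) {
      tr <- x$trials$trial[[i]]
      lab <- sprintf("%s b%02d t%02d", x$trials$participant[i],
                     x$trials$block[i], x$trials$trial_index[i])
      if (nrow(tr$emg) != 25000L) {
        push(.issue("sample-count", lab,
                    sprintf("EMG has %d samples, expected 25000",
                            nrow(tr$emg))))
      }
      if (nrow(tr$angles) != 2500L) {
        push(.issue("sample-count", lab,
                    sprintf("angles have %d samples, expected 2500",
                            nrow(tr$angles))))
      }
      if (is.unsorted(tr$emg$time_s, strictly = TRUE)) {
        push(.issue("time", lab, "EMG time stamps not strictly increasing"))
      }
    }
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    mf <- file.path(x, "manifest.csv")
    if (!file.exists(mf)) {
      push(.issue("manifest", NA_character_, "manifest.csv not found"))
      return(dplyr::bind_rows(issues))
    }
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
    need <- c("participant", "weighting", "connection", "trial_index",
              "t0", "seed", "file")
    miss <- setdiff(need, names(manifest))
    if (length(miss)) {
      push(.issue("columns", NA_character_,
                  paste("manifest missing:", paste(miss, collapse = ", "))))
      return(dplyr::bind_rows(issues))
    }
    check_tokens(manifest)
    cols <- c("time_s", "q_l_deg", "q_r_deg", "q_target_deg",
              "emg_lf_v", "emg_le_v", "emg_rf_v", "emg_re_v")
    for (i in seq_len(nrow(manifest))) {
      f <- file.path(x, manifest$file[i])
      lab <- manifest$file[i]
      if (!file.exists(f)) {
        push(.issue("missing-file", lab, "trial file not found"))
        next
      }
      d <- utils::read.csv(f, stringsAsFactors = FALSE)
      miss <- setdiff(cols, names(d))
      if (length(miss)) {
        push(.issue("columns", lab,
                    paste("missing:", paste(miss, collapse = ", "))))
        next
      }
      if (nrow(d) != 25000L) {
        push(.issue("sample-count", lab,
                    sprintf("%d rows, expected 25000", nrow(d))))
      }
      n_ang <- sum(!is.na(d$q_l_deg))
      if (n_ang != 2500L && nrow(d) == 25000L) {
        push(.issue("sample-count", lab,
                    sprintf("%d angle samples, expected 2500", n_ang)))
      }
      if (is.unsorted(d$time_s, strictly = TRUE)) {
        push(.issue("time", lab, "time stamps not strictly increasing"))
      }
    }
  }
  out <- dplyr::bind_rows(issues)
  if (!nrow(out)) {
    out <- tibble::tibble(issue = character(), trial = character(),
                          detail = character())
  }
  out
}
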