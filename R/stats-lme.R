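# Random-intercept mixed-effects slope models fitted by restricted maximum
# likelihood, with Satterthwaite approximate degrees of freedom: the
# workhorse for (a) the trial-number trend within blocks and (b) the
# imbalance-versus-cursor-weighting slopes of experiment 2.

#' Numeric coding of the cursor weighting
#'
#' Center is the reference (0) and right is +1; left is coded -1 so the
#' slope has a per-step meaning in either direction (the left coding is a
#' package convention, stated as such).
#'
#' @param weighting Character vector of weighting tokens.
#' @return Numeric vector in \{-1, 0, 1\}.
#' @export
code_weighting <- function(weighting) {
  map <- c(left = -1, center = 0, right = 1)
  bad <- setdiff(unique(weighting), names(map))
  if (length(bad)) {
    abort(paste0("Unknown weighting token(s): ", paste(bad, collapse = ", ")))
  }
  unname(map[weighting])
}

#' Random-intercept slope model
#'
#' Fits `dv ~ x + (1 | subject)` by REML, reporting the fixed slope and
#' intercept with Satterthwaite approximate degrees of freedom. When the
#' mixed fit is singular with at most one observation per subject (the
#' random intercept is unidentifiable), the model falls back to ordinary
#' least squares with residual degrees of freedom, with a warning; the
#' `df_method` field records which route produced the result.
#'
#' @param data A data frame.
#' @param dv Response column name.
#' @param x Numeric predictor column name (e.g. a coded weighting or the
#'   trial number).
#' @param subject Subject identifier column name.
#' @return A `bt_lme` object; see [tidy.bt_lme()] / [glance.bt_lme()].
#' @export
lme_slope <- function(data, dv, x, subject) {
  stopifnot(all(c(dv, x, subject) %in% names(data)))
  if (!is.numeric(data[[x]])) abort("`x` must be a numeric (coded) column.")
  d <- data.frame(.y = data[[dv]], .x = data[[x]],
                  .subj = factor(data[[subject]]))
  if (anyNA(d)) abort("Missing values in model columns.")
  n_per <- table(d$.subj)
  if (min(n_per) < 2L && max(n_per) < 2L) {
    # one observation per subject: the random intercept cannot be separated
    # from the residual
    return(.lme_fallback(d, dv, x,
                         "one observation per subject"))
  }

  # a constant response has slope exactly zero by definition
  if (sd(d$.y) == 0) {
    warn("Constant response: slope is exactly zero.")
    return(structure(
      list(dv = dv, x = x, intercept = d$.y[1L], slope = 0,
           intercept_se = 0, slope_se = 0,
           intercept_df = nrow(d) - 2, slope_df = nrow(d) - 2,
           intercept_t = NA_real_, slope_t = NA_real_,
           intercept_p = NA_real_, slope_p = NA_real_,
           df_method = "residual", n_obs = nrow(d),
           n_subjects = nlevels(d$.subj), sigma = 0, fit = NULL),
      class = "bt_lme"))
  }

  # a response that subject dummies + slope explain perfectly has no
  # residual variance: the mixed model is unidentifiable there
  sat <- suppressWarnings(lm(.y ~ .x + .subj, data = d))
  if (stats::sigma(sat) < max(1e-10, 1e-8 * sd(d$.y))) {
    return(.lme_fallback(d, dv, x, "zero residual variance"))
  }

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(.y ~ .x + (1 | .subj), data = d,
                                    REML = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.lme_fallback(d, dv, x, "mixed fit failed"))
  }
  if (lme4::isSingular(fit, tol = 1e-5) && max(n_per) < 2L) {
    return(.lme_fallback(d, dv, x, "singular fit"))
  }

  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(
    list(dv = dv, x = x,
         intercept = cf[1L, "Estimate"], slope = cf[2L, "Estimate"],
         intercept_se = cf[1L, "Std. Error"], slope_se = cf[2L, "Std. Error"],
         intercept_df = cf[1L, "df"], slope_df = cf[2L, "df"],
         intercept_t = cf[1L, "t value"], slope_t = cf[2L, "t value"],
         intercept_p = cf[1L, "Pr(>|t|)"], slope_p = cf[2L, "Pr(>|t|)"],
         df_method = "satterthwaite_approx",
         n_obs = nrow(d), n_subjects = nlevels(d$.subj),
         sigma = stats::sigma(fit), fit = fit),
    class = "bt_lme")
}

.lme_fallback <- function(d, dv, x, why) {
  warn(sprintf(
    "Random intercept unidentifiable (%s); falling back to ordinary regression.",
    why))
  fit <- lm(.y ~ .x, data = d)
  cf <- summary(fit)$coefficients
  df <- fit$df.residual
  structure(
    list(dv = dv, x = x,
         intercept = cf[1L, 1L], slope = cf[2L, 1L],
         intercept_se = cf[1L, 2L], slope_se = cf[2L, 2L],
         intercept_df = df, slope_df = df,
         intercept_t = cf[1L, 3L], slope_t = cf[2L, 3L],
         intercept_p = cf[1L, 4L], slope_p = cf[2L, 4L],
         df_method = "residual",
         n_obs = nrow(d), n_subjects = nlevels(d$.subj),
         sigma = summary(fit)$sigma, fit = fit),
    class = "bt_lme")
}

#' @export
print.bt_lme <- function(x, ...) {
  cat(sprintf(
    "<bt_lme> %s ~ %s + (1 | subject): s = %.4g (t(%.2f) = %.2f, p = %.3g), b = %.4g [df: %s]\n",
    x$dv, x$x, x$slope, x$slope_df, x$slope_t, x$slope_p, x$intercept,
    x$df_method))
  invisible(x)
}

#' Tidy a random-intercept slope model
#'
#' @param x A `bt_lme` object.
#' @param conf.int Add a Wald confidence interval on the approximate-t
#'   scale.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per fixed term: `term`, `estimate`,
#'   `std.error`, `df`, `statistic`, `p.value` (and bounds when
#'   `conf.int = TRUE`).
#' @export
tidy.bt_lme <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    df = c(x$intercept_df, x$slope_df),
    statistic = c(x$intercept_t, x$slope_t),
    p.value = c(x$intercept_p, x$slope_p))
  if (conf.int) {
    crit <- qt(1 - (1 - conf.level) / 2, out$df)
    out$conf.low <- out$estimate - crit * out$std.error
    out$conf.high <- out$estimate + crit * out$std.error
  }
  out
}

#' @rdname tidy.bt_lme
#' @export
glance.bt_lme <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_subjects = x$n_subjects,
                 sigma = x$sigma, df_method = x$df_method)
}

#' Trial-number trend within blocks
#'
#' Mixed-effects slope of a metric on the trial number over the first or
#' last five trials of each block - the check that performance has
#' plateaued before steady-state aggregation.
#'
#' @param metrics Per-trial metrics table ([compute_metrics()]).
#' @param dv Metric column name.
#' @param which `"first5"` or `"last5"`.
#' @param subject Subject column name.
#' @return A `bt_lme` object.
#' @export
trial_trend <- function(metrics, dv, which = c("first5", "last5"),
                        subject = "participant") {
  which <- match.arg(which)
  d <- if (which == "first5") {
    dplyr::filter(metrics, .data$trial_index <= 5)
  } else {
    dplyr::filter(metrics, .data$trial_index >= 6)
  }
  lme_slope(d, dv, "trial_index", subject)
}

#' Imbalance-versus-weighting slopes per connection group
#'
#' For each connection level, fits the random-intercept model of an
#' imbalance metric on the coded cursor weighting (left -1, center 0,
#' right +1). A negative slope means the task-relevant hand contributes
#' more when the cursor follows it.
#'
#' @param aggregated Participant-level table ([trim_and_aggregate()]).
#' @param dv Imbalance column (`"nal_imb"`, `"ra_imb"` or `"cc_imb"`).
#' @param subject Subject column name.
#' @return A tibble, one row per connection level: slope and intercept
#'   estimates with SE, approximate df, t and p, plus `df_method`.
#' @export
imbalance_slopes <- function(aggregated, dv, subject = "participant") {
  stopifnot("connection" %in% names(aggregated))
  d <- dplyr::mutate(aggregated,
                     weighting_code = code_weighting(.data$weighting))
  purrr::map_dfr(split(d, d$connection), function(g) {
    m <- lme_slope(g, dv, "weighting_code", subject)
    tibble::tibble(
      connection = g$connection[1L], dv = dv,
      slope = m$slope, slope_se = m$slope_se, slope_df = m$slope_df,
      slope_t = m$slope_t, slope_p = m$slope_p,
      intercept = m$intercept, intercept_se = m$intercept_se,
      intercept_df = m$intercept_df, intercept_t = m$intercept_t,
      intercept_p = m$intercept_p, df_method = m$df_method)
  })
}

#' Shapiro-Wilk normality screen
#'
#' Applies the Shapiro-Wilk test to a metric within each condition cell.
#' Cells must hold 3-5000 non-constant values (the test's domain);
#' degenerate cells raise an error naming the cell.
#'
#' @param data A data frame.
#' @param dv Metric column name.
#' @param by Character vector of grouping columns.
#' @return A tibble with the grouping columns, `statistic_name`
#'   (`"W_shapiro"`), `statistic` and `p_raw`.
#' @export
shapiro_screen <- function(data, dv, by) {
  stopifnot(dv %in% names(data), all(by %in% names(data)))
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::group_modify(function(d, key) {
      v <- d[[dv]]
      if (length(v) < 3L || length(v) > 5000L) {
        abort(sprintf("Shapiro-Wilk needs 3-5000 values; cell %s has %d.",
                      paste(unlist(key), collapse = "/"), length(v)))
      }
      if (var(v) <= .Machine$double.eps) {
        abort(sprintf("Shapiro-Wilk undefined for the constant cell %s.",
                      paste(unlist(key), collapse = "/")))
      }
      sw <- shapiro.test(v)
      tibble::tibble(statistic_name = "W_shapiro",
                     statistic = unname(sw$statistic),
                     p_raw = sw$p.value)
    }) %>%
    dplyr::ungroup()
}
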