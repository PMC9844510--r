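# Aligned rank transform (ART) factorial ANOVA: for each main effect and
# interaction, strip the cell-mean estimates of every *other* effect from
# the response, rank the aligned values, and run the factorial ANOVA on the
# ranks with the subject as error/blocking term. This gives nonparametric
# tests of main effects and interactions in repeated-measures and mixed
# designs.

# marginal-mean effect estimate for a subset of factors, by
# inclusion-exclusion over its sub-subsets
.art_effect_estimate <- function(data, dv, effect) {
  y <- data[[dv]]
  est <- rep(0, nrow(data))
  k <- length(effect)
  for (m in 0:k) {
    subsets <- if (m == 0) list(character(0)) else
      utils::combn(effect, m, simplify = FALSE)
    sgn <- (-1)^(k - m)
    for (s in subsets) {
      mt <- if (length(s) == 0) {
        rep(mean(y), nrow(data))
      } else {
        stats::ave(y, data[s], FUN = mean)
      }
      est <- est + sgn * mt
    }
  }
  est
}

# aligned response for one target effect: residual about the full fixed-
# factorial cell mean (and the subject effect, when a subject is given)
# plus the target effect's own estimate
.art_align <- function(data, dv, factors, effect, subject = NULL,
                       between = NULL) {
  y <- data[[dv]]
  cell_mean <- stats::ave(y, data[factors], FUN = mean)
  subj_eff <- 0
  if (!is.null(subject)) {
    subj_mean <- stats::ave(y, data[[subject]], FUN = mean)
    ref <- if (length(between)) {
      stats::ave(y, data[between], FUN = mean)
    } else {
      mean(y)
    }
    subj_eff <- subj_mean - ref
  }
  y - cell_mean - subj_eff + .art_effect_estimate(data, dv, effect)
}

# pull F, df and p for one term out of a (possibly multi-stratum) aov summary
.aov_extract <- function(fit, term) {
  smry <- summary(fit)
  tabs <- if (inherits(fit, "aovlist")) lapply(smry, function(s) s[[1L]]) else
    list(smry[[1L]])
  for (tab in tabs) {
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    if (!is.na(i)) {
      resid_row <- match("Residuals", rn)
      return(list(F = tab[i, "F value"], df1 = tab[i, "Df"],
                  df2 = tab[resid_row, "Df"], p = tab[i, "Pr(>F)"]))
    }
  }
  abort(sprintf("Term '%s' not found in the rank ANOVA.", term))
}

#' Aligned-rank-transform factorial ANOVA
#'
#' Nonparametric factorial ANOVA for repeated-measures, between-subject or
#' mixed designs. For every main effect and interaction of the supplied
#' factors, the response is aligned (all other effects' cell-mean estimates
#' subtracted, and the per-subject offset removed when a subject column is
#' given), ranked with average ranks on ties, and submitted to a full
#' factorial ANOVA on the ranks with the subject as the error term for
#' within-subject factors; only the target effect's row is reported from
#' each aligned fit.
#'
#' The design must be complete and balanced within subjects: every subject
#' contributes the same number of observations to each within-subject
#' cell, and every between-subject group has at least two subjects.
#'
#' @param data A data frame in long format.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param between Character vector of between-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return A tibble with one row per effect: `effect`, `statistic_name`
#'   (`"F"`), `statistic`, `df1`, `df2`, `p_raw`.
#' @export
art_anova <- function(data, dv, within = NULL, between = NULL, subject) {
  factors <- c(within, between)
  stopifnot(length(factors) >= 1L, dv %in% names(data),
            all(factors %in% names(data)), subject %in% names(data))
  data <- as.data.frame(data)
  for (f in c(factors, subject)) data[[f]] <- factor(data[[f]])
  if (anyNA(data[[dv]])) abort("Response contains missing values.")

  # balance checks
  if (length(within)) {
    per_cell <- table(data[[subject]],
                      interaction(data[within], drop = FALSE))
    if (length(unique(as.vector(per_cell))) != 1L) {
      abort("Unbalanced design: subjects differ in within-cell counts.")
    }
  }
  if (length(between)) {
    grp <- unique(data[c(subject, between)])
    n_per <- table(interaction(grp[between], drop = FALSE))
    if (any(n_per < 2L)) {
      abort("At least 2 subjects per between-subject cell are required.")
    }
  }

  fixed <- paste(factors, collapse = " * ")
  err <- if (length(within)) {
    sprintf(" + Error(%s/(%s))", subject, paste(within, collapse = " * "))
  } else {
    ""
  }

  effects <- unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)

  purrr::map_dfr(effects, function(eff) {
    data$.aligned_rank <- rank(.art_align(data, dv, factors, eff,
                                          subject = subject,
                                          between = between))
    fml <- stats::as.formula(paste0(".aligned_rank ~ ", fixed, err))
    fit <- suppressWarnings(aov(fml, data = data))
    res <- .aov_extract(fit, paste(eff, collapse = ":"))
    tibble::tibble(effect = paste(eff, collapse = ":"),
                   statistic_name = "F", statistic = res$F,
                   df1 = res$df1, df2 = res$df2, p_raw = res$p)
  })
}

#' Aligned (unranked) response for one effect
#'
#' Diagnostic access to the alignment stage of [art_anova()]: after
#' aligning for a target effect, a factorial ANOVA on the *unranked*
#' aligned response should show (near-)zero sums of squares for every
#' other effect - the standard correctness check for an ART
#' implementation.
#'
#' @inheritParams art_anova
#' @param effect Character vector naming the target effect's factors.
#' @return Numeric vector of aligned responses, one per row of `data`.
#' @export
art_align <- function(data, dv, within = NULL, between = NULL, subject,
                      effect) {
  factors <- c(within, between)
  data <- as.data.frame(data)
  for (f in c(factors, subject)) data[[f]] <- factor(data[[f]])
  .art_align(data, dv, factors, effect, subject = subject,
             between = between)
}
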