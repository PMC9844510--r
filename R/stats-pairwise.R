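# Nonparametric pairwise comparisons and multiplicity control. W (signed
# rank) and U (rank sum) are reported together with the tie-corrected
# normal-approximation Z, as is conventional for these designs; zero
# differences are dropped (classic signed-rank convention) and ties get
# average ranks.

#' Wilcoxon signed-rank test (paired)
#'
#' Computes W (sum of positive ranks of the non-zero paired differences,
#' average ranks on ties), the tie-corrected normal-approximation Z and
#' the two-sided p-value. All-zero differences make the test undefined:
#' the result is flagged rather than silently reported as p = 1.
#'
#' @param x,y Paired samples (equal length).
#' @return One-row tibble: `statistic_name` (`"W"`), `statistic`, `z`,
#'   `p_raw`, `n_effective` (pairs after zero-dropping), `undefined`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("Wilcoxon signed-rank undefined: all paired differences are zero.")
    return(tibble::tibble(statistic_name = "W", statistic = NA_real_,
                          z = NA_real_, p_raw = NA_real_,
                          n_effective = 0L, undefined = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else NA_real_
  p <- if (is.na(z)) NA_real_ else min(1, 2 * pnorm(-abs(z)))
  tibble::tibble(statistic_name = "W", statistic = w, z = z, p_raw = p,
                 n_effective = n, undefined = is.na(z))
}

#' Mann-Whitney U test (unpaired)
#'
#' Rank-sum comparison of two independent samples: U for the first sample,
#' tie-corrected normal-approximation Z, and the two-sided p-value.
#'
#' @param x,y Independent samples.
#' @return One-row tibble: `statistic_name` (`"U"`), `statistic`, `z`,
#'   `p_raw`, `n_effective`, `undefined`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else NA_real_
  p <- if (is.na(z)) NA_real_ else min(1, 2 * pnorm(-abs(z)))
  if (is.na(z)) warn("Mann-Whitney undefined: all values tie.")
  tibble::tibble(statistic_name = "U", statistic = u, z = z, p_raw = p,
                 n_effective = n, undefined = is.na(z))
}

#' Multiplicity adjustment
#'
#' Hommel closed-testing or Benjamini-Hochberg step-up adjustment (thin
#' validated wrappers over [stats::p.adjust()]). By the analysis
#' convention, Hommel is used for families of up to 24 comparisons and
#' Benjamini-Hochberg for larger families; [choose_correction()] encodes
#' that rule.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"hommel"` or `"bh"`.
#' @return Adjusted p-values (monotone, >= raw, clipped to `[0, 1]`).
#'   `NA`s are passed through.
#' @export
adjust_pvalues <- function(p, method = c("hommel", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = c(hommel = "hommel", bh = "BH")[[method]])
}

#' @rdname adjust_pvalues
#' @param k Family size (number of comparisons).
#' @export
choose_correction <- function(k) if (k > 24) "bh" else "hommel"

# run one paired/unpaired comparison and label it
.one_comparison <- function(d1, d2, label, paired) {
  res <- if (paired) wilcoxon_signed_rank(d1, d2) else mann_whitney_u(d1, d2)
  dplyr::mutate(res, effect = label, .before = 1L)
}

#' Tailored pairwise comparison families
#'
#' The three post-hoc families of the analysis:
#' \describe{
#'   \item{`within_cursor`}{cursor-weighting pairs within each connection
#'     level (always paired: weightings are within-subject).}
#'   \item{`across_connection`}{connection-level pairs within each cursor
#'     weighting; paired when connection is within-subject (experiment 1),
#'     unpaired across groups (experiment 2).}
#'   \item{`left_vs_right`}{left- versus right-hand values of a per-hand
#'     metric for every weighting x connection cell (always paired).}
#' }
#' Raw p-values are adjusted within the family, using Hommel up to 24
#' comparisons and Benjamini-Hochberg beyond.
#'
#' @param data Participant-level metrics ([trim_and_aggregate()]).
#' @param dv Metric column; for `left_vs_right`, the metric stem
#'   (`"nal"`, `"ra"` or `"cc"`) whose `_l`/`_r` columns are compared.
#' @param family One of `"within_cursor"`, `"across_connection"`,
#'   `"left_vs_right"`.
#' @param paired Paired comparisons (`across_connection` only; the other
#'   families are inherently paired).
#' @param subject Subject column name.
#' @return A tibble, one row per comparison: `analysis`, `effect`,
#'   `statistic_name`, `statistic`, `z`, `p_raw`, `p_adj`, `correction`.
#' @export
pairwise_family <- function(data, dv,
                            family = c("within_cursor", "across_connection",
                                       "left_vs_right"),
                            paired = TRUE, subject = "participant") {
  family <- match.arg(family)
  res <- switch(
    family,
    within_cursor = {
      purrr::map_dfr(split(data, data$connection), function(g) {
        combos <- utils::combn(sort(unique(g$weighting)), 2, simplify = FALSE)
        purrr::map_dfr(combos, function(pr) {
          wide <- tidyr::pivot_wider(
            g[, c(subject, "weighting", dv)],
            names_from = "weighting", values_from = dplyr::all_of(dv))
          .one_comparison(wide[[pr[1L]]], wide[[pr[2L]]],
                          sprintf("%s: %s vs %s", g$connection[1L],
                                  pr[1L], pr[2L]),
                          paired = TRUE)
        })
      })
    },
    across_connection = {
      purrr::map_dfr(split(data, data$weighting), function(g) {
        combos <- utils::combn(sort(unique(g$connection)), 2,
                               simplify = FALSE)
        purrr::map_dfr(combos, function(pr) {
          if (paired) {
            wide <- tidyr::pivot_wider(
              g[, c(subject, "connection", dv)],
              names_from = "connection", values_from = dplyr::all_of(dv))
            .one_comparison(wide[[pr[1L]]], wide[[pr[2L]]],
                            sprintf("%s: %s vs %s", g$weighting[1L],
                                    pr[1L], pr[2L]),
                            paired = TRUE)
          } else {
            .one_comparison(g[[dv]][g$connection == pr[1L]],
                            g[[dv]][g$connection == pr[2L]],
                            sprintf("%s: %s vs %s", g$weighting[1L],
                                    pr[1L], pr[2L]),
                            paired = FALSE)
          }
        })
      })
    },
    left_vs_right = {
      col_l <- paste0(dv, "_l"); col_r <- paste0(dv, "_r")
      stopifnot(all(c(col_l, col_r) %in% names(data)))
      cells <- dplyr::distinct(data, .data$weighting, .data$connection)
      purrr::map_dfr(seq_len(nrow(cells)), function(i) {
        g <- data[data$weighting == cells$weighting[i] &
                    data$connection == cells$connection[i], ]
        .one_comparison(g[[col_l]], g[[col_r]],
                        sprintf("%s/%s: left vs right", cells$weighting[i],
                                cells$connection[i]),
                        paired = TRUE)
      })
    })

  method <- choose_correction(nrow(res))
  res %>%
    dplyr::mutate(analysis = family, .before = 1L) %>%
    dplyr::mutate(p_adj = adjust_pvalues(.data$p_raw, method),
                  correction = method)
}
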