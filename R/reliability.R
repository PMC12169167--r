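#' Test-retest reliability statistics
#'
#' Reliability of a measurement repeated in two sessions
#' (familiarisation and baseline) on the same participants:
#' ICC(3,1), typical error, and coefficient of variation.
#'
#' @name reliability
NULL

as_retest <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stopf("retest table must be numeric with exactly 2 session columns")
  }
  if (anyNA(m)) stopf("retest table must have no missing cells")
  if (nrow(m) < 3L) stopf("need at least 3 participants")
  m
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measure intraclass
#' correlation (Shrout-Fleiss model 3,1):
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`, with
#' mean squares from the two-way subject x session decomposition
#' (`k = 2` sessions here). Consistency means a constant shift between
#' sessions does not lower the coefficient.
#'
#' @param table participants x 2 matrix or data.frame of the outcome in
#'   the two sessions.
#' @return list with `icc`, `ms_subjects`, `ms_sessions`, `ms_error`,
#'   `n`, `k`, and `flagged` (TRUE when between-subject variance does
#'   not exceed error variance, i.e. `icc <= 0`).
#' @export
icc_3_1 <- function(table) {
  m <- as_retest(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ms_subj <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  ms_sess <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  resid <- m - outer(rowMeans(m), rep(1, k)) -
    outer(rep(1, n), colMeans(m)) + grand
  ms_err <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- if (ms_subj + (k - 1) * ms_err > 0) {
    (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
  } else NA_real_
  list(icc = icc, ms_subjects = ms_subj, ms_sessions = ms_sess,
       ms_error = ms_err, n = n, k = k,
       flagged = !is.finite(icc) || icc <= 0)
}

#' Typical error of measurement
#'
#' Within-subject test-retest error: the standard deviation of the
#' between-session differences divided by sqrt(2), in outcome units.
#'
#' @inheritParams icc_3_1
#' @return typical error (outcome units).
#' @export
typical_error <- function(table) {
  m <- as_retest(table)
  stats::sd(m[, 2] - m[, 1]) / sqrt(2)
}

#' Coefficient of variation of measurement
#'
#' `100 * typical_error / grand mean` of all observations, in percent.
#'
#' @inheritParams icc_3_1
#' @return CV, percent.
#' @export
coefficient_of_variation <- function(table) {
  m <- as_retest(table)
  g <- mean(m)
  if (abs(g) < sqrt(.Machine$double.eps)) stopf("grand mean is zero; CV undefined")
  100 * typical_error(m) / g
}

#' One-row reliability summary of a retest table
#'
#' @inheritParams icc_3_1
#' @param outcome label for the measured quantity.
#' @return data.frame with columns `outcome`, `n`, `icc`, `te`,
#'   `cv_percent`.
#' @export
reliability_summary <- function(table, outcome = "outcome") {
  m <- as_retest(table)
  data.frame(outcome = outcome, n = nrow(m),
             icc = icc_3_1(m)$icc,
             te = typical_error(m),
             cv_percent = coefficient_of_variation(m))
}
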