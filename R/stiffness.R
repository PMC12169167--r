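#' Pair tendon force with elongation over the loading phase
#'
#' For each ultrasound frame `t` (0-based), the tendon force is read at
#' force sample `trigger_index + round(t * rate / frame_rate)`. The
#' paired samples are then restricted to the monotonically loading
#' phase: from force onset (first frame at or above `onset_frac` of the
#' trial peak) to the peak-force frame.
#'
#' @param force a [force_trace()] whose samples are tendon force, N
#'   (see [tendon_force_trace()]), with the trigger set.
#' @param elong an `elongation_series` from [elongation_from_tracks()]
#'   covering the loading ramp.
#' @param frame_rate ultrasound frame rate, Hz.
#' @param onset_frac onset threshold as a fraction of the trial peak
#'   force (default 0.05).
#' @return an object of class `fe_trial` with fields `force`,
#'   `elongation` (loading-phase pairs), `peak_force`, and empty fit
#'   slots (see [fit_trial()]).
#' @export
pair_force_elongation <- function(force, elong, frame_rate,
                                  onset_frac = 0.05) {
  stopifnot(inherits(force, "force_trace"),
            inherits(elong, "elongation_series"))
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  n_frames <- length(elong$values)
  if (n_frames < 2L) stopf("need at least two frames of elongation")
  idx <- force$trigger_index +
    round((seq_len(n_frames) - 1L) * force$rate / frame_rate)
  if (any(idx > length(force$samples))) {
    stopf("frames extend past the end of the force record")
  }
  f <- force$samples[idx]
  e <- elong$values
  i_peak <- which.max(f)
  if (i_peak < 2L) stopf("no loading phase: force peaks at the first frame")
  onset <- f[i_peak] * onset_frac
  i_on <- which(f[seq_len(i_peak)] >= onset)[1]
  if (is.na(i_on) || i_peak - i_on < 1L) stopf("zero-length loading phase")
  keep <- i_on:i_peak
  structure(list(force = f[keep], elongation = e[keep],
                 peak_force = f[i_peak],
                 fit = NULL, r2 = NA_real_, included = NA),
            class = "fe_trial")
}

#' Construct a force-elongation trial from raw paired samples
#'
#' Convenience constructor used when force and elongation pairs are
#' already assembled (e.g. read from disk).
#'
#' @param force,elongation equal-length numeric vectors (N, mm).
#' @return an `fe_trial`.
#' @export
fe_trial <- function(force, elongation) {
  if (length(force) != length(elongation)) {
    stopf("force and elongation must have equal length")
  }
  structure(list(force = as.numeric(force),
                 elongation = as.numeric(elongation),
                 peak_force = max(force),
                 fit = NULL, r2 = NA_real_, included = NA),
            class = "fe_trial")
}

#' Trial inclusion rule on fit quality
#'
#' A trial is retained when the coefficient of determination of its
#' quadratic fit is at least `r2_min`; only fits strictly below the
#' threshold are excluded.
#'
#' @param r2 coefficient of determination.
#' @param r2_min inclusion threshold (default 0.90).
#' @return logical.
#' @export
trial_included <- function(r2, r2_min = 0.90) {
  !is.na(r2) & r2 >= r2_min
}

#' Resample and fit a quadratic to a force-elongation trial
#'
#' The loading-phase pairs are resampled to `resample_n` points evenly
#' spaced in force from 0 to the trial peak (elongation linearly
#' interpolated; the rest point (0 N, 0 mm) anchors the curve below the
#' onset threshold, consistent with the zero-referenced elongation
#' definition). A least-squares 2nd-degree polynomial of force as a
#' function of elongation, `F = A e^2 + B e + C` (unconstrained), is
#' fitted to the resampled pairs; the coefficient of determination is
#' computed on those points and the inclusion flag set by
#' [trial_included()].
#'
#' @param trial an `fe_trial`.
#' @param resample_n number of resampled points (default 100).
#' @param r2_min inclusion threshold on the fit R^2 (default 0.90).
#' @return the trial with `fit` (coefficients `A`, `B`, `C`), `r2`,
#'   `included`, and `resampled` (data.frame of the force grid and
#'   interpolated elongation) filled.
#' @export
fit_trial <- function(trial, resample_n = 100L, r2_min = 0.90) {
  stopifnot(inherits(trial, "fe_trial"))
  if (length(trial$force) < 10L) {
    stopf("need at least 10 loading-phase pairs to fit a trial")
  }
  if (diff(range(trial$force)) < sqrt(.Machine$double.eps) * max(abs(trial$force), 1)) {
    stopf("degenerate trial: force is constant")
  }
  f <- c(0, trial$force)
  e <- c(0, trial$elongation)
  o <- order(f)
  grid <- seq(0, trial$peak_force, length.out = resample_n)
  e_rs <- stats::approx(f[o], e[o], xout = grid, ties = mean, rule = 2)$y
  X <- cbind(e_rs^2, e_rs, 1)
  beta <- qr.solve(X, grid)
  pred <- drop(X %*% beta)
  ss_res <- sum((grid - pred)^2)
  ss_tot <- sum((grid - mean(grid))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  trial$fit <- c(A = beta[[1]], B = beta[[2]], C = beta[[3]])
  trial$r2 <- r2
  trial$included <- trial_included(r2, r2_min)
  trial$resampled <- data.frame(force = grid, elongation = e_rs)
  trial
}

# Elongation at given force levels on a fitted trial curve: inverts the
# quadratic F = A e^2 + B e + C, picking the root on the branch the data
# occupy (nearest to the linearly interpolated resampled curve).
eval_trial_curve <- function(trial, force) {
  stopifnot(!is.null(trial$fit))
  a <- trial$fit[["A"]]; b <- trial$fit[["B"]]; c0 <- trial$fit[["C"]]
  guess <- stats::approx(trial$resampled$force, trial$resampled$elongation,
                         xout = force, rule = 2, ties = mean)$y
  scale_f <- max(abs(force), abs(b) * max(abs(trial$resampled$elongation)), 1)
  if (abs(a) * max(trial$resampled$elongation)^2 < 1e-10 * scale_f) {
    return((force - c0) / b)
  }
  disc <- b^2 - 4 * a * (c0 - force)
  if (any(disc < 0)) {
    # force beyond the fitted parabola's reach: clamp at the vertex
    disc <- pmax(disc, 0)
  }
  r1 <- (-b + sqrt(disc)) / (2 * a)
  r2 <- (-b - sqrt(disc)) / (2 * a)
  ifelse(abs(r1 - guess) <= abs(r2 - guess), r1, r2)
}

#' Common force level across the two sessions of one participant
#'
#' The lowest peak force observed over all included trials of either
#' session; both sessions' curves are later evaluated up to this level
#' so pre and post stiffness are compared over the same force range.
#'
#' @param peaks_pre,peaks_post numeric vectors of included-trial peak
#'   forces, N.
#' @return the common force, N.
#' @export
common_force <- function(peaks_pre, peaks_post) {
  if (length(peaks_pre) == 0L || length(peaks_post) == 0L) {
    stopf("a session has no included trials; participant flagged")
  }
  min(c(peaks_pre, peaks_post))
}

#' Mean force-elongation curve over included trials
#'
#' Each included trial's fitted quadratic is evaluated on a grid of
#' `n_grid` force levels from 0 to the common force; elongations are
#' averaged pointwise.
#'
#' @param trials list of fitted, included `fe_trial`s.
#' @param common_force common force level, N.
#' @param n_grid grid size (default 100).
#' @return an object of class `mean_curve`: list with `force_grid`,
#'   `elongation`, `common_force`, `n_trials`.
#' @export
mean_curve <- function(trials, common_force, n_grid = 100L) {
  trials <- Filter(function(tr) isTRUE(tr$included), trials)
  if (length(trials) == 0L) stopf("no included trials")
  grid <- seq(0, common_force, length.out = n_grid)
  el <- rowMeans(vapply(trials, eval_trial_curve, numeric(n_grid),
                        force = grid))
  structure(list(force_grid = grid, elongation = el,
                 common_force = common_force, n_trials = length(trials)),
            class = "mean_curve")
}

#' Tendon stiffness as the 60-100 % slope of the mean curve
#'
#' Ordinary least-squares slope of force against elongation over the
#' grid points whose force lies in `[lower_frac, 1] x common_force`
#' (default 60-100 %), in N/mm. A negative or undefined slope, or
#' non-monotonic elongation over the range, is flagged.
#'
#' @param curve a [mean_curve()].
#' @param lower_frac lower bound of the analysis range as a fraction of
#'   the common force (default 0.6).
#' @return an object of class `stiffness_result`: list with
#'   `stiffness` (N/mm), `analysis_range` (N), `n_trials_used`, `flagged`.
#' @export
stiffness_slope <- function(curve, lower_frac = 0.6) {
  stopifnot(inherits(curve, "mean_curve"))
  sel <- curve$force_grid >= lower_frac * curve$common_force - 1e-9
  f <- curve$force_grid[sel]
  e <- curve$elongation[sel]
  ve <- sum((e - mean(e))^2)
  slope <- if (ve > 0) sum((e - mean(e)) * (f - mean(f))) / ve else NA_real_
  flagged <- !is.finite(slope) || slope <= 0 || any(diff(e) <= 0)
  structure(list(stiffness = slope,
                 analysis_range = c(lower_frac, 1) * curve$common_force,
                 n_trials_used = curve$n_trials,
                 flagged = flagged),
            class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result> %.1f N/mm over %.0f-%.0f N (%d trials)%s\n",
              x$stiffness, x$analysis_range[1], x$analysis_range[2],
              x$n_trials_used, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}
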