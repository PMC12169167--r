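#' Moment arms converting cuff force to tendon force
#'
#' The external arm is the lever from the cuff mid-width to the knee
#' rotational axis; the internal arm is the perpendicular distance from
#' the patellar tendon's frontal edge to the lateral epicondyle. Both are
#' per-participant constants (the internal arm is reused pre/post, as it
#' is not expected to change with training).
#'
#' @param external_arm metres.
#' @param internal_arm metres; must be smaller than the external arm.
#' @return an object of class `moment_arms`.
#' @export
moment_arms <- function(external_arm, internal_arm) {
  assert_scalar_num(external_arm, "external_arm", positive = TRUE)
  assert_scalar_num(internal_arm, "internal_arm", positive = TRUE)
  if (internal_arm >= external_arm) stopf("internal_arm must be < external_arm")
  structure(list(external_arm = external_arm, internal_arm = internal_arm),
            class = "moment_arms")
}

#' Zero-phase lowpass filtering of a force trace
#'
#' Applies a Butterworth lowpass forward and backward (zero phase, so the
#' filtered force stays aligned with the ultrasound frames). The signal
#' is extended by reflection at both ends before filtering to suppress
#' edge transients at the ramp boundaries, then trimmed back; length and
#' trigger index are preserved.
#'
#' @param trace a [force_trace()].
#' @param cutoff cutoff frequency, Hz (default 30). Must be below the
#'   Nyquist frequency.
#' @param order filter order (default 4).
#' @return a filtered [force_trace()].
#' @export
lowpass_filter <- function(trace, cutoff = 30, order = 4) {
  stopifnot(inherits(trace, "force_trace"))
  assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= trace$rate / 2) {
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, trace$rate / 2)
  }
  x <- trace$samples
  n <- length(x)
  bf <- signal::butter(order, cutoff / (trace$rate / 2), type = "low")
  npad <- min(n - 1L, 12L * ceiling(trace$rate / cutoff))
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(bf, xp)[(npad + 1L):(npad + n)]
  force_trace(y, trace$rate, trace$trigger_index)
}

#' Knee-extension moment from the cuff force
#'
#' @param trace a (typically filtered) [force_trace()] of cuff force, N.
#' @param arms a [moment_arms()].
#' @return numeric vector of knee-extension moment, N·m.
#' @export
knee_moment <- function(trace, arms) {
  stopifnot(inherits(trace, "force_trace"), inherits(arms, "moment_arms"))
  trace$samples * arms$external_arm
}

#' Tendon force from the knee-extension moment
#'
#' @param moment numeric vector of knee-extension moment, N·m.
#' @param arms a [moment_arms()].
#' @return numeric vector of patellar tendon force, N.
#' @export
tendon_force <- function(moment, arms) {
  stopifnot(inherits(arms, "moment_arms"))
  if (arms$internal_arm <= 0) stopf("internal_arm must be > 0")
  moment / arms$internal_arm
}

#' Full cuff-force-to-tendon-force conditioning chain
#'
#' Lowpass-filters the raw cuff force and converts it to tendon force via
#' the external and internal moment arms, preserving sampling metadata.
#'
#' @inheritParams lowpass_filter
#' @param arms a [moment_arms()].
#' @return a [force_trace()] whose samples are tendon force, N.
#' @export
tendon_force_trace <- function(trace, arms, cutoff = 30, order = 4) {
  filt <- lowpass_filter(trace, cutoff = cutoff, order = order)
  force_trace(tendon_force(knee_moment(filt, arms), arms),
              filt$rate, filt$trigger_index)
}
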