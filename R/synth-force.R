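#' Force-trace container
#'
#' A single-channel force recording (cuff force at the strain gauge, N)
#' with its sampling rate and the trigger sample that aligns ultrasound
#' frame 0 with the force record.
#'
#' @param samples numeric vector, N.
#' @param rate sampling rate, Hz.
#' @param trigger_index 1-based sample index of the ramp onset (frame 0).
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(samples, rate, trigger_index = 1L) {
  assert_scalar_num(rate, "rate", positive = TRUE)
  trigger_index <- as.integer(trigger_index)
  if (trigger_index < 1L || trigger_index > length(samples)) {
    stopf("trigger_index out of bounds")
  }
  structure(list(samples = as.numeric(samples), rate = rate,
                 trigger_index = trigger_index),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz, trigger at %d, peak %.1f N\n",
              length(x$samples), x$rate, x$trigger_index, max(x$samples)))
  invisible(x)
}

#' Simulate the cuff-force recording of a ramped isometric contraction
#'
#' The knee-extension moment rises linearly at `moment_ramp_rate` from 0
#' to `peak_moment`, then holds briefly; the recorded channel is the cuff
#' force, i.e. moment divided by the external moment arm. A zero-force
#' lead-in of `lead_in_s` seconds precedes the ramp and the trigger index
#' marks the ramp onset. Gaussian sensor noise of SD `noise_force_sd` is
#' added to every sample.
#'
#' @param spec a [trial_spec()].
#' @param hold_s seconds the peak is held after the ramp (default 0.2).
#' @return a [force_trace()]; attribute `true_samples` carries the
#'   noise-free channel.
#' @export
generate_force_trace <- function(spec, hold_s = 0.2) {
  stopifnot(inherits(spec, "trial_spec"))
  rate <- spec$force_rate
  ramp_T <- spec$peak_moment / spec$moment_ramp_rate
  n_lead <- round(spec$lead_in_s * rate)
  n_ramp <- round(ramp_T * rate)            # samples strictly before peak
  n_hold <- round(hold_s * rate)
  t_ramp <- seq_len(n_ramp + 1L) - 1L       # 0 .. ramp_T inclusive
  moment <- c(rep(0, n_lead),
              spec$moment_ramp_rate * t_ramp / rate,
              rep(spec$peak_moment, n_hold))
  clean <- moment / spec$external_arm
  noisy <- if (spec$noise_force_sd > 0) {
    with_seed(spec$seed, clean + stats::rnorm(length(clean), 0, spec$noise_force_sd))
  } else clean
  tr <- force_trace(noisy, rate, trigger_index = n_lead + 1L)
  attr(tr, "true_samples") <- clean
  tr
}
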