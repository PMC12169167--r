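#' Specification of a synthetic ramped-contraction trial
#'
#' Bundles every parameter needed to simulate one isometric knee-extension
#' trial: the torque ramp recorded by the dynamometer, the moment arms that
#' convert cuff force to tendon force, the tendon's true force-elongation
#' law, and the imaging geometry of the synthetic B-mode frame stack.
#'
#' The tendon is modelled as monotonically stiffening, with tendon force
#' `F = a * e^2 + b * e` (force in N, elongation `e` in mm). With `a >= 0`
#' and `b > 0` the law is invertible for all `F >= 0`, which the frame
#' generator uses to place the patella-apex landmark.
#'
#' @param peak_moment peak knee-extension moment, N·m.
#' @param moment_ramp_rate ramp slope of the moment, N·m/s. Default 70,
#'   the target loading rate of the protocol.
#' @param external_arm cuff-to-knee-axis lever, m.
#' @param internal_arm patellar-tendon internal moment arm, m.
#' @param curve_a,curve_b true force-elongation coefficients (N/mm^2, N/mm).
#' @param frame_rate ultrasound frame rate, Hz (default 50).
#' @param force_rate force sampling rate, Hz (default 1000).
#' @param pixel_scale image scale, mm per pixel (default 0.1).
#' @param noise_force_sd additive Gaussian noise on the cuff force, N
#'   (default 3 N, a realistic strain-gauge noise floor).
#' @param noise_image_sd additive Gaussian image noise, intensity units
#'   (images are rendered on a 0-255 scale; default 3, about 1 % of full
#'   scale).
#' @param seed integer seed making the whole trial reproducible.
#' @param image_size `c(rows, cols)` of the synthetic frames.
#' @param rest_length_px apex-to-plateau distance at rest, pixels.
#' @param lead_in_s seconds of zero-force baseline recorded before the
#'   ramp onset (the trigger).
#' @return an object of class `trial_spec`.
#' @export
trial_spec <- function(peak_moment,
                       moment_ramp_rate = 70,
                       external_arm = 0.40,
                       internal_arm = 0.0355,
                       curve_a = 200,
                       curve_b = 500,
                       frame_rate = 50,
                       force_rate = 1000,
                       pixel_scale = 0.1,
                       noise_force_sd = 3,
                       noise_image_sd = 3,
                       seed = 1L,
                       image_size = c(96L, 224L),
                       rest_length_px = 100,
                       lead_in_s = 0.2) {
  assert_scalar_num(peak_moment, "peak_moment", positive = TRUE)
  assert_scalar_num(moment_ramp_rate, "moment_ramp_rate", positive = TRUE)
  assert_scalar_num(external_arm, "external_arm", positive = TRUE)
  assert_scalar_num(internal_arm, "internal_arm", positive = TRUE)
  assert_scalar_num(curve_a, "curve_a", nonneg = TRUE)
  assert_scalar_num(curve_b, "curve_b", positive = TRUE)
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  assert_scalar_num(force_rate, "force_rate", positive = TRUE)
  assert_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  assert_scalar_num(noise_force_sd, "noise_force_sd", nonneg = TRUE)
  assert_scalar_num(noise_image_sd, "noise_image_sd", nonneg = TRUE)
  if (internal_arm >= external_arm) {
    stopf("internal_arm must be smaller than external_arm")
  }
  structure(
    list(peak_moment = peak_moment, moment_ramp_rate = moment_ramp_rate,
         external_arm = external_arm, internal_arm = internal_arm,
         curve_a = curve_a, curve_b = curve_b,
         frame_rate = frame_rate, force_rate = force_rate,
         pixel_scale = pixel_scale,
         noise_force_sd = noise_force_sd, noise_image_sd = noise_image_sd,
         seed = as.integer(seed),
         image_size = as.integer(image_size),
         rest_length_px = rest_length_px, lead_in_s = lead_in_s),
    class = "trial_spec")
}

#' Invert the quadratic force-elongation law
#'
#' Solves `F = a e^2 + b e` for the elongation `e >= 0` (mm) at tendon
#' force `F >= 0` (N).
#'
#' @param force tendon force, N (vectorised).
#' @param a,b curve coefficients (N/mm^2, N/mm), `a >= 0`, `b > 0`.
#' @return elongation, mm.
#' @export
invert_curve <- function(force, a, b) {
  if (any(force < -sqrt(.Machine$double.eps))) {
    stopf("force must be non-negative to invert the loading curve")
  }
  force <- pmax(force, 0)
  if (a == 0) return(force / b)
  (-b + sqrt(b^2 + 4 * a * force)) / (2 * a)
}

#' Specification of a synthetic pre/post training cohort
#'
#' Describes a two-group (combined-oral-contraceptive users, OC, versus
#' eumenorrheic non-users, NOC) pre/post design with subject random
#' effects, a training main effect and an optional group x training
#' interaction, optionally replicated over three measurement sites along
#' the tendon.
#'
#' The generated outcome for subject *s* of group *g* at time *t* and
#' location *l* is
#' `mu_baseline + u_s + t * training_effect + t * g * interaction_effect
#'  + offset_l + eps`,
#' with `t` coded 0 (pre) / 1 (post), `g` coded 0 (OC) / 1 (NOC),
#' `u_s ~ N(0, sd_between)` and `eps ~ N(0, sd_within)` drawn per
#' observation. The group difference in the post-minus-pre change
#' therefore equals `interaction_effect` exactly in expectation.
#'
#' @param n_per_group length-2 integer vector `c(n_OC, n_NOC)`.
#' @param mu_baseline baseline mean, outcome units.
#' @param sd_between between-subject SD, outcome units.
#' @param training_effect training main effect, outcome units.
#' @param interaction_effect group x training interaction, outcome units.
#' @param sd_within residual (within-subject, per observation) SD.
#' @param n_locations 1 or 3 measurement sites.
#' @param location_offsets site offsets, outcome units (length
#'   `n_locations`).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(15L, 17L),
                        mu_baseline = 100,
                        sd_between = 10,
                        training_effect = 0,
                        interaction_effect = 0,
                        sd_within = 5,
                        n_locations = 1L,
                        location_offsets = NULL,
                        seed = 1L) {
  n_per_group <- as.integer(rep_len(n_per_group, 2L))
  if (any(n_per_group < 2L)) stopf("need at least 2 participants per group")
  assert_scalar_num(sd_between, "sd_between", nonneg = TRUE)
  assert_scalar_num(sd_within, "sd_within", nonneg = TRUE)
  n_locations <- as.integer(n_locations)
  if (!n_locations %in% c(1L, 3L)) stopf("n_locations must be 1 or 3")
  if (is.null(location_offsets)) location_offsets <- rep(0, n_locations)
  if (length(location_offsets) != n_locations) {
    stopf("location_offsets must have length n_locations")
  }
  structure(
    list(n_per_group = n_per_group, mu_baseline = mu_baseline,
         sd_between = sd_between, training_effect = training_effect,
         interaction_effect = interaction_effect, sd_within = sd_within,
         n_locations = n_locations, location_offsets = location_offsets,
         seed = as.integer(seed)),
    class = "cohort_spec")
}
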