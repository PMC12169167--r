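# Shared fixtures: synthetic trials run through the measurement chain,
# and independent oracles used across test files.

default_arms <- function() moment_arms(0.40, 0.0355)

# Brute-force analytic oracle for the 60-100 % stiffness slope: OLS line
# slope of F against e(F) on a dense grid of the true curve.
oracle_slope <- function(a, b, fc, lower = 0.6, n = 20000L) {
  f <- seq(lower * fc, fc, length.out = n)
  e <- invert_curve(f, a, b)
  sum((e - mean(e)) * (f - mean(f))) / sum((e - mean(e))^2)
}

# Generate one trial and run it through tracking -> elongation ->
# pairing -> fitting. Returns everything the tests inspect.
synth_tracked_trial <- function(noise_force_sd = 0, noise_image_sd = 0,
                                seed = 1L, peak_moment = 140,
                                frame_rate = 50, curve_a = 200,
                                curve_b = 500, arms = default_arms(),
                                rigid_translation = NULL) {
  sp <- trial_spec(peak_moment = peak_moment,
                   external_arm = arms$external_arm,
                   internal_arm = arms$internal_arm,
                   curve_a = curve_a, curve_b = curve_b,
                   frame_rate = frame_rate,
                   noise_force_sd = noise_force_sd,
                   noise_image_sd = noise_image_sd, seed = seed)
  force <- generate_force_trace(sp)
  fs <- generate_frame_sequence(sp, force, rigid_translation = rigid_translation)
  apex <- track_landmark(fs$frames, fs$apex_truth$positions[1, ])
  plat <- track_landmark(fs$frames, fs$plateau_truth$positions[1, ])
  el <- elongation_from_tracks(apex, plat, sp$pixel_scale)
  tf <- tendon_force_trace(force, arms)
  trial <- fit_trial(pair_force_elongation(tf, el, sp$frame_rate))
  list(spec = sp, force = force, fs = fs, apex = apex, plateau = plat,
       elongation = el, tendon = tf, trial = trial,
       elong_err = el$values - fs$elongation_truth_mm)
}

# Independent mixed-ANOVA oracle via stats::aov error strata.
aov_oracle_2way <- function(d) {
  s <- summary(stats::aov(outcome ~ group * time + Error(participant / time),
                          data = d))
  b <- s[["Error: participant"]][[1]]
  w <- s[["Error: participant:time"]][[1]]
  list(ss_group = b["group", "Sum Sq"], ss_subj = b["Residuals", "Sum Sq"],
       F_group = b["group", "F value"],
       ss_time = w["time", "Sum Sq"], ss_tg = w["group:time", "Sum Sq"],
       ss_werr = w["Residuals", "Sum Sq"],
       F_time = w["time", "F value"], F_tg = w["group:time", "F value"],
       p_time = w["time", "Pr(>F)"], p_tg = w["group:time", "Pr(>F)"])
}

aov_oracle_3way <- function(d) {
  s <- summary(stats::aov(
    outcome ~ group * time * location + Error(participant / (time * location)),
    data = d))
  g <- function(stratum, row, col) s[[stratum]][[1]][row, col]
  list(
    F_group = g("Error: participant", "group", "F value"),
    F_time = g("Error: participant:time", "time", "F value"),
    F_tg = g("Error: participant:time", "group:time", "F value"),
    F_loc = g("Error: participant:location", "location", "F value"),
    F_lg = g("Error: participant:location", "group:location", "F value"),
    F_tl = g("Error: participant:time:location", "time:location", "F value"),
    F_tlg = g("Error: participant:time:location", "group:time:location",
              "F value"))
}

anova_stat <- function(res, effect, col) {
  res$table[res$table$effect == effect, col]
}

# Random complete cohort table for property tests.
random_cohort_2way <- function(seed, n1 = 5L, n2 = 7L) {
  generate_cohort(cohort_spec(
    n_per_group = c(n1, n2),
    training_effect = stats::runif(1, -5, 5),
    interaction_effect = stats::runif(1, -5, 5),
    sd_between = stats::runif(1, 1, 10),
    sd_within = stats::runif(1, 0.5, 5),
    seed = seed))
}
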