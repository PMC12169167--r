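test_that("force ramp geometry follows the moment ramp rate", {
  sp <- trial_spec(peak_moment = 210, moment_ramp_rate = 70,
                   noise_force_sd = 0, seed = 1)
  tr <- generate_force_trace(sp)
  # 3.0 s ramp at 1000 Hz: 3000 samples strictly before the peak sample
  i_peak <- which.max(attr(tr, "true_samples"))
  expect_equal(i_peak - tr$trigger_index, 3000)
  # noise-free: moment exactly linear during the ramp
  moment <- tr$samples * sp$external_arm
  ramp <- moment[tr$trigger_index:i_peak]
  t_s <- (seq_along(ramp) - 1) / tr$rate
  expect_equal(ramp, 70 * t_s, tolerance = 1e-12)
  expect_equal(max(moment), 210)
})

test_that("force generation is deterministic given the seed", {
  sp <- trial_spec(peak_moment = 100, noise_force_sd = 4, seed = 77)
  expect_identical(generate_force_trace(sp)$samples,
                   generate_force_trace(sp)$samples)
  sp2 <- trial_spec(peak_moment = 100, noise_force_sd = 4, seed = 78)
  expect_false(identical(generate_force_trace(sp)$samples,
                         generate_force_trace(sp2)$samples))
})

test_that("invalid trial specs are rejected", {
  expect_error(trial_spec(peak_moment = -5), "peak_moment")
  expect_error(trial_spec(peak_moment = 100, moment_ramp_rate = 0),
               "moment_ramp_rate")
  expect_error(trial_spec(peak_moment = 100, curve_b = 0), "curve_b")
})

test_that("frame generator places landmarks on the true elongation law", {
  # linear law e = F / b: peak tendon force 2000 N at b = 1000 N/mm
  arms <- default_arms()
  # 1 s ramp whose final frame lands exactly on the peak
  sp <- trial_spec(peak_moment = 2000 * arms$internal_arm,
                   moment_ramp_rate = 2000 * arms$internal_arm,
                   curve_a = 0, curve_b = 1000,
                   noise_force_sd = 0, noise_image_sd = 0, seed = 3)
  tr <- generate_force_trace(sp)
  fs <- generate_frame_sequence(sp, tr)
  expect_equal(max(fs$elongation_truth_mm), 2.0, tolerance = 1e-3)
  # truth distance at frame 0 equals the rest length
  d0 <- sqrt(sum((fs$apex_truth$positions[1, ] -
                    fs$plateau_truth$positions[1, ])^2))
  expect_equal(d0, sp$rest_length_px)
  # same seed -> bit-identical stacks
  fs2 <- generate_frame_sequence(sp, tr)
  expect_identical(fs$frames$frames, fs2$frames$frames)
})

test_that("rigid whole-image translation leaves true elongation unchanged", {
  sp <- trial_spec(peak_moment = 70, noise_force_sd = 0,
                   noise_image_sd = 0, seed = 5)
  tr <- generate_force_trace(sp)
  n_frames <- floor(sp$peak_moment / sp$moment_ramp_rate * sp$frame_rate) + 1
  shift <- cbind(seq(0, 3, length.out = n_frames),
                 seq(0, -2, length.out = n_frames))
  fs0 <- generate_frame_sequence(sp, tr)
  fs1 <- generate_frame_sequence(sp, tr, rigid_translation = shift)
  expect_equal(fs1$elongation_truth_mm, fs0$elongation_truth_mm,
               tolerance = 1e-12)
})

test_that("elongation beyond the image bounds is rejected", {
  sp <- trial_spec(peak_moment = 300, curve_a = 0, curve_b = 100, seed = 1)
  tr <- generate_force_trace(sp)
  expect_error(generate_frame_sequence(sp, tr), "exceeds image bounds")
})

test_that("swv generator hits the requested saturation exactly", {
  r0 <- generate_swv_map(c(50, 50), 7, 0, n_frames = 2, seed = 1)
  expect_equal(saturation_fraction(r0), 0)
  r1 <- generate_swv_map(c(50, 50), 7, 1, n_frames = 2, seed = 1)
  expect_equal(saturation_fraction(r1), 1)
  r05 <- generate_swv_map(c(100, 100), 7, 0.05, n_frames = 3, seed = 2)
  counts <- vapply(r05$maps, function(m) sum(m > 18), integer(1))
  expect_true(all(counts == 500L))
  expect_error(generate_swv_map(c(10, 10), -1, 0), "base_velocity")
  # determinism
  expect_identical(generate_swv_map(c(20, 20), 7, 0.1, seed = 9)$maps,
                   generate_swv_map(c(20, 20), 7, 0.1, seed = 9)$maps)
})

test_that("cohort generator reproduces programmed effects exactly when noiseless", {
  d <- generate_cohort(cohort_spec(n_per_group = c(3, 4), sd_between = 0,
                                   sd_within = 0, training_effect = 20,
                                   interaction_effect = 0, seed = 1))
  w <- tapply(d$outcome, list(d$participant, d$time), mean)
  expect_true(all(abs((w[, "post"] - w[, "pre"]) - 20) < 1e-12))

  d2 <- generate_cohort(cohort_spec(n_per_group = c(3, 4), sd_between = 0,
                                    sd_within = 0, training_effect = 20,
                                    interaction_effect = 10, seed = 1))
  w2 <- tapply(d2$outcome, list(d2$participant, d2$time), mean)
  diffs <- w2[, "post"] - w2[, "pre"]
  grp <- tapply(as.character(d2$group), d2$participant, `[`, 1)[names(diffs)]
  expect_equal(mean(diffs[grp == "NOC"]) - mean(diffs[grp == "OC"]), 10,
               tolerance = 1e-12)
})

test_that("cohort generation is deterministic and respects the design shape", {
  sp <- cohort_spec(n_per_group = c(4, 5), n_locations = 3,
                    location_offsets = c(1, 0, -1), seed = 42)
  d1 <- generate_cohort(sp)
  expect_identical(d1, generate_cohort(sp))
  expect_equal(nrow(d1), 9 * 2 * 3)
  expect_setequal(levels(d1$location), c("proximal", "mid", "distal"))
  expect_equal(as.integer(table(d1$group)[c("OC", "NOC")]), c(4L, 5L) * 6L)
})
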