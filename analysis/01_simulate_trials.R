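#!/usr/bin/env Rscript
# Simulate the raw recordings of one synthetic participant's ramped
# knee-extension trials: cuff-force traces (1,000 Hz, ~70 N·m/s moment
# ramp) and synchronized speckle frame stacks in which the patella-apex
# landmark separates from the tibial-plateau landmark according to a
# known quadratic force-elongation law. Everything downstream works
# from these files; ground truth goes into JSON sidecars.

suppressPackageStartupMessages(library(tendonmech))

seed <- 20260930L
out <- "results/raw"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

arms <- moment_arms(external_arm = 0.40, internal_arm = 0.0355)
n_trials <- 4L

for (k in seq_len(n_trials)) {
  sp <- trial_spec(peak_moment = 140, moment_ramp_rate = 70,
                   external_arm = arms$external_arm,
                   internal_arm = arms$internal_arm,
                   curve_a = 200, curve_b = 500,
                   noise_force_sd = 3, noise_image_sd = 3,
                   seed = seed + k)
  force <- generate_force_trace(sp)
  fs <- generate_frame_sequence(sp, force)
  stem <- file.path(out, sprintf("trial%02d", k))
  write_force_trace(force, paste0(stem, "_force.tsv"))
  write_frames_tiff(fs$frames, paste0(stem, "_frames.tif"))
  write_truth_json(list(
    seed = sp$seed, curve_a = sp$curve_a, curve_b = sp$curve_b,
    external_arm_m = sp$external_arm, internal_arm_m = sp$internal_arm,
    frame_rate_hz = sp$frame_rate, pixel_scale_mm = sp$pixel_scale,
    init_apex = unname(fs$apex_truth$positions[1, ]),
    init_plateau = unname(fs$plateau_truth$positions[1, ]),
    elongation_truth_mm = fs$elongation_truth_mm),
    paste0(stem, "_truth.json"))
  cat(sprintf("trial %d: %d frames, peak tendon force %.0f N, peak elongation %.2f mm\n",
              k, dim(fs$frames$frames)[3],
              sp$peak_moment / sp$internal_arm,
              max(fs$elongation_truth_mm)))
}
cat("raw recordings written to", out, "\n")
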