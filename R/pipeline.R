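#' Reduce MVC attempts to the strength outcome
#'
#' Mean of the two attempts with the highest peak moment.
#'
#' @param attempts numeric vector of peak moments, N·m (>= 2 attempts).
#' @return strength, N·m.
#' @export
mvc_strength <- function(attempts) {
  if (length(attempts) < 2L) stopf("need at least 2 MVC attempts")
  mean(sort(attempts, decreasing = TRUE)[1:2])
}

#' Mean tendon cross-sectional area over the three sites
#'
#' @param site_csas numeric vector of the proximal, mid and distal CSAs,
#'   mm^2.
#' @return mean CSA, mm^2.
#' @export
mean_csa <- function(site_csas) {
  if (length(site_csas) != 3L) stopf("expected CSAs for exactly 3 sites")
  mean(site_csas)
}

#' Simulate the complete raw data of one synthetic participant
#'
#' Builds everything the processing pipeline consumes for one
#' participant: per-session ramped-contraction trials (force trace plus
#' frame stack with ground truth), shear-wave recordings for both sides,
#' site CSAs and MVC attempts, for the pre and post sessions. Training
#' scales the tendon's true curve coefficients by `stiffness_gain`,
#' adds `strength_gain_nm` to the peak moment, `csa_gain_mm2` to each
#' site CSA and `swv_gain_ms` to the base shear-wave velocity.
#'
#' @param id participant label.
#' @param group `"OC"` or `"NOC"`.
#' @param seed integer seed for everything this participant generates.
#' @param n_trials ramped trials per session (default 4).
#' @param peak_moment pre-training peak moment, N·m.
#' @param curve_a,curve_b pre-training true curve coefficients.
#' @param stiffness_gain multiplicative post/pre stiffness ratio
#'   (default 1.2).
#' @param strength_gain_nm,csa_gain_mm2,swv_gain_ms additive training
#'   effects on the other outcomes.
#' @param arms a [moment_arms()].
#' @param frame_rate,noise_force_sd,noise_image_sd,pixel_scale imaging
#'   and noise settings forwarded to [trial_spec()].
#' @param csa_sites pre-training site CSAs, mm^2 (proximal, mid,
#'   distal).
#' @param swv_base pre-training shear-wave velocity, m/s.
#' @param swv_shape,swv_frames geometry of the simulated velocity maps.
#' @return a `participant_data` list consumed by [run_participant()].
#' @export
simulate_participant <- function(id, group, seed,
                                 n_trials = 4L,
                                 peak_moment = 140,
                                 curve_a = 200, curve_b = 500,
                                 stiffness_gain = 1.2,
                                 strength_gain_nm = 20,
                                 csa_gain_mm2 = 1,
                                 swv_gain_ms = 1,
                                 arms = moment_arms(0.40, 0.0355),
                                 frame_rate = 50,
                                 noise_force_sd = 3,
                                 noise_image_sd = 3,
                                 pixel_scale = 0.1,
                                 csa_sites = c(72, 75, 78),
                                 swv_base = 7,
                                 swv_shape = c(40L, 60L),
                                 swv_frames = 3L) {
  seed <- as.integer(seed)
  sessions <- list()
  for (session in c("pre", "post")) {
    post <- session == "post"
    a <- if (post) curve_a * stiffness_gain else curve_a
    b <- if (post) curve_b * stiffness_gain else curve_b
    pk <- peak_moment + if (post) strength_gain_nm else 0
    trials <- lapply(seq_len(n_trials), function(k) {
      sp <- trial_spec(peak_moment = pk,
                       external_arm = arms$external_arm,
                       internal_arm = arms$internal_arm,
                       curve_a = a, curve_b = b,
                       frame_rate = frame_rate,
                       pixel_scale = pixel_scale,
                       noise_force_sd = noise_force_sd,
                       noise_image_sd = noise_image_sd,
                       seed = seed + 131L * k + if (post) 67L else 0L)
      force <- generate_force_trace(sp)
      fs <- generate_frame_sequence(sp, force)
      list(spec = sp, force = force, frames = fs$frames,
           init_apex = fs$apex_truth$positions[1, ],
           init_plateau = fs$plateau_truth$positions[1, ],
           truth = list(elongation_mm = fs$elongation_truth_mm,
                        apex = fs$apex_truth, plateau = fs$plateau_truth))
    })
    swv_b <- swv_base + if (post) swv_gain_ms else 0
    swv <- list(
      medial = generate_swv_map(swv_shape, swv_b, 0, n_frames = swv_frames,
                                seed = seed + 7L + post, side = "medial"),
      lateral = generate_swv_map(swv_shape, swv_b + 0.5, 0,
                                 n_frames = swv_frames,
                                 seed = seed + 9L + post, side = "lateral"))
    mvc <- with_seed(seed + 3L + post,
                     pk + stats::rnorm(3, 0, 0.02 * pk))
    csa <- csa_sites + if (post) csa_gain_mm2 else 0
    sessions[[session]] <- list(trials = trials, swv = swv,
                                csa_sites = csa, mvc_attempts = mvc)
  }
  structure(list(id = id, group = group, arms = arms, seed = seed,
                 true_stiffness_gain = stiffness_gain,
                 sessions = sessions),
            class = "participant_data")
}

process_session_trials <- function(trials, arms, cutoff, lk, resample_n,
                                   r2_min) {
  lapply(trials, function(tr) {
    tf <- tendon_force_trace(tr$force, arms, cutoff = cutoff)
    apex <- track_landmark(tr$frames, tr$init_apex,
                           window = lk$window,
                           pyramid_levels = lk$pyramid_levels,
                           max_iter = lk$max_iter, tol = lk$tol)
    plat <- track_landmark(tr$frames, tr$init_plateau,
                           window = lk$window,
                           pyramid_levels = lk$pyramid_levels,
                           max_iter = lk$max_iter, tol = lk$tol)
    el <- elongation_from_tracks(apex, plat, tr$frames$pixel_scale)
    fit_trial(pair_force_elongation(tf, el, tr$frames$frame_rate),
              resample_n = resample_n, r2_min = r2_min)
  })
}

#' Process one participant end to end
#'
#' Runs the full measurement chain on a `participant_data` bundle:
#' force conditioning and tendon-force conversion, landmark tracking and
#' elongation, per-trial quadratic fits with R^2 gating, common-force
#' standardization across the two sessions, mean curves and 60-100 %
#' stiffness; shear-wave QC and per-side / mean-of-sides summaries; mean
#' CSA; MVC strength.
#'
#' @param pd a `participant_data` from [simulate_participant()] (or
#'   assembled from disk in the same shape).
#' @param cutoff lowpass cutoff, Hz.
#' @param lk list of Lucas-Kanade settings (`window`, `pyramid_levels`,
#'   `max_iter`, `tol`).
#' @param resample_n,r2_min trial fit settings (see [fit_trial()]).
#' @return list with `outcomes` (one data.frame row per session:
#'   stiffness, SWV summaries, mean CSA, strength, trial counts) and
#'   `details` (per-session fitted trials, mean curves, common force).
#' @export
run_participant <- function(pd, cutoff = 30,
                            lk = list(window = 21L, pyramid_levels = 3L,
                                      max_iter = 30L, tol = 0.01),
                            resample_n = 100L, r2_min = 0.90) {
  stopifnot(inherits(pd, "participant_data"))
  fitted <- lapply(pd$sessions, function(s) {
    process_session_trials(s$trials, pd$arms, cutoff, lk, resample_n, r2_min)
  })
  peaks <- lapply(fitted, function(tl) {
    vapply(Filter(function(tr) isTRUE(tr$included), tl),
           function(tr) tr$peak_force, numeric(1))
  })
  cf <- tryCatch(common_force(peaks$pre, peaks$post), error = function(e) NA_real_)
  rows <- list(); details <- list(common_force = cf, trials = fitted)
  for (session in names(pd$sessions)) {
    s <- pd$sessions[[session]]
    stiff <- NA_real_; n_inc <- sum(vapply(fitted[[session]],
                                           function(tr) isTRUE(tr$included),
                                           logical(1)))
    if (!is.na(cf) && n_inc > 0) {
      mc <- mean_curve(fitted[[session]], cf)
      sr <- stiffness_slope(mc)
      stiff <- sr$stiffness
      details[[paste0("curve_", session)]] <- mc
      details[[paste0("stiffness_", session)]] <- sr
    }
    med <- qc_recording(s$swv$medial)
    lat <- qc_recording(s$swv$lateral)
    sm <- side_mean(med, lat)
    rows[[session]] <- data.frame(
      participant = pd$id, group = pd$group, time = session,
      n_trials_total = length(s$trials), n_trials_included = n_inc,
      common_force_N = cf, stiffness_N_per_mm = stiff,
      swv_medial = med$mean_velocity, swv_lateral = lat$mean_velocity,
      swv_mean = sm$mean_velocity,
      csa_mean_mm2 = mean_csa(s$csa_sites),
      csa_proximal = s$csa_sites[1], csa_mid = s$csa_sites[2],
      csa_distal = s$csa_sites[3],
      strength_Nm = mvc_strength(s$mvc_attempts),
      stringsAsFactors = FALSE)
  }
  list(outcomes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       details = details)
}

#' Assemble participant outcomes and run the cohort-level statistics
#'
#' Stacks per-participant outcome rows into long-format cohort tables,
#' then runs the configured inference: two-way (training x group) mixed
#' ANOVAs for stiffness, strength and mean SWV, and the three-way
#' (training x group x location) ANOVA for site CSA, with per-outcome
#' listwise inclusion and logged ns.
#'
#' @param outcome_rows data.frame stacking the `outcomes` element of
#'   [run_participant()] over participants.
#' @return list with the cohort table, one `anova_result` per outcome,
#'   and the per-outcome inclusion counts.
#' @export
run_cohort <- function(outcome_rows) {
  d <- outcome_rows
  d$time <- factor(d$time, levels = c("pre", "post"))
  d$group <- factor(d$group, levels = c("OC", "NOC"))
  long2 <- function(col) {
    out <- data.frame(participant = d$participant, group = d$group,
                      time = d$time, outcome = d[[col]],
                      stringsAsFactors = FALSE)
    out[is.finite(out$outcome), ]
  }
  csa_long <- do.call(rbind, lapply(
    c(proximal = "csa_proximal", mid = "csa_mid", distal = "csa_distal"),
    function(col) {
      cbind(long2(col)[, c("participant", "group", "time")],
            location = sub("csa_", "", col),
            outcome = d[[col]][is.finite(d[[col]])])
    }))
  csa_long$location <- factor(csa_long$location,
                              levels = c("proximal", "mid", "distal"))
  anovas <- list(
    stiffness = tryCatch(mixed_anova_2way(long2("stiffness_N_per_mm")),
                         error = function(e) e),
    strength = tryCatch(mixed_anova_2way(long2("strength_Nm")),
                        error = function(e) e),
    swv_mean = tryCatch(mixed_anova_2way(long2("swv_mean")),
                        error = function(e) e),
    csa = tryCatch(mixed_anova_3way(csa_long), error = function(e) e))
  ns <- vapply(anovas, function(a) {
    if (inherits(a, "anova_result")) a$n_included else NA_integer_
  }, integer(1))
  list(outcomes = d, csa_long = csa_long, anovas = anovas,
       n_per_outcome = ns)
}

#' Run a complete synthetic study and write every output
#'
#' Simulates a two-group cohort with [simulate_participant()], processes
#' each participant with [run_participant()], runs [run_cohort()], and
#' writes the outcome table, the per-outcome ANOVA tables and an audit
#' log under `out_dir`. Deterministic: the same `seed` and settings
#' produce byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; participant seeds derive from it.
#' @param n_per_group participants per group `c(OC, NOC)`.
#' @param n_trials ramped trials per session.
#' @param peak_moment pre-training peak moment, N·m (sets the ramp
#'   duration at 70 N·m/s).
#' @param frame_rate ultrasound frame rate, Hz.
#' @param noise_force_sd,noise_image_sd sensor and image noise.
#' @param stiffness_gain,strength_gain_nm,csa_gain_mm2,swv_gain_ms
#'   programmed training effects (identical in both groups by default,
#'   i.e. no group x training interaction).
#' @return invisibly, the [run_cohort()] report.
#' @export
run_study <- function(out_dir, seed = 1L,
                      n_per_group = c(2L, 2L),
                      n_trials = 2L,
                      peak_moment = 105,
                      frame_rate = 25,
                      noise_force_sd = 3,
                      noise_image_sd = 2,
                      stiffness_gain = 1.2,
                      strength_gain_nm = 20,
                      csa_gain_mm2 = 1,
                      swv_gain_ms = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_per_group <- as.integer(rep_len(n_per_group, 2L))
  groups <- rep(c("OC", "NOC"), times = n_per_group)
  rows <- list()
  log <- c(sprintf("seed=%d", as.integer(seed)),
           sprintf("n_per_group=%d/%d", n_per_group[1], n_per_group[2]))
  for (i in seq_along(groups)) {
    pd <- simulate_participant(
      id = sprintf("P%02d", i), group = groups[i],
      seed = as.integer(seed) + 1000L * i,
      n_trials = n_trials, peak_moment = peak_moment,
      frame_rate = frame_rate,
      noise_force_sd = noise_force_sd, noise_image_sd = noise_image_sd,
      stiffness_gain = stiffness_gain,
      strength_gain_nm = strength_gain_nm,
      csa_gain_mm2 = csa_gain_mm2, swv_gain_ms = swv_gain_ms)
    res <- run_participant(pd)
    rows[[i]] <- res$outcomes
    log <- c(log, sprintf(
      "%s (%s): common_force=%.6g N, trials included pre=%d post=%d",
      pd$id, pd$group, res$details$common_force,
      res$outcomes$n_trials_included[1], res$outcomes$n_trials_included[2]))
  }
  outcomes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  report <- run_cohort(outcomes)
  write_cohort(outcomes, file.path(out_dir, "participant_outcomes.tsv"))
  for (nm in names(report$anovas)) {
    a <- report$anovas[[nm]]
    if (inherits(a, "anova_result")) {
      utils::write.table(format(a$table, digits = 10),
                         file.path(out_dir, paste0("anova_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log <- c(log, sprintf("anova %s: n=%d included, %d excluded",
                            nm, a$n_included, a$n_excluded))
    } else {
      log <- c(log, sprintf("anova %s: not run (%s)", nm, conditionMessage(a)))
    }
  }
  writeLines(log, file.path(out_dir, "audit_log.txt"))
  invisible(report)
}
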