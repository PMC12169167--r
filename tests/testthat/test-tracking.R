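# Small static speckle scene with one trackable blob, built directly.
static_scene <- function(n_frames = 5, nr = 64, nc = 64, seed = 11,
                         shift_per_frame = c(0, 0)) {
  set.seed(seed)
  base <- 60 + 18 * gaussian_smooth_test(matrix(rnorm((nr + 40) * (nc + 40)),
                                                nr + 40, nc + 40))
  xs <- rep(0:(nc - 1), each = nr); ys <- rep(0:(nr - 1), times = nc)
  arr <- array(0, dim = c(nr, nc, n_frames))
  for (f in 1:n_frames) {
    sh <- (f - 1) * shift_per_frame
    img <- matrix(tendonmech:::bilinear_sample(base, xs + 20 - sh[1],
                                               ys + 20 - sh[2]), nr, nc)
    blob <- 120 * exp(-((xs - 32 - sh[1])^2 + (ys - 32 - sh[2])^2) / (2 * 2.5^2))
    arr[, , f] <- img + matrix(blob, nr, nc)
  }
  frame_sequence(arr, 50, 0.1)
}

gaussian_smooth_test <- function(m) {
  k <- stats::dnorm(-4:4, sd = 1.5); k <- k / sum(k)
  m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(t(m), 2, function(row) stats::filter(row, k, circular = TRUE)))
}

test_that("a static sequence tracks as zero flow", {
  fs <- static_scene()
  tk <- track_landmark(fs, c(32, 32))
  expect_true(all(tk$status))
  expect_equal(tk$positions,
               matrix(32, 5, 2, dimnames = list(NULL, c("x", "y"))),
               tolerance = 1e-3)
})

test_that("global sub-pixel translation is recovered within 0.05 px per step", {
  fs <- static_scene(n_frames = 8, shift_per_frame = c(0.30, 0))
  tk <- track_landmark(fs, c(32, 32))
  steps <- diff(tk$positions[, 1])
  expect_true(all(abs(steps - 0.30) < 0.05))
  expect_lt(mean(abs(diff(tk$positions[, 2]))), 0.05)
})

test_that("noise-free synthetic trial is tracked to sub-0.1 px accuracy", {
  s <- synth_tracked_trial(seed = 21, peak_moment = 70)
  expect_lt(max(abs(s$apex$positions - s$fs$apex_truth$positions)), 0.1)
  expect_lt(max(abs(s$plateau$positions - s$fs$plateau_truth$positions)), 0.1)
  expect_true(all(s$apex$status))
})

test_that("reversing the frame order negates the accumulated displacement", {
  s <- synth_tracked_trial(seed = 23, peak_moment = 70)
  fwd_disp <- s$apex$positions[nrow(s$apex$positions), ] -
    s$apex$positions[1, ]
  rev_fs <- frame_sequence(s$fs$frames$frames[, , rev(seq_len(
    dim(s$fs$frames$frames)[3]))], s$fs$frames$frame_rate,
    s$fs$frames$pixel_scale)
  tk_rev <- track_landmark(rev_fs, s$fs$apex_truth$positions[
    nrow(s$fs$apex_truth$positions), ])
  rev_disp <- tk_rev$positions[nrow(tk_rev$positions), ] - tk_rev$positions[1, ]
  expect_equal(unname(rev_disp), unname(-fwd_disp), tolerance = 0.05)
})

test_that("a zero-gradient scene flags non-convergence and carries forward", {
  arr <- array(50, dim = c(48, 48, 3))
  fs <- frame_sequence(arr, 50, 0.1)
  tk <- track_landmark(fs, c(24, 24))
  expect_false(any(tk$status[-1]))
  expect_equal(tk$positions[3, ], c(x = 24, y = 24))
})

test_that("initial positions outside the window margin are rejected", {
  fs <- static_scene()
  expect_error(track_landmark(fs, c(2, 32)), "margin")
  expect_error(track_landmark(fs, c(32, 62)), "margin")
})

test_that("elongation is the zero-referenced inter-landmark distance in mm", {
  n <- 4
  plat <- landmark_track(cbind(rep(10, n), rep(20, n)))
  apex0 <- cbind(c(50, 50, 51, 52), rep(20, n))
  apex <- landmark_track(apex0)
  el <- elongation_from_tracks(apex, plat, 0.1)
  expect_equal(el$values, c(0, 0, 0.1, 0.2))
  # identical tracks -> all zeros
  same <- elongation_from_tracks(plat, plat, 0.1)
  expect_equal(same$values, rep(0, n))
  # rigid translation of both tracks -> all zeros beyond frame 0 reference
  shift <- cbind(1:n, (1:n) / 2)
  el2 <- elongation_from_tracks(landmark_track(apex0 + shift),
                                landmark_track(plat$positions + shift), 0.1)
  expect_equal(el2$values, el$values, tolerance = 1e-12)
  expect_error(elongation_from_tracks(landmark_track(apex0[1:3, ]), plat, 0.1),
               "same length")
})

test_that("tracked elongation is invariant to whole-image rigid translation", {
  n_frames <- floor(70 / 70 * 50) + 1
  drift <- cbind(seq(0, 2, length.out = n_frames),
                 seq(0, 1.5, length.out = n_frames))
  s <- synth_tracked_trial(seed = 25, peak_moment = 70,
                           rigid_translation = drift)
  expect_lt(mean(abs(s$elong_err)), 0.05)
})
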