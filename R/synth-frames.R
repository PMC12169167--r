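#' Frame-sequence container
#'
#' A grayscale image stack with its frame rate and spatial scale. Frames
#' are stored as a numeric array of dimension `rows x cols x n_frames`;
#' pixel coordinates everywhere in the package are 0-based, `x` along
#' columns (rightward), `y` along rows (downward).
#'
#' @param frames numeric 3-D array, `rows x cols x n_frames`.
#' @param frame_rate Hz.
#' @param pixel_scale mm per pixel.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, pixel_scale) {
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L) {
    stopf("frames must be a rows x cols x n_frames array with >= 2 frames")
  }
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  assert_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_scale = pixel_scale),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %g Hz, %g mm/px\n",
              d[3], d[1], d[2], x$frame_rate, x$pixel_scale))
  invisible(x)
}

# Smooth compositing mask: 1 inside `flat` px, cosine falloff to 0 at `outer`.
patch_mask <- function(r, flat, outer) {
  m <- numeric(length(r))
  m[r <= flat] <- 1
  i <- r > flat & r < outer
  m[i] <- 0.5 * (1 + cos(pi * (r[i] - flat) / (outer - flat)))
  m
}

# Continuous landmark patch texture: bright Gaussian blob plus local
# speckle, sampled at sub-pixel local offsets (dx, dy) by bilinear
# interpolation of a precomputed speckle grid.
make_patch <- function(radius, blob_amp, blob_sigma, speckle_sd, base_level) {
  n <- 2L * (radius + 1L) + 1L
  grid <- gaussian_smooth(matrix(stats::rnorm(n * n), n, n), 1.5)
  grid <- grid / stats::sd(grid) * speckle_sd
  list(radius = radius, blob_amp = blob_amp, blob_sigma = blob_sigma,
       base = base_level, grid = grid)
}

sample_patch <- function(patch, dx, dy) {
  r0 <- patch$radius + 1L
  patch$base +
    patch$blob_amp * exp(-(dx^2 + dy^2) / (2 * patch$blob_sigma^2)) +
    bilinear_sample(patch$grid, dx + r0, dy + r0)
}

# Composite a rigidly translated patch into `img` at (px, py), blending
# with the smooth mask so motion inside the tracker window is exactly
# the patch translation.
composite_patch <- function(img, patch, px, py, flat, outer) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0L, floor(px - outer)); x1 <- min(nc - 1L, ceiling(px + outer))
  y0 <- max(0L, floor(py - outer)); y1 <- min(nr - 1L, ceiling(py + outer))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs, each = length(ys)) - px
  dy <- rep(ys, times = length(xs)) - py
  r <- sqrt(dx^2 + dy^2)
  m <- patch_mask(r, flat, outer)
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  val <- sample_patch(patch, dx, dy)
  img[ys + 1L, xs + 1L] <- (1 - m) * sub + m * val
  img
}

#' Simulate a speckle-textured ultrasound frame stack for one trial
#'
#' Renders a stack of B-mode-like frames containing two high-contrast
#' landmark patches on a speckle background. The tibial-plateau landmark
#' is static (up to an optional rigid whole-image translation); the
#' patella-apex landmark displaces along +x so that the inter-landmark
#' distance at frame `t` equals the rest length plus `e(F(t))`, where
#' `e(.)` inverts the trial's true force-elongation law and `F(t)` is the
#' noise-free tendon force at the frame time. Each landmark is rendered
#' as a rigidly translated continuous patch (analytic Gaussian blob plus
#' bilinearly interpolated local speckle) composited over the background
#' with a smooth mask, so sub-pixel motion is exact. Image noise is added
#' after warping.
#'
#' @param spec a [trial_spec()].
#' @param force a [force_trace()] from [generate_force_trace()] covering
#'   the frame timeline (used for its ramp geometry; landmark placement
#'   follows the noise-free ramp).
#' @param rigid_translation optional `n_frames x 2` matrix of (dx, dy)
#'   whole-image translations in pixels, applied to both landmarks and
#'   the background.
#' @return a list with elements `frames` ([frame_sequence()]),
#'   `apex_truth` and `plateau_truth` (ground-truth [landmark_track()]s),
#'   and `elongation_truth_mm` (numeric, per frame).
#' @export
generate_frame_sequence <- function(spec, force, rigid_translation = NULL) {
  stopifnot(inherits(spec, "trial_spec"), inherits(force, "force_trace"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  ramp_T <- spec$peak_moment / spec$moment_ramp_rate
  n_frames <- floor(ramp_T * spec$frame_rate) + 1L
  t_frames <- (seq_len(n_frames) - 1L) / spec$frame_rate
  n_avail <- (length(force$samples) - force$trigger_index) / force$rate
  if (max(t_frames) > n_avail + 1e-9) {
    stopf("force trace does not cover the frame timeline")
  }
  # noise-free tendon force at frame times, then true elongation (mm -> px)
  f_tendon <- spec$moment_ramp_rate * t_frames / spec$internal_arm
  elong_mm <- invert_curve(f_tendon, spec$curve_a, spec$curve_b)
  disp_px <- elong_mm / spec$pixel_scale

  flat <- 15; outer <- 28
  plateau0 <- c(44, (nr - 1) / 2)
  apex0 <- plateau0 + c(spec$rest_length_px, 0)
  if (is.null(rigid_translation)) {
    rigid_translation <- matrix(0, n_frames, 2L)
  }
  stopifnot(nrow(rigid_translation) == n_frames)
  max_x <- max(apex0[1] + disp_px + rigid_translation[, 1])
  if (max_x + outer + 1 > nc - 1 ||
      any(plateau0[1] + rigid_translation[, 1] - outer < 1)) {
    stopf("peak elongation (%.1f px) exceeds image bounds", max(disp_px))
  }

  frames <- with_seed(spec$seed + 1L, {
    bg <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 1.5)
    bg <- 60 + bg / stats::sd(bg) * 18
    patch_ap <- make_patch(outer + 2L, blob_amp = 120, blob_sigma = 2.5,
                           speckle_sd = 18, base_level = 60)
    patch_pl <- make_patch(outer + 2L, blob_amp = 120, blob_sigma = 2.5,
                           speckle_sd = 18, base_level = 60)
    xg <- rep(0:(nc - 1), each = nr)
    yg <- rep(0:(nr - 1), times = nc)
    arr <- array(0, dim = c(nr, nc, n_frames))
    for (f in seq_len(n_frames)) {
      tr <- rigid_translation[f, ]
      img <- if (all(tr == 0)) bg else {
        matrix(bilinear_sample(bg, xg - tr[1], yg - tr[2]), nr, nc)
      }
      img <- composite_patch(img, patch_pl,
                             plateau0[1] + tr[1], plateau0[2] + tr[2],
                             flat, outer)
      img <- composite_patch(img, patch_ap,
                             apex0[1] + disp_px[f] + tr[1], apex0[2] + tr[2],
                             flat, outer)
      if (spec$noise_image_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_image_sd), nr, nc)
      }
      arr[, , f] <- img
    }
    arr
  })

  apex_pos <- cbind(apex0[1] + disp_px + rigid_translation[, 1],
                    apex0[2] + rigid_translation[, 2])
  plat_pos <- cbind(plateau0[1] + rigid_translation[, 1],
                    plateau0[2] + rigid_translation[, 2])
  list(frames = frame_sequence(frames, spec$frame_rate, spec$pixel_scale),
       apex_truth = landmark_track(apex_pos),
       plateau_truth = landmark_track(plat_pos),
       elongation_truth_mm = elong_mm)
}
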