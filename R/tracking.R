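#' Landmark track container
#'
#' Per-frame sub-pixel landmark positions with a convergence flag.
#'
#' @param positions `n_frames x 2` matrix of (x, y) pixel coordinates,
#'   0-based.
#' @param status logical per frame; `FALSE` where tracking did not
#'   converge (position carried forward).
#' @return an object of class `landmark_track`.
#' @export
landmark_track <- function(positions, status = rep(TRUE, nrow(positions))) {
  positions <- matrix(as.numeric(positions), ncol = 2L,
                      dimnames = list(NULL, c("x", "y")))
  stopifnot(length(status) == nrow(positions))
  structure(list(positions = positions, status = as.logical(status)),
            class = "landmark_track")
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track> %d frames, %d converged\n",
              nrow(x$positions), sum(x$status)))
  invisible(x)
}

# Smooth + gradient images for one pyramid level. Gradients by central
# differences on the Gaussian-smoothed image (LK assumes differentiability).
level_images <- function(img, sigma = 1) {
  s <- gaussian_smooth(img, sigma)
  nr <- nrow(s); nc <- ncol(s)
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2
  list(img = s, gx = gx, gy = gy)
}

# Coarse-to-fine pyramid: each level halves resolution.
build_pyramid <- function(img, levels, sigma = 1) {
  pyr <- vector("list", levels)
  pyr[[1]] <- level_images(img, sigma)
  cur <- pyr[[1]]$img
  for (l in seq_len(levels - 1L)) {
    cur <- gaussian_smooth(cur, 1)[seq(1, nrow(cur), by = 2),
                                   seq(1, ncol(cur), by = 2), drop = FALSE]
    pyr[[l + 1L]] <- level_images(cur, 0)  # already smoothed while shrinking
  }
  pyr
}

# Iterative LK refinement at one pyramid level. Returns the residual
# displacement nu solving the local optical-flow least squares problem,
# or NULL when the structure tensor is near-singular / iteration
# diverges.
lk_refine <- function(lvl_I, lvl_J, p, guess, half_w, max_iter, tol) {
  off <- seq(-half_w, half_w)
  wx <- rep(p[1] + off, each = length(off))
  wy <- rep(p[2] + off, times = length(off))
  iw <- bilinear_sample(lvl_I$img, wx, wy)
  ix <- bilinear_sample(lvl_I$gx, wx, wy)
  iy <- bilinear_sample(lvl_I$gy, wx, wy)
  gxx <- sum(ix * ix); gxy <- sum(ix * iy); gyy <- sum(iy * iy)
  det_g <- gxx * gyy - gxy * gxy
  tr_g <- gxx + gyy
  min_eig <- tr_g / 2 - sqrt(max((tr_g / 2)^2 - det_g, 0))
  if (!is.finite(min_eig) || min_eig < 1e-8 * length(iw)) return(NULL)
  nu <- c(0, 0)
  for (it in seq_len(max_iter)) {
    jw <- bilinear_sample(lvl_J$img,
                          wx + guess[1] + nu[1], wy + guess[2] + nu[2])
    err <- iw - jw
    b <- c(sum(err * ix), sum(err * iy))
    delta <- c(gyy * b[1] - gxy * b[2], -gxy * b[1] + gxx * b[2]) / det_g
    nu <- nu + delta
    if (sqrt(sum(delta^2)) < tol) break
    if (sqrt(sum(nu^2)) > 2 * half_w + 2) return(NULL)  # diverged
  }
  nu
}

# Pyramidal LK displacement of the point p from pyramid I to pyramid J.
lk_displacement <- function(pyr_I, pyr_J, p, half_w, max_iter, tol) {
  levels <- length(pyr_I)
  g <- c(0, 0)
  for (l in seq(levels, 1L)) {
    scale <- 2^(l - 1L)
    nu <- lk_refine(pyr_I[[l]], pyr_J[[l]], p / scale, g,
                    half_w, max_iter, tol)
    if (is.null(nu)) return(NULL)
    d <- g + nu
    g <- if (l > 1L) 2 * d else d
  }
  g
}

#' Track a landmark through a frame stack with pyramidal Lucas-Kanade
#'
#' Frame-to-frame accumulating tracker: for each consecutive frame pair
#' the local optical-flow least-squares system (spatial-gradient
#' structure tensor against the temporal difference) is solved
#' iteratively with coarse-to-fine pyramid refinement and bilinear
#' sub-pixel sampling; the recovered displacement is added to the
#' current position. When the structure tensor is near-singular or the
#' iteration diverges the frame is flagged unconverged and the position
#' carried forward.
#'
#' @param seq a [frame_sequence()].
#' @param init initial (x, y) position in frame 0, 0-based pixels.
#' @param window square window side in pixels (odd; default 21).
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param max_iter maximum refinement iterations per level (default 30).
#' @param tol convergence tolerance on the update step, pixels
#'   (default 0.01).
#' @return a [landmark_track()].
#' @export
track_landmark <- function(seq, init, window = 21L, pyramid_levels = 3L,
                           max_iter = 30L, tol = 0.01) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames)
  half_w <- (as.integer(window) - 1L) %/% 2L
  if (init[1] < half_w || init[1] > d[2] - 1 - half_w ||
      init[2] < half_w || init[2] > d[1] - 1 - half_w) {
    stopf("initial position must lie inside the image with window margin")
  }
  n <- d[3]
  pyrs <- lapply(seq_len(n),
                 function(f) build_pyramid(seq$frames[, , f], pyramid_levels))
  pos <- matrix(NA_real_, n, 2L)
  status <- rep(TRUE, n)
  pos[1, ] <- init
  for (f in seq_len(n - 1L)) {
    dsp <- lk_displacement(pyrs[[f]], pyrs[[f + 1L]], pos[f, ],
                           half_w, max_iter, tol)
    if (is.null(dsp)) {
      status[f + 1L] <- FALSE
      pos[f + 1L, ] <- pos[f, ]
    } else {
      pos[f + 1L, ] <- pos[f, ] + dsp
    }
  }
  landmark_track(pos, status)
}

#' Tendon elongation from two landmark tracks
#'
#' Elongation at frame `t` is the change, relative to frame 0, in the
#' Euclidean distance between the patella-apex and tibial-plateau
#' landmarks, converted to millimetres. Rigid whole-image motion cancels
#' in the distance.
#'
#' @param apex,plateau [landmark_track()]s of equal length.
#' @param pixel_scale mm per pixel.
#' @return an object of class `elongation_series`: list with `values`
#'   (mm per frame, `values[1] == 0`) and `status` (both tracks
#'   converged).
#' @export
elongation_from_tracks <- function(apex, plateau, pixel_scale) {
  stopifnot(inherits(apex, "landmark_track"), inherits(plateau, "landmark_track"))
  assert_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  if (nrow(apex$positions) != nrow(plateau$positions)) {
    stopf("apex and plateau tracks must have the same length")
  }
  dist <- sqrt(rowSums((apex$positions - plateau$positions)^2))
  structure(list(values = (dist - dist[1]) * pixel_scale,
                 status = apex$status & plateau$status),
            class = "elongation_series")
}
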