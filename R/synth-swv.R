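#' Simulate a shear-wave-velocity recording
#'
#' Generates `n_frames` pixel-velocity maps. Unsaturated pixels are drawn
#' from `Normal(base_velocity, velocity_sd)` and clipped to
#' `[0, 0.9 * v_max]`; in every frame, exactly
#' `round(saturated_fraction * n_pixels)` pixels (chosen at random per
#' frame) are forced into the saturated band `(0.9 * v_max, v_max]`, so
#' the realized saturation fraction equals the request to within
#' `1/n_pixels`.
#'
#' @param shape `c(rows, cols)` of each map.
#' @param base_velocity mean tissue shear-wave velocity, m/s.
#' @param saturated_fraction fraction of pixels saturated, in `[0, 1]`.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param velocity_sd pixel SD around `base_velocity`, m/s (default 1).
#' @param side `"medial"` or `"lateral"`.
#' @param v_max instrument ceiling, m/s (default 20).
#' @return an [swv_recording()].
#' @export
generate_swv_map <- function(shape, base_velocity, saturated_fraction,
                             n_frames = 5L, seed = 1L, velocity_sd = 1,
                             side = "medial", v_max = 20) {
  if (base_velocity < 0) stopf("base_velocity must be >= 0")
  if (saturated_fraction < 0 || saturated_fraction > 1) {
    stopf("saturated_fraction must be in [0, 1]")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  npix <- nr * nc
  n_sat <- round(saturated_fraction * npix)
  sat_v <- 0.9 * v_max
  maps <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      v <- stats::rnorm(npix, base_velocity, velocity_sd)
      v <- pmin(pmax(v, 0), sat_v)
      if (n_sat > 0) {
        idx <- sample.int(npix, n_sat)
        v[idx] <- stats::runif(n_sat, sat_v + 1e-6 * v_max, v_max)
      }
      matrix(v, nr, nc)
    })
  })
  swv_recording(maps, side = side, v_max = v_max)
}
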