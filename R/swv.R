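#' Shear-wave-velocity recording
#'
#' Per-frame pixel velocity maps from shear-wave elastography of one
#' tendon side, with the instrument ceiling and the saturation QC
#' thresholds. An optional binary region-of-interest mask restricts both
#' the saturation count and the velocity mean; without a mask the rule
#' applies to the full map.
#'
#' @param maps list of numeric matrices (m/s), one per frame, all the
#'   same shape.
#' @param side `"medial"` or `"lateral"`.
#' @param v_max maximal measurable velocity, m/s (default 20).
#' @param saturation_velocity_fraction fraction of `v_max` above which a
#'   pixel counts as saturated (default 0.90).
#' @param saturation_threshold_fraction recording-level discard
#'   threshold on the mean saturated-pixel fraction (default 0.05).
#' @param roi optional logical matrix, same shape as the maps.
#' @return an object of class `swv_recording`.
#' @export
swv_recording <- function(maps, side = c("medial", "lateral"),
                          v_max = 20,
                          saturation_velocity_fraction = 0.90,
                          saturation_threshold_fraction = 0.05,
                          roi = NULL) {
  side <- match.arg(side)
  if (is.matrix(maps)) maps <- list(maps)
  if (length(maps) < 1L) stopf("need at least one frame")
  shp <- dim(maps[[1]])
  ok <- vapply(maps, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stopf("all frames must have the same shape")
  rng <- range(unlist(lapply(maps, range)))
  if (rng[1] < 0 || rng[2] > v_max + 1e-9) {
    stopf("pixel velocities must lie in [0, v_max]")
  }
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), shp))
    roi <- as.logical(roi); dim(roi) <- shp
    if (!any(roi)) stopf("ROI mask is empty")
  }
  structure(list(maps = maps, side = side, v_max = v_max,
                 saturation_velocity_fraction = saturation_velocity_fraction,
                 saturation_threshold_fraction = saturation_threshold_fraction,
                 roi = roi),
            class = "swv_recording")
}

#' Mean saturated-pixel fraction of a recording
#'
#' Per frame, the fraction of (ROI) pixels whose velocity exceeds
#' `saturation_velocity_fraction * v_max` (18 m/s at the defaults); the
#' recording value is the mean of the per-frame fractions.
#'
#' @param rec an [swv_recording()].
#' @return fraction in `[0, 1]`.
#' @export
saturation_fraction <- function(rec) {
  stopifnot(inherits(rec, "swv_recording"))
  thr <- rec$saturation_velocity_fraction * rec$v_max
  fr <- vapply(rec$maps, function(m) {
    v <- if (is.null(rec$roi)) m else m[rec$roi]
    mean(v > thr)
  }, numeric(1))
  mean(fr)
}

#' Saturation QC and velocity summary of one recording
#'
#' A recording is discarded when more than
#' `saturation_threshold_fraction` (strictly) of its pixels, averaged
#' across frames, are saturated; a fraction exactly at the threshold
#' passes. Passing recordings are summarized by the pooled mean velocity
#' over all (ROI) pixels of all frames (set `per_frame = TRUE` to
#' average per-frame means instead); discarded recordings carry no mean.
#'
#' @param rec an [swv_recording()].
#' @param per_frame average per-frame means instead of pooling pixels.
#' @return an object of class `swv_summary`: list with `side`,
#'   `n_frames`, `saturation_fraction`, `passed_qc`, `mean_velocity`
#'   (NA when discarded).
#' @export
qc_recording <- function(rec, per_frame = FALSE) {
  stopifnot(inherits(rec, "swv_recording"))
  sat <- saturation_fraction(rec)
  passed <- sat <= rec$saturation_threshold_fraction
  mv <- if (!passed) NA_real_ else if (per_frame) {
    mean(vapply(rec$maps, function(m) {
      mean(if (is.null(rec$roi)) m else m[rec$roi])
    }, numeric(1)))
  } else {
    vals <- unlist(lapply(rec$maps, function(m) {
      if (is.null(rec$roi)) as.vector(m) else m[rec$roi]
    }))
    mean(vals)
  }
  structure(list(side = rec$side, n_frames = length(rec$maps),
                 saturation_fraction = sat, passed_qc = passed,
                 mean_velocity = mv),
            class = "swv_summary")
}

#' Mean-of-sides shear-wave velocity
#'
#' Unweighted arithmetic mean of the medial and lateral side means;
#' undefined (NA, flagged) when either side failed QC.
#'
#' @param medial,lateral `swv_summary` objects.
#' @return list with `mean_velocity` (NA when flagged) and `flagged`.
#' @export
side_mean <- function(medial, lateral) {
  stopifnot(inherits(medial, "swv_summary"), inherits(lateral, "swv_summary"))
  if (!isTRUE(medial$passed_qc) || !isTRUE(lateral$passed_qc)) {
    return(list(mean_velocity = NA_real_, flagged = TRUE))
  }
  list(mean_velocity = (medial$mean_velocity + lateral$mean_velocity) / 2,
       flagged = FALSE)
}
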