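#' Read and write the pipeline's on-disk formats
#'
#' Force traces travel as 2-column delimited text (`time_s`, `force_N`)
#' with the sampling rate and trigger recorded in a JSON sidecar or
#' header comment; frame stacks and velocity maps as multi-frame
#' grayscale TIFF (intensities scaled to `[0, 1]` by the stated
#' full-scale value); cohort tables as tab-separated text with header.
#'
#' @name tendonmech_io
NULL

#' @rdname tendonmech_io
#' @param trace a [force_trace()].
#' @param path output file.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g trigger_index=%d",
                     trace$rate, trace$trigger_index), con)
  t_s <- (seq_along(trace$samples) - 1L) / trace$rate
  utils::write.table(data.frame(time_s = t_s, force_N = trace$samples),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname tendonmech_io
#' @return `read_force_trace()`: a [force_trace()].
#' @export
read_force_trace <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("rate_hz=([0-9.eE+-]+) trigger_index=([0-9]+)", hdr))[[1]]
  if (length(m) != 3L) stopf("missing rate/trigger header in %s", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  force_trace(d$force_N, as.numeric(m[2]), as.integer(m[3]))
}

#' @rdname tendonmech_io
#' @param seq a [frame_sequence()].
#' @param full_scale intensity mapped to white (default 255).
#' @export
write_frames_tiff <- function(seq, path, full_scale = 255) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- dim(seq$frames)[3]
  imgs <- lapply(seq_len(n), function(f) {
    pmin(pmax(seq$frames[, , f] / full_scale, 0), 1)
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tendonmech_io
#' @param frame_rate,pixel_scale metadata not stored in the TIFF.
#' @return `read_frames_tiff()`: a [frame_sequence()].
#' @export
read_frames_tiff <- function(path, frame_rate, pixel_scale, full_scale = 255) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(imgs[[1]])[1:2], length(imgs)))
  for (f in seq_along(imgs)) arr[, , f] <- imgs[[f]] * full_scale
  frame_sequence(arr, frame_rate, pixel_scale)
}

#' @rdname tendonmech_io
#' @param rec an [swv_recording()].
#' @export
write_swv_tiff <- function(rec, path) {
  stopifnot(inherits(rec, "swv_recording"))
  imgs <- lapply(rec$maps, function(m) pmin(pmax(m / rec$v_max, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname tendonmech_io
#' @inheritParams swv_recording
#' @return `read_swv_tiff()`: an [swv_recording()].
#' @export
read_swv_tiff <- function(path, side = "medial", v_max = 20, roi = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  swv_recording(lapply(imgs, function(m) m * v_max),
                side = side, v_max = v_max, roi = roi)
}

#' @rdname tendonmech_io
#' @param track a [landmark_track()].
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "landmark_track"))
  d <- data.frame(frame = seq_len(nrow(track$positions)) - 1L,
                  x = track$positions[, 1], y = track$positions[, 2],
                  converged = track$status)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname tendonmech_io
#' @param table a cohort data.frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname tendonmech_io
#' @return `read_cohort()`: data.frame with factors releveled to the
#'   study's conventions (OC/NOC, pre/post, proximal/mid/distal).
#' @export
read_cohort <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if ("group" %in% names(d)) d$group <- factor(d$group, levels = c("OC", "NOC"))
  if ("time" %in% names(d)) d$time <- factor(d$time, levels = c("pre", "post"))
  if ("location" %in% names(d)) {
    d$location <- factor(d$location, levels = c("proximal", "mid", "distal"))
  }
  d
}

#' @rdname tendonmech_io
#' @param truth list of ground-truth values for one synthetic trial.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
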