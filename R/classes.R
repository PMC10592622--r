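# S3 containers shared across the pipeline.

#' Body-part keypoints tracked by the pipeline
#'
#' Limb keypoints are the four paws (LF, LR, RF, RR = left/right front/rear);
#' `gait_keypoints()` adds the nose and tail base used to define the body
#' axis.
#' @return Character vector of keypoint names.
#' @export
gait_limbs <- function() c("LF", "LR", "RF", "RR")

#' @rdname gait_limbs
#' @export
gait_keypoints <- function() c(gait_limbs(), "nose", "tail")

#' Construct a pose track
#'
#' A pose track holds frame-indexed 2-D coordinates (in mm) of the six
#' tracked body parts, with the acquisition frame rate and the pixel
#' calibration used to convert from image coordinates.
#'
#' @param coords Numeric array `n_frames x 6 x 2`; the keypoint dimension
#'   must be named with `gait_keypoints()` and the last dimension is (x, y)
#'   in mm. Missing samples are `NA`.
#' @param frame_rate Frames per second (> 0).
#' @param pixel_scale mm per pixel used during calibration (informational
#'   once coordinates are in mm).
#' @param frame_times Optional frame onset times in seconds; defaults to
#'   `(0:(n-1)) / frame_rate`. Each frame covers
#'   `[t, t + 1/frame_rate)`.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(coords, frame_rate, pixel_scale = NA_real_,
                       frame_times = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 6L,
            dim(coords)[3] == 2L)
  if (is.null(dimnames(coords)[[2]])) {
    dimnames(coords)[[2]] <- gait_keypoints()
  }
  if (!setequal(dimnames(coords)[[2]], gait_keypoints())) {
    stop("coords keypoints must be ", paste(gait_keypoints(), collapse = ", "))
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("'frame_rate' must be positive")
  }
  n <- dim(coords)[1]
  if (is.null(frame_times)) frame_times <- (seq_len(n) - 1) / frame_rate
  if (length(frame_times) != n) stop("'frame_times' length mismatch")
  dt <- diff(frame_times)
  if (n > 1 && (any(dt <= 0) || max(abs(dt - 1 / frame_rate)) > 1e-6)) {
    stop("'frame_times' must be uniform at 1/frame_rate and increasing")
  }
  structure(
    list(coords = coords, frame_times = frame_times, frame_rate = frame_rate,
         pixel_scale = pixel_scale),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  n <- dim(x$coords)[1]
  cat(sprintf("<pose_track> %d frames @ %g fps (%.1f s), %d keypoints\n",
              n, x$frame_rate, n / x$frame_rate, dim(x$coords)[2]))
  invisible(x)
}

#' @export
n_frames <- function(track) UseMethod("n_frames")

#' @export
n_frames.pose_track <- function(track) dim(track$coords)[1]

#' Construct a stride table
#'
#' Bundles the output of gait segmentation: per-limb strides, the
#' per-frame limb-phase series, and the walking bouts they came from.
#'
#' @param strides Data frame with columns `limb`, `stance_onset`,
#'   `swing_onset`, `next_stance_onset`, `length`, `duration`, `speed`,
#'   `swing_stance_ratio` (times in s, length in mm, speed in mm/s).
#' @param phase Numeric matrix `n_frames x 4` (columns `gait_limbs()`),
#'   limb phase in degrees `[0, 360)`, `NA` outside strides.
#' @param bouts Data frame of walking bouts (`bout_id`, `start`, `stop`,
#'   `accepted`, `rhythmicity_score`).
#' @param frame_times Frame onset times matching `phase` rows.
#' @param frame_rate Frames per second.
#' @return An object of class `stride_table`.
#' @export
stride_table <- function(strides, phase, bouts, frame_times, frame_rate) {
  stopifnot(is.data.frame(strides), is.matrix(phase),
            ncol(phase) == 4L, nrow(phase) == length(frame_times))
  if (is.null(colnames(phase))) colnames(phase) <- gait_limbs()
  structure(
    list(strides = strides, phase = phase, bouts = bouts,
         frame_times = frame_times, frame_rate = frame_rate),
    class = "stride_table"
  )
}

#' @export
print.stride_table <- function(x, ...) {
  tab <- table(factor(x$strides$limb, levels = gait_limbs()))
  cat(sprintf("<stride_table> %d strides (%s), %d accepted bouts\n",
              nrow(x$strides),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
              sum(x$bouts$accepted)))
  invisible(x)
}

#' Construct a spike train
#'
#' One unit's spike times in session time, with optional per-spike waveform
#' snippets and an optogenetic laser protocol appended after the behavioral
#' recording.
#'
#' @param times Sorted spike times in seconds.
#' @param session_end End of the recording in seconds (laser period
#'   included when present).
#' @param unit_id Identifier for the unit.
#' @param laser Optional `laser_protocol()` describing tagging pulses.
#' @param waveforms Optional numeric matrix `n_spikes x n_samples` of
#'   per-spike waveform snippets (rows align with `times`).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, session_end, unit_id = "unit",
                        laser = NULL, waveforms = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) && (times[1] < 0 || times[length(times)] > session_end)) {
    stop("spike times must lie within [0, session_end]")
  }
  if (!is.null(waveforms) && nrow(waveforms) != length(times)) {
    stop("'waveforms' must have one row per spike")
  }
  structure(
    list(unit_id = unit_id, times = times, session_end = session_end,
         laser = laser, waveforms = waveforms,
         first_laser_time = if (is.null(laser)) NA_real_ else
           laser$pulse_times[1]),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s (%.2f Hz)%s\n",
              x$unit_id, length(x$times), x$session_end,
              length(x$times) / x$session_end,
              if (is.null(x$laser)) "" else
                sprintf(", %d laser pulses", length(x$laser$pulse_times))))
  invisible(x)
}

#' Laser protocol for optogenetic tagging
#'
#' @param pulse_times Sorted pulse-onset times in seconds.
#' @param pulse_duration Pulse duration in seconds (default 10 ms).
#' @param artifact_window Post-onset window in which photoelectric
#'   artifacts can masquerade as spikes; spikes inside it are discarded by
#'   the tagging analysis (default 0.6 ms).
#' @return An object of class `laser_protocol`.
#' @export
laser_protocol <- function(pulse_times, pulse_duration = 0.010,
                           artifact_window = 0.0006) {
  pulse_times <- sort(as.numeric(pulse_times))
  stopifnot(artifact_window >= 0, pulse_duration > 0)
  structure(
    list(pulse_times = pulse_times, pulse_duration = pulse_duration,
         artifact_window = artifact_window),
    class = "laser_protocol"
  )
}

# internal: map event times onto frame indices (frame i covers
# [t_i, t_i + 1/frame_rate)); returns NA for times outside the video.
frame_index_of <- function(times, frame_times, frame_rate) {
  idx <- findInterval(times, frame_times)
  idx[idx == 0L] <- NA_integer_
  last_end <- frame_times[length(frame_times)] + 1 / frame_rate
  idx[times >= last_end] <- NA_integer_
  idx
}
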