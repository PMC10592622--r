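# Plain-text readers and writers for the pipeline's tabular formats.

#' Read a keypoint table from CSV
#'
#' Expects the long layout `frame, keypoint, x_px, y_px[, confidence]`;
#' coordinates are converted to mm via `pixel_scale`. Samples with
#' confidence below `min_confidence` become missing.
#'
#' @param path CSV file path.
#' @param frame_rate Frames per second.
#' @param pixel_scale mm per pixel.
#' @param min_confidence Confidence threshold (default 0.5; ignored when
#'   no confidence column is present).
#' @return A `pose_track`.
#' @export
read_pose_csv <- function(path, frame_rate, pixel_scale,
                          min_confidence = 0.5) {
  df <- utils::read.csv(path)
  need <- c("frame", "keypoint", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("pose CSV must contain columns ", paste(need, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  n <- length(frames)
  coords <- array(NA_real_, c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  if ("confidence" %in% names(df)) {
    low <- !is.na(df$confidence) & df$confidence < min_confidence
    df$x_px[low] <- NA_real_
    df$y_px[low] <- NA_real_
  }
  fi <- match(df$frame, frames)
  ki <- match(df$keypoint, gait_keypoints())
  ok <- !is.na(ki)
  coords[cbind(fi[ok], ki[ok], 1L)] <- df$x_px[ok] * pixel_scale
  coords[cbind(fi[ok], ki[ok], 2L)] <- df$y_px[ok] * pixel_scale
  pose_track(coords, frame_rate, pixel_scale)
}

#' Write a pose track to CSV
#'
#' Long layout `frame, keypoint, x_px, y_px, confidence` (coordinates
#' divided by the track's pixel scale; confidence 1 for observed
#' samples, 0 for missing).
#'
#' @param track A `pose_track`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path) {
  ps <- if (is.finite(track$pixel_scale)) track$pixel_scale else 1
  kp <- dimnames(track$coords)[[2]]
  df <- do.call(rbind, lapply(seq_along(kp), function(k) {
    x <- track$coords[, k, 1] / ps
    y <- track$coords[, k, 2] / ps
    data.frame(frame = seq_along(x) - 1L, keypoint = kp[k],
               x_px = x, y_px = y,
               confidence = as.numeric(is.finite(x) & is.finite(y)))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike times from a one-column CSV
#'
#' @param path CSV with a `time_s` column (or a single unnamed column).
#' @param session_end Session end in seconds (defaults to the last spike).
#' @param unit_id Unit label (defaults to the file name).
#' @return A `spike_train`.
#' @export
read_spike_csv <- function(path, session_end = NULL, unit_id = NULL) {
  df <- utils::read.csv(path)
  times <- if ("time_s" %in% names(df)) df$time_s else df[[1]]
  spike_train(times,
              session_end %||% max(times),
              unit_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write spike times to CSV
#' @param spikes A `spike_train`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  utils::write.csv(data.frame(time_s = spikes$times), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the tables of a session report
#'
#' Emits strides, walking bouts, motion bouts and (when present) the
#' unit x limb tuning table and per-unit summary as CSV, plus a JSON
#' session summary carrying the gait metrics, Venn counts and the
#' analysis parameters in effect.
#'
#' @param report A `session_report` from [run_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$strides$strides, file.path(dir, "strides.csv"),
                   row.names = FALSE)
  utils::write.csv(report$strides$bouts, file.path(dir, "walking_bouts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$motion_bouts, file.path(dir, "motion_bouts.csv"),
                   row.names = FALSE)
  if (!is.null(report$tuning)) {
    utils::write.csv(report$tuning, file.path(dir, "phase_tuning.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$units)) {
    utils::write.csv(report$units, file.path(dir, "units.csv"),
                     row.names = FALSE)
  }
  summary <- list(group = report$group, genotype = report$genotype,
                  gait = report$gait[c("per_limb", "totals")],
                  venn = report$venn,
                  excluded_units = report$excluded_units,
                  config = report$config)
  jsonlite::write_json(summary, file.path(dir, "session_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(dir)
}

#' Write a synthetic session to disk
#'
#' Saves the pose track, one spike-time CSV per unit, and a YAML
#' manifest naming every file together with the ground-truth generator
#' parameters, so a generated session can be re-analyzed from plain
#' files.
#'
#' @param track A `pose_track` from [generate_pose_track()].
#' @param spikes List of `spike_train` objects.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_synthetic_session <- function(track, spikes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pose_csv(track, file.path(dir, "pose.csv"))
  spike_files <- vapply(spikes, function(s) {
    f <- file.path(dir, paste0(s$unit_id, ".csv"))
    write_spike_csv(s, f)
    basename(f)
  }, character(1))
  truth <- attr(track, "truth")
  manifest <- list(
    pose = "pose.csv",
    frame_rate = track$frame_rate,
    pixel_scale = track$pixel_scale,
    spikes = as.list(spike_files),
    ground_truth = list(
      gait = if (!is.null(truth)) {
        p <- truth$params
        list(stride_frequency = p$stride_frequency,
             limb_phase_offsets = as.list(p$limb_phase_offsets),
             stride_amplitude = p$stride_amplitude,
             bout_schedule = p$bout_schedule, seed = p$seed)
      },
      units = lapply(spikes, function(s) {
        tp <- attr(s, "truth")$params
        if (is.null(tp)) return(list(unit_id = s$unit_id))
        list(unit_id = s$unit_id, base_rate = tp$base_rate,
             phase_kappa = tp$phase_kappa,
             preferred_phase = tp$preferred_phase,
             coupled_limb = tp$coupled_limb, seed = tp$seed)
      })
    )
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
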