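# Kinematics: from tracked keypoints to walking bouts, strides, limb phase
# and whole-body speed.

#' Configuration for gait segmentation
#'
#' Collects every tunable used between raw keypoints and the stride table.
#' Defaults follow the analysis conventions of the pipeline: mm, seconds
#' and degrees throughout.
#'
#' @param sg_window Savitzky-Golay window length in frames (odd, > 3;
#'   default 7, ~87 ms at 80 fps, preserving content up to the 8 Hz edge of
#'   the gait band).
#' @param band Gait frequency band in Hz (default `c(0.5, 8)`).
#' @param speed_threshold Candidate walking-bout body-speed threshold,
#'   mm/s (default 50).
#' @param min_bout_duration Minimum sustained supra-threshold duration, s
#'   (default 0.5).
#' @param merge_gap Candidate bouts separated by less than this are
#'   merged, s (default 0.25).
#' @param rhythmicity_threshold Minimum fraction of detrended
#'   projected-limb variance inside the gait band for a candidate bout to
#'   be auto-accepted (default 0.5).
#' @param min_prominence Extremum amplitude threshold as a fraction of the
#'   band-passed bout SD (default 0.1).
#' @param min_separation_s Minimum spacing between successive extrema of
#'   the same limb, s (default `1/16`, the half-period of the 8 Hz band
#'   edge).
#' @param stride_duration_range Admissible stride durations, s (default
#'   `c(1/8, 2)`, the gait band's period range).
#' @param max_gap_frames Missing-keypoint gaps up to this many frames are
#'   linearly interpolated (default 5); longer gaps invalidate the frames.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(sg_window = 7,
                        band = c(0.5, 8),
                        speed_threshold = 50,
                        min_bout_duration = 0.5,
                        merge_gap = 0.25,
                        rhythmicity_threshold = 0.5,
                        min_prominence = 0.1,
                        min_separation_s = 1 / 16,
                        stride_duration_range = c(1 / 8, 2),
                        max_gap_frames = 5) {
  structure(as.list(environment()), class = "gait_config")
}

# internal: linear interpolation of NA gaps up to max_gap frames
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  r <- rle(is.na(x))
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- pos[k] - 1L
    i1 <- pos[k] + r$lengths[k]
    if (i0 < 1L || i1 > n) next
    x[(i0 + 1L):(i1 - 1L)] <-
      approx(c(i0, i1), x[c(i0, i1)], xout = (i0 + 1L):(i1 - 1L))$y
  }
  x
}

#' Smooth a pose track with a Savitzky-Golay filter
#'
#' Each coordinate series is replaced by its third-order Savitzky-Golay
#' fit. Short missing-data gaps are linearly interpolated first.
#'
#' @param track A `pose_track`.
#' @param window_frames Odd window length in frames (> 3).
#' @param max_gap_frames Interpolate NA gaps up to this length.
#' @return The smoothed `pose_track` (same length; `truth` attribute, if
#'   any, is preserved).
#' @export
smooth_track <- function(track, window_frames = 7, max_gap_frames = 5) {
  stopifnot(inherits(track, "pose_track"))
  if (window_frames %% 2 != 1 || window_frames <= 3) {
    stop("'window_frames' must be odd and greater than 3")
  }
  if (window_frames > n_frames(track)) {
    stop("'window_frames' exceeds the track length")
  }
  coords <- track$coords
  for (k in seq_len(dim(coords)[2])) {
    for (d in 1:2) {
      x <- fill_short_gaps(coords[, k, d], max_gap_frames)
      if (anyNA(x)) {
        # smooth around remaining gaps segment by segment
        ok <- !is.na(x)
        r <- rle(ok)
        pos <- cumsum(c(1L, r$lengths))
        for (j in seq_along(r$lengths)) {
          if (!r$values[j]) next
          i0 <- pos[j]; i1 <- pos[j] + r$lengths[j] - 1L
          if (i1 - i0 + 1L >= window_frames) {
            x[i0:i1] <- signal::sgolayfilt(x[i0:i1], p = 3, n = window_frames)
          }
        }
      } else {
        x <- signal::sgolayfilt(x, p = 3, n = window_frames)
      }
      coords[, k, d] <- x
    }
  }
  out <- pose_track(coords, track$frame_rate, track$pixel_scale,
                    track$frame_times)
  attr(out, "truth") <- attr(track, "truth")
  out
}

#' Project a limb onto the nose-tail body axis
#'
#' Per-frame scalar position of a limb along the unit vector from the tail
#' base to the nose; larger values are closer to the nose. Frames with a
#' degenerate (coincident) nose-tail pair are flagged `NA` and interpolated
#' when isolated.
#'
#' @param track A `pose_track` (ideally smoothed).
#' @param limb One of `gait_limbs()`.
#' @return Numeric vector, mm per frame.
#' @export
project_limb <- function(track, limb) {
  stopifnot(inherits(track, "pose_track"), limb %in% gait_limbs())
  nose <- track$coords[, "nose", ]
  tail <- track$coords[, "tail", ]
  p <- track$coords[, limb, ]
  ax <- nose[, 1] - tail[, 1]
  ay <- nose[, 2] - tail[, 2]
  len <- sqrt(ax^2 + ay^2)
  bad <- !is.finite(len) | len < .Machine$double.eps^0.5
  len[bad] <- NA_real_
  proj <- ((p[, 1] - tail[, 1]) * ax + (p[, 2] - tail[, 2]) * ay) / len
  fill_short_gaps(proj, 5L)
}

#' Zero-phase band-pass of a projected limb signal
#'
#' Third-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), so extrema timing is not phase-shifted. The mean
#' is removed before filtering.
#'
#' @param x Numeric signal (one sample per frame).
#' @param frame_rate Sampling rate in frames/s (> 16, i.e. more than twice
#'   the 8 Hz band edge).
#' @param band Pass band in Hz, default `c(0.5, 8)`.
#' @return Filtered signal, same length.
#' @export
bandpass_gait <- function(x, frame_rate, band = c(0.5, 8)) {
  if (frame_rate <= 2 * band[2]) stop("'frame_rate' must exceed twice the band edge")
  bf <- signal::butter(3, band / (frame_rate / 2), type = "pass")
  x <- x - mean(x, na.rm = TRUE)
  x[is.na(x)] <- 0
  as.numeric(signal::filtfilt(bf, x))
}

# internal: zero-phase high-pass (used by the rhythmicity score)
highpass_gait <- function(x, frame_rate, cutoff = 0.5) {
  bf <- signal::butter(3, cutoff / (frame_rate / 2), type = "high")
  x <- x - mean(x, na.rm = TRUE)
  x[is.na(x)] <- 0
  as.numeric(signal::filtfilt(bf, x))
}

#' Whole-body speed from the keypoint centroid
#'
#' Speed is the magnitude of the centered finite-difference velocity of
#' the six-keypoint average position (one-sided at the ends).
#'
#' @param track A `pose_track`.
#' @return Numeric vector, mm/s per frame.
#' @export
body_speed <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  cx <- rowMeans(track$coords[, , 1], na.rm = TRUE)
  cy <- rowMeans(track$coords[, , 2], na.rm = TRUE)
  n <- length(cx)
  if (n < 3) return(rep(0, n))
  fr <- track$frame_rate
  vx <- c(cx[2] - cx[1], (cx[3:n] - cx[1:(n - 2)]) / 2, cx[n] - cx[n - 1]) * fr
  vy <- c(cy[2] - cy[1], (cy[3:n] - cy[1:(n - 2)]) / 2, cy[n] - cy[n - 1]) * fr
  sqrt(vx^2 + vy^2)
}

# internal: contiguous runs of a logical vector as (start, end) frame indices
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Identify well-defined walking bouts
#'
#' Candidate bouts are periods in which body speed exceeds
#' `speed_threshold` for at least `min_bout_duration` (gaps shorter than
#' `merge_gap` merged). Each candidate is then scored for limb
#' rhythmicity: the fraction of the detrended projected-limb variance that
#' falls inside the gait band, averaged over the four limbs. Candidates
#' scoring at least `rhythmicity_threshold` are auto-accepted; the
#' `overrides` argument (named logical vector, names = bout ids) replaces
#' the interactive review step and forces acceptance or rejection.
#'
#' @param track A `pose_track` (smoothed).
#' @param config A `gait_config()`.
#' @param overrides Optional named logical vector of manual accept/reject
#'   decisions keyed by bout id.
#' @return Data frame with `bout_id`, `start`, `stop` (s),
#'   `rhythmicity_score` and `accepted`.
#' @export
find_walking_bouts <- function(track, config = gait_config(),
                               overrides = NULL) {
  stopifnot(inherits(track, "pose_track"))
  fr <- track$frame_rate
  sp <- body_speed(track)
  fast <- sp > config$speed_threshold
  runs <- logical_runs(fast)
  if (nrow(runs)) {
    # merge runs separated by brief dips
    keep <- list()
    cur <- runs[1, ]
    for (k in seq_len(nrow(runs))[-1]) {
      if ((runs[k, 1] - cur[2] - 1) / fr < config$merge_gap) {
        cur[2] <- runs[k, 2]
      } else {
        keep[[length(keep) + 1]] <- cur
        cur <- runs[k, ]
      }
    }
    keep[[length(keep) + 1]] <- cur
    runs <- do.call(rbind, keep)
    runs <- runs[(runs[, 2] - runs[, 1] + 1) / fr >= config$min_bout_duration,
                 , drop = FALSE]
  }
  if (!nrow(runs)) {
    return(data.frame(bout_id = integer(), start = numeric(),
                      stop = numeric(), rhythmicity_score = numeric(),
                      accepted = logical()))
  }
  band_sig <- lapply(gait_limbs(), function(l) {
    pr <- project_limb(track, l)
    list(band = bandpass_gait(pr, fr, config$band),
         high = highpass_gait(pr, fr, config$band[1]))
  })
  score <- apply(runs, 1, function(r) {
    idx <- r[1]:r[2]
    mean(vapply(band_sig, function(s) {
      vb <- stats::var(s$band[idx])
      vh <- stats::var(s$high[idx])
      if (!is.finite(vh) || vh <= 0) return(0)
      min(vb / vh, 1)
    }, numeric(1)))
  })
  out <- data.frame(
    bout_id = seq_len(nrow(runs)),
    start = track$frame_times[runs[, 1]],
    stop = track$frame_times[runs[, 2]],
    rhythmicity_score = score,
    accepted = score >= config$rhythmicity_threshold
  )
  if (!is.null(overrides)) {
    ids <- as.integer(names(overrides))
    hit <- match(ids, out$bout_id)
    out$accepted[hit[!is.na(hit)]] <- as.logical(overrides)[!is.na(hit)]
  }
  out
}

# internal: alternating trough/peak detection on a band-passed segment.
# Returns a data.frame(idx, type) with type -1 = trough, +1 = peak,
# consecutive same-type extrema resolved by keeping the more extreme one.
find_alternating_extrema <- function(x, min_prominence_sd = 0.1,
                                     min_separation = 1L) {
  n <- length(x)
  if (n < 3) return(data.frame(idx = integer(), type = integer()))
  d <- sign(diff(x))
  # carry plateau signs forward so flat tops still register once
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  chg <- which(d[-1] != d[-length(d)] & d[-length(d)] != 0) + 1L
  if (!length(chg)) return(data.frame(idx = integer(), type = integer()))
  type <- ifelse(d[chg - 1L] > 0, 1L, -1L)
  thr <- min_prominence_sd * stats::sd(x)
  keep <- ifelse(type > 0, x[chg] >= thr, x[chg] <= -thr)
  idx <- chg[keep]; type <- type[keep]
  if (!length(idx)) return(data.frame(idx = integer(), type = integer()))
  # enforce alternation and minimum separation
  out_idx <- idx[1]; out_type <- type[1]
  for (k in seq_along(idx)[-1]) {
    m <- length(out_idx)
    if (type[k] == out_type[m]) {
      better <- if (type[k] > 0) x[idx[k]] > x[out_idx[m]] else
        x[idx[k]] < x[out_idx[m]]
      if (better) out_idx[m] <- idx[k]
    } else if (idx[k] - out_idx[m] < min_separation) {
      next
    } else {
      out_idx <- c(out_idx, idx[k])
      out_type <- c(out_type, type[k])
    }
  }
  data.frame(idx = out_idx, type = out_type)
}

#' Detect strides within walking bouts
#'
#' Within each accepted bout, stance onsets are troughs and swing onsets
#' are peaks of the band-passed nose-tail projection of each limb; strides
#' are assembled trough-peak-trough and incomplete cycles at bout edges
#' are discarded. Stride length is the Euclidean distance between the
#' limb's (smoothed, unfiltered) positions at the two stance onsets.
#'
#' @param track A smoothed `pose_track`.
#' @param bouts Walking-bout data frame from [find_walking_bouts()].
#' @param config A `gait_config()`.
#' @return Data frame of strides (see [stride_table()]).
#' @export
detect_strides <- function(track, bouts, config = gait_config()) {
  stopifnot(inherits(track, "pose_track"))
  fr <- track$frame_rate
  ft <- track$frame_times
  min_sep <- max(1L, floor(fr * config$min_separation_s))
  bouts <- bouts[bouts$accepted, , drop = FALSE]
  res <- list()
  for (limb in gait_limbs()) {
    proj <- project_limb(track, limb)
    filt <- bandpass_gait(proj, fr, config$band)
    for (b in seq_len(nrow(bouts))) {
      i0 <- which.min(abs(ft - bouts$start[b]))
      i1 <- which.min(abs(ft - bouts$stop[b]))
      if (i1 - i0 < 3) next
      seg <- filt[i0:i1]
      ext <- find_alternating_extrema(seg, config$min_prominence, min_sep)
      if (nrow(ext) < 3) next
      ext$idx <- ext$idx + i0 - 1L
      troughs <- which(ext$type == -1L)
      for (k in troughs) {
        if (k + 2L > nrow(ext)) break
        if (ext$type[k + 1L] != 1L || ext$type[k + 2L] != -1L) next
        st_i <- ext$idx[k]
        sw_i <- ext$idx[k + 1L]
        nx_i <- ext$idx[k + 2L]
        dur <- (nx_i - st_i) / fr
        if (dur < config$stride_duration_range[1] ||
            dur > config$stride_duration_range[2]) next
        dx <- track$coords[nx_i, limb, 1] - track$coords[st_i, limb, 1]
        dy <- track$coords[nx_i, limb, 2] - track$coords[st_i, limb, 2]
        len <- sqrt(dx^2 + dy^2)
        res[[length(res) + 1]] <- data.frame(
          limb = limb, bout_id = bouts$bout_id[b],
          stance_onset = ft[st_i], swing_onset = ft[sw_i],
          next_stance_onset = ft[nx_i],
          length = len, duration = dur, speed = len / dur,
          swing_stance_ratio = (nx_i - sw_i) / (sw_i - st_i)
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(limb = character(), bout_id = integer(),
                      stance_onset = numeric(), swing_onset = numeric(),
                      next_stance_onset = numeric(), length = numeric(),
                      duration = numeric(), speed = numeric(),
                      swing_stance_ratio = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign a per-frame gait phase to each limb
#'
#' Phase runs linearly from 0 degrees at each stance onset to 360 degrees
#' at the next stance onset; frames outside strides are `NA`.
#'
#' @param strides Stride data frame from [detect_strides()].
#' @param track The `pose_track` the strides came from.
#' @return Numeric matrix `n_frames x 4` (columns `gait_limbs()`), degrees
#'   in `[0, 360)`.
#' @export
assign_phase <- function(strides, track) {
  n <- n_frames(track)
  ft <- track$frame_times
  fr <- track$frame_rate
  phase <- matrix(NA_real_, n, 4, dimnames = list(NULL, gait_limbs()))
  for (limb in gait_limbs()) {
    s <- strides[strides$limb == limb, , drop = FALSE]
    for (k in seq_len(nrow(s))) {
      i0 <- frame_index_of(s$stance_onset[k], ft, fr)
      i1 <- frame_index_of(s$next_stance_onset[k], ft, fr)
      if (is.na(i0) || is.na(i1) || i1 <= i0) next
      idx <- i0:(i1 - 1L)
      phase[idx, limb] <- 360 * (idx - i0) / (i1 - i0)
    }
  }
  phase
}

#' Segment a pose track into a stride table
#'
#' Convenience wrapper running the whole kinematic chain: smoothing,
#' walking-bout identification, stride detection and phase assignment.
#'
#' @param track A raw `pose_track`.
#' @param config A `gait_config()`.
#' @param overrides Optional bout accept/reject overrides, see
#'   [find_walking_bouts()].
#' @return A `stride_table`.
#' @export
segment_gait <- function(track, config = gait_config(), overrides = NULL) {
  sm <- smooth_track(track, config$sg_window, config$max_gap_frames)
  bouts <- find_walking_bouts(sm, config, overrides)
  strides <- detect_strides(sm, bouts, config)
  phase <- assign_phase(strides, sm)
  stride_table(strides, phase, bouts, sm$frame_times, sm$frame_rate)
}

#' Relative limb phase and swing-start offsets
#'
#' For each limb pair (A, B): the circular mean of A's phase sampled at
#' B's stance onsets (degrees), and the mean swing-onset time of A within
#' B's strides relative to B's stance onset (seconds and as a fraction of
#' the stride).
#'
#' @param st A `stride_table`.
#' @param ref Reference limb(s); defaults to all four (all ordered pairs).
#' @return Data frame with `limb`, `ref`, `phase_offset_deg`,
#'   `phase_offset_sd_deg`, `swing_time_offset_s`, `swing_offset_frac`,
#'   `n` (stance onsets used). Pairs with no overlapping strides have
#'   `NA` offsets.
#' @export
relative_limb_phase <- function(st, ref = gait_limbs()) {
  stopifnot(inherits(st, "stride_table"))
  ft <- st$frame_times
  fr <- st$frame_rate
  out <- list()
  for (b in ref) {
    sb <- st$strides[st$strides$limb == b, , drop = FALSE]
    onset_idx <- frame_index_of(sb$stance_onset, ft, fr)
    onset_idx <- onset_idx[!is.na(onset_idx)]
    for (a in gait_limbs()) {
      ph <- st$phase[onset_idx, a]
      ph <- ph[!is.na(ph)]
      mean_ph <- if (length(ph)) circ_mean_deg(ph) else NA_real_
      sd_ph <- if (length(ph) >= 2) angular_deviation(ph) else NA_real_
      # swing-start offset of limb a inside each of b's strides
      sa <- st$strides[st$strides$limb == a, , drop = FALSE]
      offs <- rep(NA_real_, nrow(sb))
      fracs <- rep(NA_real_, nrow(sb))
      if (nrow(sa)) {
        for (k in seq_len(nrow(sb))) {
          w <- sa$swing_onset >= sb$stance_onset[k] &
            sa$swing_onset < sb$next_stance_onset[k]
          if (any(w)) {
            tsw <- min(sa$swing_onset[w])
            offs[k] <- tsw - sb$stance_onset[k]
            fracs[k] <- offs[k] / sb$duration[k]
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        limb = a, ref = b,
        phase_offset_deg = if (a == b) 0 else mean_ph,
        phase_offset_sd_deg = sd_ph,
        swing_time_offset_s = mean(offs, na.rm = TRUE),
        swing_offset_frac = mean(fracs, na.rm = TRUE),
        n = length(ph)
      )
    }
  }
  do.call(rbind, out)
}

#' Per-session gait summary metrics
#'
#' Per-limb stride statistics (mean, SD, CV of length, duration and speed,
#' and the swing:stance duration ratio), whole-body totals (distance,
#' mean body speed, movement-initiation rate) and the per-bout heading
#' change. Heading is the unwrapped angle of the tail-to-nose axis
#' relative to the start of each bout; with a right-hemisphere recording
#' convention and a bottom-up camera, positive change is contraversive
#' (counter-clockwise) and negative ipsiversive.
#'
#' @param st A `stride_table`.
#' @param track The (smoothed) `pose_track`.
#' @return A list with `per_limb` (data frame), `totals` (list) and
#'   `heading` (data frame of per-bout mean and final heading change,
#'   degrees).
#' @export
gait_summary <- function(st, track) {
  stopifnot(inherits(st, "stride_table"), inherits(track, "pose_track"))
  per_limb <- do.call(rbind, lapply(gait_limbs(), function(l) {
    s <- st$strides[st$strides$limb == l, , drop = FALSE]
    cv <- function(x) if (length(x) > 1 && mean(x) != 0)
      stats::sd(x) / mean(x) else 0
    data.frame(
      limb = l, n_strides = nrow(s),
      length_mean = mean(s$length), length_sd = stats::sd(s$length),
      length_cv = cv(s$length),
      duration_mean = mean(s$duration), duration_sd = stats::sd(s$duration),
      duration_cv = cv(s$duration),
      speed_mean = mean(s$speed), speed_sd = stats::sd(s$speed),
      speed_cv = cv(s$speed),
      swing_stance_ratio_mean = mean(s$swing_stance_ratio)
    )
  }))
  sp <- body_speed(track)
  fr <- track$frame_rate
  cx <- rowMeans(track$coords[, , 1], na.rm = TRUE)
  cy <- rowMeans(track$coords[, , 2], na.rm = TRUE)
  total_distance <- sum(sqrt(diff(cx)^2 + diff(cy)^2))
  mbouts <- detect_motion_bouts(sp, fr)
  session_duration <- n_frames(track) / fr

  heading_all <- unwrap_deg(atan2(
    track$coords[, "nose", 2] - track$coords[, "tail", 2],
    track$coords[, "nose", 1] - track$coords[, "tail", 1]) * 180 / pi)
  acc <- st$bouts[st$bouts$accepted, , drop = FALSE]
  heading <- do.call(rbind, lapply(seq_len(nrow(acc)), function(k) {
    i0 <- frame_index_of(acc$start[k], track$frame_times, fr)
    i1 <- frame_index_of(acc$stop[k], track$frame_times, fr)
    h <- heading_all[i0:i1] - heading_all[i0]
    data.frame(bout_id = acc$bout_id[k], mean_change_deg = mean(h),
               final_change_deg = h[length(h)])
  }))
  if (is.null(heading)) {
    heading <- data.frame(bout_id = integer(), mean_change_deg = numeric(),
                          final_change_deg = numeric())
  }
  list(
    per_limb = per_limb,
    totals = list(
      total_distance_mm = total_distance,
      mean_body_speed = mean(sp),
      session_duration_s = session_duration,
      n_motion_bouts = nrow(mbouts),
      initiation_rate_per_min = initiation_rate(mbouts, session_duration),
      mean_heading_change_deg = if (nrow(heading)) mean(heading$mean_change_deg)
        else NA_real_
    ),
    heading = heading
  )
}

# internal: unwrap a degree series so increments never jump more than 180
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1], x[1] + cumsum(d))
}
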