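# Whole-body motion bouts for event-aligned neural analysis.

#' Detect whole-body motion bouts from a speed series
#'
#' Motion bouts are contiguous runs of body speed above `high` (50 mm/s);
#' runs shorter than `min_duration` (0.3 s) are discarded. Each surviving
#' run is then extended backward and forward to the frames at which speed
#' crosses `low` (20 mm/s) -- the defined start and stop times -- and
#' overlapping extended bouts are merged. Ties at exactly the low
#' threshold count as above it.
#'
#' @param speed Per-frame body speed, mm/s (uniform sampling).
#' @param frame_rate Frames per second.
#' @param high Confirmation threshold, mm/s (default 50).
#' @param low Start/stop threshold, mm/s (default 20).
#' @param min_duration Minimum supra-`high` run duration, s (default 0.3).
#' @param frame_times Optional frame onset times (default
#'   `(0:(n-1))/frame_rate`).
#' @return Data frame with `start`, `stop` (s), `peak_speed` (mm/s) and
#'   `truncated` (bout touches a session edge).
#' @export
detect_motion_bouts <- function(speed, frame_rate, high = 50, low = 20,
                                min_duration = 0.3, frame_times = NULL) {
  n <- length(speed)
  if (is.null(frame_times)) frame_times <- (seq_len(n) - 1) / frame_rate
  runs <- logical_runs(speed > high)
  if (nrow(runs)) {
    runs <- runs[(runs[, 2] - runs[, 1] + 1) / frame_rate >= min_duration,
                 , drop = FALSE]
  }
  if (!nrow(runs)) {
    return(data.frame(start = numeric(), stop = numeric(),
                      peak_speed = numeric(), truncated = logical()))
  }
  slow_ok <- speed >= low
  ext <- t(apply(runs, 1, function(r) {
    a <- r[1]
    while (a > 1L && slow_ok[a - 1L]) a <- a - 1L
    b <- r[2]
    while (b < n && slow_ok[b + 1L]) b <- b + 1L
    c(a, b)
  }))
  # merge overlapping extended bouts
  ord <- order(ext[, 1])
  ext <- ext[ord, , drop = FALSE]
  merged <- list(ext[1, ])
  for (k in seq_len(nrow(ext))[-1]) {
    m <- length(merged)
    if (ext[k, 1] <= merged[[m]][2] + 1L) {
      merged[[m]][2] <- max(merged[[m]][2], ext[k, 2])
    } else {
      merged[[m + 1]] <- ext[k, ]
    }
  }
  ext <- do.call(rbind, merged)
  data.frame(
    start = frame_times[ext[, 1]],
    stop = frame_times[ext[, 2]],
    peak_speed = apply(ext, 1, function(r) max(speed[r[1]:r[2]])),
    truncated = ext[, 1] == 1L | ext[, 2] == n
  )
}

#' Movement-initiation rate
#'
#' @param bouts Motion-bout data frame from [detect_motion_bouts()].
#' @param session_duration Session length in seconds (> 0).
#' @return Bout starts per minute.
#' @export
initiation_rate <- function(bouts, session_duration) {
  if (!is.numeric(session_duration) || session_duration <= 0) {
    stop("'session_duration' must be positive")
  }
  nrow(bouts) / session_duration * 60
}
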