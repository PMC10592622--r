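# Start/stop and speed coding of whole-body motion.

# internal: count spikes in [a, b) for sorted spike times
count_in <- function(times, a, b) {
  findInterval(b - 1e-12, times) - findInterval(a - 1e-12, times)
}

# internal: usable events (full baseline and event windows in-session)
usable_events <- function(bouts, event, session_end) {
  ev <- if (event == "start") bouts$start else bouts$stop
  ev[ev - 5 >= 0 & ev + 0.5 <= session_end]
}

#' Start/stop coding test
#'
#' Compares, across motion bouts, the mean firing rate in a baseline
#' window (-5 to -1 s before the event) against the event window
#' (plus/minus 0.5 s around it) with a paired t-test. Bouts whose
#' baseline window extends outside the session are excluded.
#'
#' @param spikes A `spike_train` (or numeric spike times).
#' @param bouts Motion-bout data frame from [detect_motion_bouts()].
#' @param event `"start"` or `"stop"`.
#' @param session_end Session end used to validate windows; defaults to
#'   the spike train's (behavioral recordings should pass the pre-laser
#'   end).
#' @param alpha Significance level (default 0.05).
#' @return List with `event`, `n_events`, `baseline_rate`, `event_rate`,
#'   `p_value`, `significant`, and `modulation_index` (see
#'   [modulation_index()]). With fewer than 2 usable events all
#'   statistics are `NA` and `significant` is `FALSE`.
#' @export
start_stop_test <- function(spikes, bouts, event = c("start", "stop"),
                            session_end = NULL, alpha = 0.05) {
  event <- match.arg(event)
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  if (is.null(session_end)) {
    session_end <- if (inherits(spikes, "spike_train")) {
      if (!is.na(spikes$first_laser_time)) spikes$first_laser_time else
        spikes$session_end
    } else max(bouts$stop)
  }
  ev <- usable_events(bouts, event, session_end)
  if (length(ev) < 2) {
    return(list(event = event, n_events = length(ev),
                baseline_rate = NA_real_, event_rate = NA_real_,
                p_value = NA_real_, significant = FALSE,
                modulation_index = NA_real_))
  }
  base <- vapply(ev, function(t0) count_in(times, t0 - 5, t0 - 1) / 4,
                 numeric(1))
  evr <- vapply(ev, function(t0) count_in(times, t0 - 0.5, t0 + 0.5),
                numeric(1))
  d <- evr - base
  p <- if (all(d == 0)) 1 else if (stats::sd(d) == 0) 0 else
    stats::t.test(evr, base, paired = TRUE)$p.value
  list(event = event, n_events = length(ev),
       baseline_rate = mean(base), event_rate = mean(evr),
       p_value = p, significant = is.finite(p) && p < alpha,
       modulation_index = modulation_index(times, bouts, event, session_end))
}

#' Start/stop modulation index
#'
#' Firing rates are normalized by the mean baseline-window rate (so the
#' normalized baseline is ~1); the event-aligned average rate in the
#' plus/minus 0.5 s window is binned at 20 ms, and the index is
#' `|FR_event - FR_baseline| / FR_baseline` with `FR_event` the maximum
#' normalized bin. It therefore captures fractional rate changes of
#' either sign and is invariant to uniform rescaling of the unit's rate.
#'
#' @inheritParams start_stop_test
#' @param bin_width Event-window bin width, s (default 0.02).
#' @return Unitless index (>= 0), or `NA` when the baseline rate is zero
#'   or no event has full windows.
#' @export
modulation_index <- function(spikes, bouts, event = c("start", "stop"),
                             session_end = NULL, bin_width = 0.02) {
  event <- match.arg(event)
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  if (is.null(session_end)) {
    session_end <- if (inherits(spikes, "spike_train")) {
      if (!is.na(spikes$first_laser_time)) spikes$first_laser_time else
        spikes$session_end
    } else max(bouts$stop)
  }
  ev <- usable_events(bouts, event, session_end)
  if (!length(ev)) return(NA_real_)
  base_rate <- mean(vapply(ev, function(t0)
    count_in(times, t0 - 5, t0 - 1) / 4, numeric(1)))
  if (!is.finite(base_rate) || base_rate <= 0) return(NA_real_)
  edges <- seq(-0.5, 0.5, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (t0 in ev) {
    rel <- times[times >= t0 - 0.5 & times < t0 + 0.5] - t0
    counts <- counts + tabulate(findInterval(rel, edges,
                                             rightmost.closed = TRUE),
                                length(edges) - 1)
  }
  psth <- counts / (length(ev) * bin_width)
  fr_event <- max(psth / base_rate)
  abs(fr_event - 1)
}

#' Speed-coding score and shuffle test
#'
#' Whole-session body speed is binned in 10 mm/s increments; the
#' occupancy-normalized mean firing rate is computed per bin (bins with
#' occupancy below `min_occupancy` seconds are dropped as unstable). The
#' score is the absolute Pearson correlation between bin rate and bin
#' center. Significance: the correlation is recomputed after shuffling
#' the rate values across speed bins, `n_iter` times; the unit is speed
#' coding when the real |r| exceeds the shuffled |r| on more than
#' `percentile`% of iterations.
#'
#' @param spikes A `spike_train` (or numeric spike times).
#' @param speed Per-frame body speed, mm/s.
#' @param frame_times Frame onset times, s.
#' @param frame_rate Frames per second.
#' @param bin_width Speed bin width, mm/s (default 10).
#' @param min_occupancy Minimum bin occupancy, s (default 1).
#' @param n_iter Shuffle iterations (default 100).
#' @param percentile Significance percentile (default 95).
#' @return List of class `speed_tuning`: `bin_centers`, `rate`,
#'   `occupancy_s`, `score`, `p`, `significant`, `n_bins`. With fewer
#'   than 3 occupied bins the score is `NA` and `significant` `FALSE`.
#' @export
speed_coding <- function(spikes, speed, frame_times, frame_rate,
                         bin_width = 10, min_occupancy = 1,
                         n_iter = 100, percentile = 95) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  bin <- floor(speed / bin_width) + 1L
  nb <- max(bin, na.rm = TRUE)
  occ_frames <- tabulate(bin, nb)
  idx <- frame_index_of(times, frame_times, frame_rate)
  sb <- bin[idx[!is.na(idx)]]
  counts <- tabulate(sb[!is.na(sb)], nb)
  occ_s <- occ_frames / frame_rate
  keep <- occ_s >= min_occupancy
  centers <- (seq_len(nb) - 0.5) * bin_width
  if (sum(keep) < 3) {
    return(structure(list(bin_centers = centers[keep],
                          rate = counts[keep] / occ_s[keep],
                          occupancy_s = occ_s[keep], score = NA_real_,
                          p = NA_real_, significant = FALSE,
                          n_bins = sum(keep)),
                     class = "speed_tuning"))
  }
  rate <- counts[keep] / occ_s[keep]
  ctr <- centers[keep]
  score <- if (stats::sd(rate) == 0) 0 else abs(stats::cor(rate, ctr))
  null <- vapply(seq_len(n_iter), function(i) {
    r <- sample(rate)
    if (stats::sd(r) == 0) 0 else abs(stats::cor(r, ctr))
  }, numeric(1))
  exceed <- sum(null >= score)
  structure(
    list(bin_centers = ctr, rate = rate, occupancy_s = occ_s[keep],
         score = score, p = exceed / n_iter,
         significant = exceed / n_iter < 1 - percentile / 100,
         n_bins = sum(keep)),
    class = "speed_tuning"
  )
}

#' Session-wide firing rate
#'
#' Average spike rate over the recording, up to the first laser pulse
#' when a tagging protocol follows the behavioral session.
#'
#' @param spikes A `spike_train`.
#' @return Spikes/s.
#' @export
session_firing_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  end <- if (!is.na(spikes$first_laser_time)) spikes$first_laser_time else
    spikes$session_end
  sum(spikes$times < end) / end
}

#' Coding-category (Venn) summary across units
#'
#' Counts units by their combination of significant phase, speed and
#' start/stop coding, for the mixed single-limb/whole-body
#' representation analysis.
#'
#' @param units Data frame with logical columns `phase_coding`,
#'   `speed_coding`, `startstop_coding` (one row per unit).
#' @return List with per-category counts (all 8 combinations), the three
#'   marginal counts, and `n`.
#' @export
coding_venn <- function(units) {
  ph <- units$phase_coding
  sp <- units$speed_coding
  ss <- units$startstop_coding
  combos <- table(factor(paste0(ifelse(ph, "P", "-"),
                                ifelse(sp, "S", "-"),
                                ifelse(ss, "E", "-")),
                         levels = c("---", "P--", "-S-", "--E", "PS-",
                                    "P-E", "-SE", "PSE")))
  list(combinations = as.list(combos),
       phase = sum(ph), speed = sum(sp), startstop = sum(ss),
       all_three = sum(ph & sp & ss), n = nrow(units))
}
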