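# Optogenetic tagging: classify units as D1/D2 MSNs from laser-evoked
# responses and waveform similarity.

# internal: drop spikes inside the photoelectric artifact window after any
# pulse onset
remove_artifact_spikes <- function(times, protocol) {
  if (!length(times)) return(times)
  prev <- findInterval(times, protocol$pulse_times)
  rel <- times - c(-Inf, protocol$pulse_times)[prev + 1L]
  times[!(rel >= 0 & rel < protocol$artifact_window)]
}

#' Laser-evoked response test (tagging criterion 1)
#'
#' After removing spikes within the artifact window (0.6 ms) of each
#' pulse onset, per-pulse spike counts in the post-onset latency window
#' (0.6-6 ms) are compared with counts in duration-matched windows
#' immediately preceding each pulse, using a one-sided paired test. A
#' significant excess declares an evoked response; the latency is the
#' median first-spike time after onset among responsive pulses.
#'
#' @param spikes A `spike_train` (or numeric spike times).
#' @param protocol A `laser_protocol()` (at least 50 pulses).
#' @param latency_window Post-onset response window, s (default
#'   `c(0.0006, 0.006)`; the lower edge is the artifact window).
#' @param alpha Significance level (default 0.05).
#' @param test `"t"` (paired t-test, default) or `"wilcoxon"` (paired
#'   rank test).
#' @return List with `latency_significant`, `p_value`,
#'   `first_spike_latency` (s, `NA` when no pulse evokes a spike),
#'   `n_responsive_pulses`, `evoked_rate` and `baseline_rate` (spikes per
#'   window).
#' @export
evoked_response_test <- function(spikes, protocol,
                                 latency_window = c(0.0006, 0.006),
                                 alpha = 0.05, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(protocol, "laser_protocol"))
  if (length(protocol$pulse_times) < 50) {
    stop("need at least 50 laser pulses")
  }
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  times <- remove_artifact_spikes(sort(times), protocol)
  w <- latency_window[2] - latency_window[1]
  p0 <- protocol$pulse_times
  evoked <- vapply(p0, function(t0)
    count_in(times, t0 + latency_window[1], t0 + latency_window[2]),
    numeric(1))
  baseline <- vapply(p0, function(t0) count_in(times, t0 - w, t0),
                     numeric(1))
  d <- evoked - baseline
  p <- if (all(d == 0)) 1 else if (stats::sd(d) == 0) 0 else if (test == "t") {
    stats::t.test(evoked, baseline, paired = TRUE,
                  alternative = "greater")$p.value
  } else {
    suppressWarnings(stats::wilcox.test(evoked, baseline, paired = TRUE,
                                        alternative = "greater")$p.value)
  }
  resp <- which(evoked > 0)
  lat <- if (length(resp)) {
    stats::median(vapply(p0[resp], function(t0) {
      min(times[times > t0 + latency_window[1] &
                  times <= t0 + latency_window[2]]) - t0
    }, numeric(1)))
  } else NA_real_
  list(latency_significant = is.finite(p) && p < alpha, p_value = p,
       first_spike_latency = lat, n_responsive_pulses = length(resp),
       evoked_rate = mean(evoked), baseline_rate = mean(baseline))
}

#' Mean baseline and evoked waveforms of a unit
#'
#' Baseline spikes are those before the first laser pulse; evoked spikes
#' are those inside the post-onset latency window (artifact-window spikes
#' removed). Fewer than `min_evoked` evoked spikes leaves the evoked mean
#' undefined (and the unit untagged).
#'
#' @param spikes A `spike_train` carrying per-spike `waveforms`.
#' @param protocol A `laser_protocol()`.
#' @param latency_window Post-onset response window, s.
#' @param min_evoked Minimum evoked spike count (default 10).
#' @return List of class `unit_waveforms` with `baseline_mean_waveform`,
#'   `evoked_mean_waveform` (`NULL` when undefined), `n_baseline`,
#'   `n_evoked`.
#' @export
unit_waveforms <- function(spikes, protocol,
                           latency_window = c(0.0006, 0.006),
                           min_evoked = 10) {
  stopifnot(inherits(spikes, "spike_train"))
  if (is.null(spikes$waveforms)) stop("spike train carries no waveforms")
  times <- spikes$times
  keep <- rep(TRUE, length(times))
  prev <- findInterval(times, protocol$pulse_times)
  rel <- times - c(-Inf, protocol$pulse_times)[prev + 1L]
  keep[rel >= 0 & rel < protocol$artifact_window] <- FALSE
  is_evoked <- keep & rel >= latency_window[1] & rel <= latency_window[2]
  is_base <- keep & times < protocol$pulse_times[1]
  ev_n <- sum(is_evoked)
  structure(
    list(
      baseline_mean_waveform = if (sum(is_base))
        colMeans(spikes$waveforms[is_base, , drop = FALSE]) else NULL,
      evoked_mean_waveform = if (ev_n >= min_evoked)
        colMeans(spikes$waveforms[is_evoked, , drop = FALSE]) else NULL,
      n_baseline = sum(is_base), n_evoked = ev_n
    ),
    class = "unit_waveforms"
  )
}

#' Waveform similarity criteria (tagging criteria 2 and 3)
#'
#' Criterion 2: Pearson correlation between the mean evoked and mean
#' baseline waveforms. Criterion 3 (guards against the scale invariance
#' of the correlation): the ratio between the voltage-minimum magnitudes
#' of the two mean waveforms, symmetrized as `max(r, 1/r)` so it is at
#' least 1 and direction-independent.
#'
#' @param waveforms A `unit_waveforms` object (both means defined), or a
#'   list with `baseline_mean_waveform` and `evoked_mean_waveform`.
#' @return List with `waveform_r` and `min_ratio` (`NA` when either mean
#'   is undefined).
#' @export
waveform_criteria <- function(waveforms) {
  b <- waveforms$baseline_mean_waveform
  e <- waveforms$evoked_mean_waveform
  if (is.null(b) || is.null(e)) {
    return(list(waveform_r = NA_real_, min_ratio = NA_real_))
  }
  if (length(b) != length(e)) stop("waveforms must have equal sample counts")
  mb <- abs(min(b))
  me <- abs(min(e))
  ratio <- if (mb == 0 || me == 0) Inf else max(me / mb, mb / me)
  list(waveform_r = stats::cor(b, e), min_ratio = ratio)
}

#' Classify a unit as tagged D1/D2 MSN or untagged
#'
#' A unit is tagged when all three criteria pass: (1) a significant
#' short-latency evoked response, (2) evoked/baseline waveform
#' correlation above `r_threshold`, and (3) voltage-minimum ratio below
#' `ratio_threshold`. The cell-type label follows the session genotype
#' (`"D1-Cre"` -> D1, `"A2a-Cre"` -> D2).
#'
#' @param spikes A `spike_train` with waveforms and a laser protocol
#'   (unless `protocol`/`waveforms` are supplied).
#' @param protocol Optional `laser_protocol()` (defaults to
#'   `spikes$laser`).
#' @param waveforms Optional precomputed `unit_waveforms`.
#' @param genotype Session genotype: `"D1-Cre"`, `"A2a-Cre"` or `"none"`.
#' @param r_threshold Waveform correlation threshold (default 0.95).
#' @param ratio_threshold Voltage-minimum ratio threshold (default 2).
#' @param latency_window,alpha,test Passed to [evoked_response_test()].
#' @return List of class `tag_result`: `unit_id`, `latency_significant`,
#'   `first_spike_latency`, `waveform_r`, `min_ratio`, `tagged`, `label`.
#' @export
classify_unit <- function(spikes, protocol = NULL, waveforms = NULL,
                          genotype = c("none", "D1-Cre", "A2a-Cre"),
                          r_threshold = 0.95, ratio_threshold = 2,
                          latency_window = c(0.0006, 0.006),
                          alpha = 0.05, test = "t") {
  genotype <- match.arg(genotype)
  if (is.null(protocol)) protocol <- spikes$laser
  if (is.null(protocol)) stop("no laser protocol available")
  ev <- evoked_response_test(spikes, protocol, latency_window, alpha, test)
  if (is.null(waveforms)) {
    waveforms <- unit_waveforms(spikes, protocol, latency_window)
  }
  wc <- waveform_criteria(waveforms)
  tagged <- isTRUE(ev$latency_significant) &&
    is.finite(wc$waveform_r) && wc$waveform_r > r_threshold &&
    is.finite(wc$min_ratio) && wc$min_ratio < ratio_threshold
  label <- if (!tagged) "untagged" else
    switch(genotype, "D1-Cre" = "D1", "A2a-Cre" = "D2", "untagged")
  structure(
    list(unit_id = if (inherits(spikes, "spike_train")) spikes$unit_id else
           NA_character_,
         latency_significant = ev$latency_significant,
         latency_p = ev$p_value,
         first_spike_latency = ev$first_spike_latency,
         waveform_r = wc$waveform_r, min_ratio = wc$min_ratio,
         tagged = tagged, label = label),
    class = "tag_result"
  )
}
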