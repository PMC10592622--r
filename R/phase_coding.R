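# Spike coupling to the gait cycle: occupancy-normalized phase tuning,
# circular resultant, and the spike-time jitter null.

#' Occupancy-normalized firing rate versus limb phase
#'
#' Spikes are assigned to the video frame containing them (a frame covers
#' `[t, t + 1/frame_rate)`) and take that frame's limb phase; spikes on
#' frames without a defined phase (outside strides) are dropped. The rate
#' in each 15-degree bin is the spike count divided by the frame count in
#' that bin, times the frame rate. Bins with zero occupancy are flagged
#' `NA`.
#'
#' @param spikes A `spike_train` (or numeric vector of spike times).
#' @param phase Per-frame phase of one limb, degrees (`NA` outside
#'   strides), e.g. one column of `stride_table$phase`.
#' @param frame_times Frame onset times, s.
#' @param frame_rate Frames per second.
#' @param bin_width Phase bin width in degrees (default 15, i.e. 24 bins).
#' @param unit_id,limb Labels carried into the result.
#' @return An object of class `phase_tuning`: bin edges/centers, rate per
#'   bin, spike counts, occupancy (frames) and metadata.
#' @export
rate_by_phase <- function(spikes, phase, frame_times, frame_rate,
                          bin_width = 15, unit_id = NULL, limb = NULL) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  if (!any(!is.na(phase))) stop("no frames with defined phase")
  nb <- as.integer(round(360 / bin_width))
  frame_bin <- ifelse(is.na(phase), NA_integer_,
                      pmin(nb, floor(phase / bin_width) + 1L))
  occupancy <- tabulate(frame_bin, nb)
  idx <- frame_index_of(times, frame_times, frame_rate)
  sb <- frame_bin[idx[!is.na(idx)]]
  counts <- tabulate(sb[!is.na(sb)], nb)
  rate <- ifelse(occupancy > 0, counts / occupancy * frame_rate, NA_real_)
  structure(
    list(bin_edges = seq(0, 360, by = bin_width),
         bin_centers = seq(bin_width / 2, 360 - bin_width / 2, by = bin_width),
         rate = rate, counts = counts, occupancy = occupancy,
         n_spikes_used = sum(counts), frame_rate = frame_rate,
         unit_id = if (is.null(unit_id) && inherits(spikes, "spike_train"))
           spikes$unit_id else unit_id,
         limb = limb),
    class = "phase_tuning"
  )
}

#' Mean resultant vector of a phase-tuning curve
#'
#' The resultant of unit vectors at the bin centers weighted by the
#' per-bin firing rate, normalized by the summed rates. Length 0-1
#' measures entrainment strength; the angle is the preferred phase.
#'
#' @param tuning A `phase_tuning` from [rate_by_phase()] (at least two
#'   defined bins).
#' @return List with `length` and `angle` (degrees; `NA` when all rates
#'   are zero).
#' @export
mean_vector <- function(tuning) {
  stopifnot(inherits(tuning, "phase_tuning"))
  ok <- !is.na(tuning$rate)
  if (sum(ok) < 2) stop("need at least two defined phase bins")
  circ_resultant(tuning$bin_centers[ok], tuning$rate[ok])
}

# internal: fast vector length for the jitter null. frame_bin is the
# precomputed per-frame bin index (NA outside strides); occupancy fixed.
vector_length_fast <- function(times, frame_times, frame_rate, frame_bin,
                               occupancy, cosb, sinb) {
  idx <- frame_index_of(times, frame_times, frame_rate)
  b <- frame_bin[idx[!is.na(idx)]]
  counts <- tabulate(b[!is.na(b)], length(occupancy))
  rate <- ifelse(occupancy > 0, counts / occupancy * frame_rate, 0)
  tot <- sum(rate)
  if (tot <= 0) return(0)
  sqrt(sum(rate * cosb)^2 + sum(rate * sinb)^2) / tot
}

#' Spike-time jitter test of phase coupling
#'
#' Recomputes the mean vector length after adding an independent uniform
#' jitter on `[-jitter_halfwidth, +jitter_halfwidth]` to every spike time,
#' repeated `n_iter` times. Jittered spikes are re-binned against the same
#' phase series, so spikes jittered onto frames without a defined phase
#' are dropped, exactly as in the real computation. The unit is
#' significant for this limb when the real vector length exceeds more
#' than `percentile`% of the jittered lengths.
#'
#' @inheritParams rate_by_phase
#' @param n_iter Number of jitter iterations (default 100).
#' @param jitter_halfwidth Maximum jitter magnitude, s (default 0.5).
#' @param percentile Significance percentile (default 95).
#' @return List with `vector_length`, `vector_angle`, `jitter_p` (fraction
#'   of jittered lengths at or above the real one), `significant`,
#'   `n_spikes_used` and the jittered lengths.
#' @export
jitter_test <- function(spikes, phase, frame_times, frame_rate,
                        n_iter = 100, jitter_halfwidth = 0.5,
                        percentile = 95, bin_width = 15) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  tun <- rate_by_phase(times, phase, frame_times, frame_rate, bin_width)
  if (tun$n_spikes_used == 0) {
    return(list(vector_length = 0, vector_angle = NA_real_,
                jitter_p = 1, significant = FALSE, n_spikes_used = 0,
                null_lengths = rep(0, n_iter)))
  }
  mv <- mean_vector(tun)
  nb <- length(tun$occupancy)
  frame_bin <- ifelse(is.na(phase), NA_integer_,
                      pmin(nb, floor(phase / bin_width) + 1L))
  cosb <- cos(tun$bin_centers * pi / 180)
  sinb <- sin(tun$bin_centers * pi / 180)
  nspk <- length(times)
  null <- vapply(seq_len(n_iter), function(i) {
    jt <- times + stats::runif(nspk, -jitter_halfwidth, jitter_halfwidth)
    vector_length_fast(jt, frame_times, frame_rate, frame_bin,
                       tun$occupancy, cosb, sinb)
  }, numeric(1))
  exceed <- sum(null >= mv$length)
  list(vector_length = mv$length, vector_angle = mv$angle,
       jitter_p = exceed / n_iter,
       significant = exceed / n_iter < 1 - percentile / 100,
       n_spikes_used = tun$n_spikes_used, null_lengths = null)
}

#' Phase-coupling analysis of one unit across all four limbs
#'
#' Runs [rate_by_phase()], [mean_vector()] and [jitter_test()] per limb.
#' A unit is "phase coding" when significant for at least one limb (the
#' four per-limb tests are deliberately not corrected for multiplicity;
#' this mirrors the at-least-one-limb rule).
#'
#' @param spikes A `spike_train`.
#' @param st A `stride_table`.
#' @param n_iter,jitter_halfwidth,percentile See [jitter_test()].
#' @param bin_width Phase bin width, degrees.
#' @return Data frame: one row per limb with `unit_id`, `limb`,
#'   `vector_length`, `vector_angle`, `jitter_p`, `significant`,
#'   `n_spikes`.
#' @export
phase_coding_unit <- function(spikes, st, n_iter = 100,
                              jitter_halfwidth = 0.5, percentile = 95,
                              bin_width = 15) {
  stopifnot(inherits(st, "stride_table"))
  do.call(rbind, lapply(gait_limbs(), function(l) {
    jt <- jitter_test(spikes, st$phase[, l], st$frame_times, st$frame_rate,
                      n_iter, jitter_halfwidth, percentile, bin_width)
    data.frame(unit_id = spikes$unit_id, limb = l,
               vector_length = jt$vector_length,
               vector_angle = jt$vector_angle,
               jitter_p = jt$jitter_p, significant = jt$significant,
               n_spikes = jt$n_spikes_used)
  }))
}

#' Remove outlier units by vector length
#'
#' Units whose vector length exceeds the cutoff for any limb are excluded
#' from all downstream group analyses (including speed and start/stop
#' coding).
#'
#' @param tunings Long data frame as returned by [phase_coding_unit()]
#'   (rows = unit x limb).
#' @param cutoff Vector-length cutoff (default 0.9).
#' @return List with `kept` (filtered data frame) and `excluded`
#'   (character vector of unit ids).
#' @export
exclude_outliers <- function(tunings, cutoff = 0.9) {
  if (!nrow(tunings)) return(list(kept = tunings, excluded = character()))
  bad <- unique(tunings$unit_id[tunings$vector_length > cutoff])
  list(kept = tunings[!tunings$unit_id %in% bad, , drop = FALSE],
       excluded = as.character(bad))
}

#' Limb-coupling class of a unit
#'
#' Classifies the set of limbs a unit is significantly coupled to:
#' `none`, `single`, `pair-diagonal` (LF+RR or LR+RF), `pair-other`, or
#' `3+`. Also ranks the limbs by vector length.
#'
#' @param unit_tuning Data frame for one unit (four rows, one per limb)
#'   from [phase_coding_unit()].
#' @return List with `significant_limbs`, `class` and `ranked_limbs`.
#' @export
limb_coupling_profile <- function(unit_tuning) {
  stopifnot(all(gait_limbs() %in% unit_tuning$limb))
  sig <- unit_tuning$limb[unit_tuning$significant]
  cls <- if (length(sig) == 0) "none"
    else if (length(sig) == 1) "single"
    else if (length(sig) == 2) {
      if (setequal(sig, c("LF", "RR")) || setequal(sig, c("LR", "RF")))
        "pair-diagonal" else "pair-other"
    } else "3+"
  list(significant_limbs = sig, class = cls,
       ranked_limbs = unit_tuning$limb[order(-unit_tuning$vector_length)])
}
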