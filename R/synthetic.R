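# Synthetic session generator: pose tracks and spike trains with known
# ground-truth gait and coding parameters.

#' Parameters for the synthetic gait generator
#'
#' Defines a session of alternating rest and straight (optionally curved)
#' walking. During walking bouts each limb oscillates along the nose-tail
#' axis at `stride_frequency` with its assigned oscillator offset while the
#' body translates at the scheduled speed; between bouts the animal is
#' stationary.
#'
#' Default offsets encode a lateral-sequence gait: left-right alternation
#' within each girdle, near-synchronous diagonal pairs, footfall order
#' LR, LF, RR, RF. The small (10 degree) asymmetries reproduce the
#' "approximately" anti-phase same-side front-rear relationship seen in
#' walking mice.
#'
#' @param frame_rate Video frame rate, frames/s (default 80).
#' @param pixel_scale Calibration, mm/pixel (default 0.3).
#' @param stride_frequency Strides/s during walking (default 2.5; must lie
#'   inside the 0.5-8 Hz band used by stride segmentation).
#' @param limb_phase_offsets Named angular offsets (degrees) of each limb's
#'   oscillator relative to the common gait oscillator.
#' @param stride_amplitude Peak-to-peak limb excursion along the body axis,
#'   mm (default 15).
#' @param bout_schedule Data frame with columns `start`, `stop` (s) and
#'   `speed` (mm/s): the walking bouts. Defaults to five 30-s bouts in a
#'   300-s session at 60-120 mm/s, the typical range of spontaneous mouse
#'   walking speeds.
#' @param session_duration Session length in s (default 300).
#' @param body_length Nose-to-tail distance, mm (default 70).
#' @param timing_jitter_sd SD of stride-timing jitter, s (default 0.003).
#'   Implemented as a slowly varying (AR(1), ~0.5 s correlation time) phase
#'   noise with stationary SD `2*pi*stride_frequency*timing_jitter_sd`.
#' @param position_noise_sd Per-frame keypoint localization noise, mm
#'   (default 0.15).
#' @param turn_rate Heading change during bouts, degrees/s; positive turns
#'   counter-clockwise in the bottom-up view (default 0 = straight).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @return A list of class `gait_gen_params`.
#' @export
gait_gen_params <- function(frame_rate = 80,
                            pixel_scale = 0.3,
                            stride_frequency = 2.5,
                            limb_phase_offsets = c(LF = 175, LR = 0,
                                                   RF = 350, RR = 185),
                            stride_amplitude = 15,
                            bout_schedule = NULL,
                            session_duration = 300,
                            body_length = 70,
                            timing_jitter_sd = 0.003,
                            position_noise_sd = 0.15,
                            turn_rate = 0,
                            seed = 1L) {
  if (is.null(bout_schedule)) {
    bout_schedule <- data.frame(
      start = c(20, 75, 130, 185, 240),
      stop  = c(50, 105, 160, 215, 270),
      speed = c(60, 90, 75, 120, 105)
    )
  }
  if (frame_rate <= 0) stop("'frame_rate' must be positive")
  if (stride_frequency <= 0.5 || stride_frequency >= 8) {
    stop("'stride_frequency' must lie inside the 0.5-8 Hz gait band")
  }
  if (!all(gait_limbs() %in% names(limb_phase_offsets))) {
    stop("'limb_phase_offsets' must name all four limbs")
  }
  if (nrow(bout_schedule)) {
    b <- bout_schedule[order(bout_schedule$start), , drop = FALSE]
    if (any(b$stop <= b$start)) stop("bout stop must exceed start")
    if (nrow(b) > 1 && any(b$start[-1] < b$stop[-nrow(b)])) {
      stop("bouts must be non-overlapping and ordered")
    }
    if (b$start[1] < 0 || b$stop[nrow(b)] > session_duration) {
      stop("bouts must lie within the session")
    }
    bout_schedule <- b
  }
  if (timing_jitter_sd < 0 || position_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  structure(
    list(frame_rate = frame_rate, pixel_scale = pixel_scale,
         stride_frequency = stride_frequency,
         limb_phase_offsets = limb_phase_offsets[gait_limbs()],
         stride_amplitude = stride_amplitude,
         bout_schedule = bout_schedule,
         session_duration = session_duration,
         body_length = body_length,
         timing_jitter_sd = timing_jitter_sd,
         position_noise_sd = position_noise_sd,
         turn_rate = turn_rate,
         seed = as.integer(seed)),
    class = "gait_gen_params"
  )
}

#' Generate a synthetic pose track
#'
#' Simulates the six tracked keypoints of a walking mouse from
#' `gait_gen_params()`. The returned track carries a `truth` attribute
#' holding the generator parameters, the per-frame ground-truth limb phase
#' (degrees, `NA` outside bouts), the scheduled body speed, and the heading
#' series, so downstream stages can be validated against known values.
#'
#' @param params A `gait_gen_params()` object.
#' @return A `pose_track` with attribute `truth`.
#' @export
generate_pose_track <- function(params) {
  stopifnot(inherits(params, "gait_gen_params"))
  fr <- params$frame_rate
  n <- round(params$session_duration * fr)
  t <- (seq_len(n) - 1) / fr
  set.seed(params$seed)

  # scheduled body speed with short cosine ramps at bout edges
  speed <- numeric(n)
  in_bout <- logical(n)
  ramp <- 0.25
  sched <- params$bout_schedule
  for (k in seq_len(nrow(sched))) {
    sel <- t >= sched$start[k] & t < sched$stop[k]
    in_bout <- in_bout | sel
    s <- rep(sched$speed[k], sum(sel))
    tb <- t[sel] - sched$start[k]
    te <- sched$stop[k] - t[sel]
    s <- s * pmin(1, tb / ramp) * pmin(1, te / ramp)
    speed[sel] <- s
  }

  # heading and body-center path
  heading <- cumsum(ifelse(in_bout, params$turn_rate * pi / 180, 0)) / fr
  vx <- speed * cos(heading)
  vy <- speed * sin(heading)
  cx <- 100 + cumsum(vx) / fr
  cy <- 100 + cumsum(vy) / fr

  # common gait oscillator: advances only during bouts, plus AR(1) jitter
  phase_inc <- ifelse(in_bout, 2 * pi * params$stride_frequency / fr, 0)
  theta <- cumsum(phase_inc)
  if (params$timing_jitter_sd > 0) {
    sd_stat <- 2 * pi * params$stride_frequency * params$timing_jitter_sd
    rho <- exp(-1 / (0.5 * fr))             # ~0.5 s correlation time
    eps <- stats::rnorm(n, 0, sd_stat * sqrt(1 - rho^2))
    jit <- stats::filter(eps, rho, method = "recursive")
    theta <- theta + as.numeric(jit)
  }

  ux <- cos(heading); uy <- sin(heading)    # forward unit vector
  lx <- -uy; ly <- ux                       # leftward unit vector
  L <- params$body_length
  A <- params$stride_amplitude / 2

  anchors <- list(
    LF = c(0.25, 0.18), LR = c(-0.25, 0.18),
    RF = c(0.25, -0.18), RR = c(-0.25, -0.18)
  )
  coords <- array(NA_real_, c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  truth_phase <- matrix(NA_real_, n, 4, dimnames = list(NULL, gait_limbs()))
  for (limb in gait_limbs()) {
    delta <- params$limb_phase_offsets[[limb]] * pi / 180
    th <- theta - delta
    truth_phase[in_bout, limb] <- (th[in_bout] * 180 / pi) %% 360
    # oscillation frozen outside bouts (limb at rest posture)
    th_eff <- th
    osc <- ifelse(in_bout, -A * cos(th_eff), -A * cos(th_eff))
    # freeze: hold the last in-bout displacement during rest
    if (any(!in_bout)) {
      osc_hold <- osc
      last <- -A
      for (i in seq_len(n)) {
        if (in_bout[i]) last <- osc[i] else osc_hold[i] <- last
      }
      osc <- osc_hold
    }
    off <- anchors[[limb]]
    coords[, limb, 1] <- cx + (off[1] * L + osc) * ux + off[2] * L * lx
    coords[, limb, 2] <- cy + (off[1] * L + osc) * uy + off[2] * L * ly
  }
  coords[, "nose", 1] <- cx + 0.5 * L * ux
  coords[, "nose", 2] <- cy + 0.5 * L * uy
  coords[, "tail", 1] <- cx - 0.5 * L * ux
  coords[, "tail", 2] <- cy - 0.5 * L * uy

  if (params$position_noise_sd > 0) {
    coords <- coords + array(stats::rnorm(length(coords), 0,
                                          params$position_noise_sd),
                             dim(coords))
  }

  track <- pose_track(coords, fr, params$pixel_scale)
  attr(track, "truth") <- list(
    params = params, phase = truth_phase, speed = speed,
    in_bout = in_bout, heading_deg = heading * 180 / pi
  )
  track
}

#' Parameters for a synthetic phase-coupled unit
#'
#' Ground-truth firing model: an inhomogeneous Poisson process whose rate
#' is `base_rate` (plus a linear speed term) modulated multiplicatively by
#' a normalized von Mises kernel of the coupled limb's phase and by a
#' Gaussian start transient, rectified at zero. With this normalization the
#' expected recovered mean vector length is the Bessel ratio
#' `I1(kappa)/I0(kappa)`.
#'
#' @param base_rate Baseline firing rate, spikes/s.
#' @param phase_kappa von Mises concentration (>= 0; 0 = no coupling).
#' @param preferred_phase Preferred limb phase, degrees.
#' @param coupled_limb One of `gait_limbs()` or `NA` for an uncoupled unit.
#' @param speed_gain Linear speed term, (spikes/s)/(mm/s).
#' @param start_transient_amp Fractional rate increase at bout starts.
#' @param start_transient_width Gaussian SD of the start transient, s.
#' @param seed Integer seed.
#' @return A list of class `spike_gen_params`.
#' @export
spike_gen_params <- function(base_rate = 10,
                             phase_kappa = 1,
                             preferred_phase = 90,
                             coupled_limb = "LR",
                             speed_gain = 0,
                             start_transient_amp = 0,
                             start_transient_width = 0.2,
                             seed = 1L) {
  if (base_rate < 0) stop("'base_rate' must be non-negative")
  if (phase_kappa < 0) stop("'phase_kappa' must be non-negative")
  if (!is.na(coupled_limb) && !coupled_limb %in% gait_limbs()) {
    stop("'coupled_limb' must be one of ", paste(gait_limbs(), collapse = ", "),
         " or NA")
  }
  structure(
    list(base_rate = base_rate, phase_kappa = phase_kappa,
         preferred_phase = preferred_phase, coupled_limb = coupled_limb,
         speed_gain = speed_gain, start_transient_amp = start_transient_amp,
         start_transient_width = start_transient_width,
         seed = as.integer(seed)),
    class = "spike_gen_params"
  )
}

#' Generate spikes phase-locked to a limb's gait cycle
#'
#' Simulates an inhomogeneous Poisson spike train on a synthetic pose
#' track. The per-frame rate follows the model described in
#' [spike_gen_params()]; spikes are drawn per frame (piecewise-constant
#' rate) and placed uniformly within the frame.
#'
#' @param track A `pose_track` from [generate_pose_track()].
#' @param strides Optional `stride_table`; when supplied its phase series
#'   drives the modulation, otherwise the track's ground-truth phase is
#'   used.
#' @param params A `spike_gen_params()` object.
#' @return A `spike_train` with attribute `truth` recording the generator
#'   parameters.
#' @export
generate_phase_locked_spikes <- function(track, strides = NULL, params) {
  stopifnot(inherits(track, "pose_track"),
            inherits(params, "spike_gen_params"))
  truth <- attr(track, "truth")
  fr <- track$frame_rate
  n <- n_frames(track)
  if (is.null(strides)) {
    if (is.null(truth)) stop("need either 'strides' or a track with ground truth")
    phase <- truth$phase
  } else {
    phase <- strides$phase
  }
  rate <- rep(params$base_rate, n)
  if (params$speed_gain != 0) {
    sp <- if (!is.null(truth)) truth$speed else body_speed(track)
    rate <- rate + params$speed_gain * sp
  }
  if (!is.na(params$coupled_limb)) {
    if (!params$coupled_limb %in% colnames(phase)) {
      stop("coupled limb '", params$coupled_limb, "' missing from strides")
    }
    ph <- phase[, params$coupled_limb]
    k <- params$phase_kappa
    vm <- rep(1, n)
    ok <- !is.na(ph)
    vm[ok] <- exp(k * cos((ph[ok] - params$preferred_phase) * pi / 180)) /
      besselI(k, 0)
    rate <- rate * vm
  }
  if (params$start_transient_amp != 0 && !is.null(truth)) {
    t <- track$frame_times
    g <- rep(0, n)
    for (s in truth$params$bout_schedule$start) {
      g <- g + exp(-(t - s)^2 / (2 * params$start_transient_width^2))
    }
    rate <- rate * (1 + params$start_transient_amp * pmin(g, 1))
  }
  rate <- pmax(rate, 0)
  set.seed(params$seed)
  counts <- stats::rpois(n, rate / fr)
  idx <- rep(seq_len(n), counts)
  times <- sort(track$frame_times[idx] + stats::runif(length(idx)) / fr)
  st <- spike_train(times, session_end = n / fr,
                    unit_id = sprintf("sim%04d", params$seed))
  attr(st, "truth") <- list(params = params, rate = rate)
  st
}

#' Parameters for a synthetic optogenetic tagging protocol
#'
#' @param n_pulses Number of laser pulses (default 200).
#' @param pulse_period Seconds between pulse onsets (default 3).
#' @param pulse_duration Pulse duration, s (default 0.010).
#' @param evoked_latency Latency from pulse onset to the evoked spike, s
#'   (default 0.002, the shortest physiological tagging latency).
#' @param evoked_prob Probability per pulse of an evoked spike.
#' @param waveform_template Baseline mean waveform (voltage samples);
#'   default a stereotyped biphasic extracellular spike.
#' @param evoked_scale Amplitude multiplier applied to evoked waveforms
#'   (1 = identical waveform; a negative value inverts it).
#' @param evoked_template Optional different waveform shape for evoked
#'   spikes (overrides scaling of `waveform_template`).
#' @param waveform_noise_sd Per-sample additive waveform noise.
#' @param latency_jitter_sd SD of evoked-spike latency jitter, s.
#' @param seed Integer seed.
#' @return A list of class `tag_gen_params`.
#' @export
tag_gen_params <- function(n_pulses = 200,
                           pulse_period = 3,
                           pulse_duration = 0.010,
                           evoked_latency = 0.002,
                           evoked_prob = 0.9,
                           waveform_template = NULL,
                           evoked_scale = 1,
                           evoked_template = NULL,
                           waveform_noise_sd = 2,
                           latency_jitter_sd = 0.0003,
                           seed = 1L) {
  if (evoked_latency < 0) stop("'evoked_latency' must be non-negative")
  if (evoked_prob < 0 || evoked_prob > 1) {
    stop("'evoked_prob' must lie in [0, 1]")
  }
  if (is.null(waveform_template)) {
    # biphasic extracellular spike: sharp negative trough, slow positive bump
    s <- seq(0, 1.6, length.out = 40)
    waveform_template <- -120 * exp(-((s - 0.35) / 0.1)^2) +
      45 * exp(-((s - 0.75) / 0.25)^2)
  }
  structure(
    list(n_pulses = n_pulses, pulse_period = pulse_period,
         pulse_duration = pulse_duration, evoked_latency = evoked_latency,
         evoked_prob = evoked_prob, waveform_template = waveform_template,
         evoked_scale = evoked_scale, evoked_template = evoked_template,
         waveform_noise_sd = waveform_noise_sd,
         latency_jitter_sd = latency_jitter_sd, seed = as.integer(seed)),
    class = "tag_gen_params"
  )
}

#' Generate a unit with an optogenetic tagging block
#'
#' Background spiking (homogeneous Poisson at the background `base_rate`)
#' runs for `session_duration` seconds; the laser protocol then starts 10 s
#' later, with evoked spikes at `evoked_latency` after each pulse with
#' probability `evoked_prob`. Every spike carries a waveform snippet drawn
#' from the baseline template, with evoked spikes scaled by `evoked_scale`
#' (or given their own shape via `evoked_template`).
#'
#' @param params A `tag_gen_params()` object.
#' @param background A `spike_gen_params()` object (only `base_rate` and
#'   `seed` are used for the homogeneous background).
#' @param session_duration Behavioral recording duration before the laser
#'   block, s (default 300).
#' @return A `spike_train` with a `laser_protocol`, per-spike waveforms,
#'   and a `truth` attribute flagging which spikes were evoked.
#' @export
generate_tagged_unit <- function(params, background, session_duration = 300) {
  stopifnot(inherits(params, "tag_gen_params"),
            inherits(background, "spike_gen_params"))
  set.seed(params$seed)
  first_pulse <- session_duration + 10
  pulses <- first_pulse + params$pulse_period * (seq_len(params$n_pulses) - 1)
  session_end <- pulses[length(pulses)] + params$pulse_period

  n_bg <- stats::rpois(1, background$base_rate * session_end)
  bg <- sort(stats::runif(n_bg, 0, session_end))
  hit <- stats::runif(params$n_pulses) < params$evoked_prob
  ev <- pulses[hit] + params$evoked_latency +
    stats::rnorm(sum(hit), 0, params$latency_jitter_sd)
  ev <- pmax(ev, pulses[hit] + 0.0008)   # stay clear of the artifact window

  times <- c(bg, ev)
  evoked <- c(rep(FALSE, length(bg)), rep(TRUE, length(ev)))
  ord <- order(times)
  times <- times[ord]
  evoked <- evoked[ord]

  tmpl <- params$waveform_template
  ev_tmpl <- if (!is.null(params$evoked_template)) params$evoked_template else
    params$evoked_scale * tmpl
  if (length(ev_tmpl) != length(tmpl)) {
    stop("'evoked_template' must match 'waveform_template' length")
  }
  wf <- matrix(rep(tmpl, each = length(times)), nrow = length(times))
  if (any(evoked)) {
    wf[evoked, ] <- matrix(rep(ev_tmpl, each = sum(evoked)), nrow = sum(evoked))
  }
  wf <- wf + matrix(stats::rnorm(length(wf), 0, params$waveform_noise_sd),
                    nrow = nrow(wf))

  st <- spike_train(times, session_end = session_end,
                    unit_id = sprintf("tag%04d", params$seed),
                    laser = laser_protocol(pulses, params$pulse_duration),
                    waveforms = wf)
  attr(st, "truth") <- list(params = params, background = background,
                            evoked = evoked)
  st
}
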