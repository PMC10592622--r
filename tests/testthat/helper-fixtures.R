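# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default 300-s synthetic session, segmented
default_session <- function() {
  fixture("default_session", function() {
    params <- gait_gen_params(seed = 42)
    track <- generate_pose_track(params)
    sm <- smooth_track(track)
    st <- segment_gait(track)
    list(params = params, track = track, sm = sm, st = st,
         speed = body_speed(sm))
  })
}

# noiseless two-bout session for exactness checks
noiseless_session <- function() {
  fixture("noiseless_session", function() {
    params <- gait_gen_params(
      session_duration = 120,
      bout_schedule = data.frame(start = c(10, 60), stop = c(40, 100),
                                 speed = 75),
      timing_jitter_sd = 0, position_noise_sd = 0, seed = 7)
    track <- generate_pose_track(params)
    list(params = params, track = track, st = segment_gait(track))
  })
}

# stationary body with one limb following a pure sinusoid along the body
# axis; bout supplied by hand. Troughs of the projection are strictly
# interior to the bout, so a 10-s bout at `freq` Hz holds
# `10 * freq` troughs and one fewer complete stride.
make_sinusoid_track <- function(freq = 2.5, amp = 10, session = 30,
                                frame_rate = 80, phase_shift_s = 0.01) {
  n <- session * frame_rate
  t <- (seq_len(n) - 1) / frame_rate
  coords <- array(0, c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  coords[, "nose", 1] <- 135
  coords[, "tail", 1] <- 65
  coords[, , 2] <- 100
  osc <- -amp * cos(2 * pi * freq * (t - phase_shift_s))
  for (l in gait_limbs()) coords[, l, 1] <- 100 + osc
  coords[, "LF", 2] <- coords[, "RF", 2] <- 112
  coords[, "LR", 2] <- coords[, "RR", 2] <- 88
  list(track = pose_track(coords, frame_rate),
       bouts = data.frame(bout_id = 1L, start = 10, stop = 20,
                          rhythmicity_score = 1, accepted = TRUE))
}

# regular (deterministic) spike train at a fixed rate over [from, to)
regular_spikes <- function(rate, from, to) {
  if (rate <= 0) return(numeric())
  seq(from + 1 / (2 * rate), to, by = 1 / rate)
}
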