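test_that("Savitzky-Golay smoothing reproduces cubics and denoises", {
  n <- 400
  t <- seq_len(n)
  cubic <- 1e-4 * t^3 - 0.02 * t^2 + 0.5 * t + 3
  coords <- array(rep(cubic, 12), c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  tr <- pose_track(coords, 80)
  sm <- smooth_track(tr, 11)
  expect_equal(sm$coords[, "LF", 1], cubic, tolerance = 1e-6)

  # constant unchanged
  coords[] <- 5
  sm2 <- smooth_track(pose_track(coords, 80), 7)
  expect_equal(sm2$coords[, "nose", 2], rep(5, n), tolerance = 1e-9)

  # noisy sinusoid: residual SD strictly below input noise SD
  set.seed(31)
  clean <- 10 * sin(2 * pi * 2.5 * t / 80)
  noise <- rnorm(n, 0, 0.5)
  coords[, , 1] <- clean + noise
  sm3 <- smooth_track(pose_track(coords, 80), 7)
  expect_lt(sd(sm3$coords[, "LF", 1] - clean), sd(noise))

  expect_error(smooth_track(tr, 8), "odd")
  expect_error(smooth_track(tr, 3), "odd|greater")
  expect_error(smooth_track(pose_track(coords[1:5, , , drop = FALSE], 80), 7),
               "exceeds")
})

test_that("limb projection is geometric and rotation-invariant", {
  n <- 10
  coords <- array(0, c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  coords[, "tail", ] <- 0
  coords[, "nose", 1] <- 70
  coords[, "LF", ] <- coords[, "nose", ]     # at the nose
  coords[, "LR", ] <- coords[, "tail", ]     # at the tail
  coords[, "RF", 1] <- 35; coords[, "RF", 2] <- 12  # off-axis midpoint
  coords[, "RR", 1] <- 20
  tr <- pose_track(coords, 80)
  expect_equal(project_limb(tr, "LF"), rep(70, n))
  expect_equal(project_limb(tr, "LR"), rep(0, n))
  expect_equal(project_limb(tr, "RF"), rep(35, n))

  # rotate everything by 90 degrees about an arbitrary center
  rot <- coords
  rot[, , 1] <- -(coords[, , 2] - 30) + 5
  rot[, , 2] <- (coords[, , 1] - 11) + 60
  tr2 <- pose_track(rot, 80)
  for (l in gait_limbs()) {
    expect_equal(project_limb(tr2, l), project_limb(tr, l),
                 tolerance = 1e-9)
  }
})

test_that("gait band-pass keeps 2.5 Hz, kills DC and 20 Hz", {
  fr <- 80
  t <- (0:3999) / fr
  expect_lt(max(abs(bandpass_gait(rep(3, 4000), fr))), 1e-6)
  mid <- 1000:3000  # avoid filter edge transients
  y1 <- bandpass_gait(sin(2 * pi * 2.5 * t), fr)
  expect_equal(max(abs(y1[mid])), 1, tolerance = 0.05)
  y2 <- bandpass_gait(sin(2 * pi * 20 * t), fr)
  expect_lt(max(abs(y2[mid])), 0.1)
  expect_error(bandpass_gait(rep(0, 100), 15), "frame_rate")
})

test_that("stride detection on a noiseless sinusoid is exact", {
  fx <- make_sinusoid_track(freq = 2.5, session = 30)
  strides <- detect_strides(fx$track, fx$bouts)
  for (l in gait_limbs()) {
    s <- strides[strides$limb == l, ]
    expect_equal(nrow(s), 24)
    # durations 0.4 s within one frame
    expect_true(all(abs(s$duration - 0.4) <= 1 / 80 + 1e-9))
    # exact partition: stance + swing = stride duration
    stance <- s$swing_onset - s$stance_onset
    swing <- s$next_stance_onset - s$swing_onset
    expect_equal(stance + swing, s$duration, tolerance = 1e-12)
  }
})

test_that("consecutive troughs with no prominent peak keep the deeper one", {
  # two troughs separated by a bump that stays below the prominence
  # threshold: the shallower trough must be discarded
  t <- (0:799) / 80
  x <- 10 * sin(2 * pi * 2 * t)
  # carve the trough near t = 1.375 into two dips (-4 then -9) separated
  # by a small negative bump (not a countable peak: below +prominence)
  win <- which(t >= 1.25 & t <= 1.5)
  tt <- t[win]
  x[win] <- -3 - 1 * exp(-((tt - 1.30) / 0.02)^2) -
    6 * exp(-((tt - 1.45) / 0.02)^2)
  ext <- gaitcoupling:::find_alternating_extrema(x, 0.1, 2L)
  troughs <- ext$idx[ext$type == -1L]
  d_deep <- min(abs(t[troughs] - 1.45))
  d_shallow <- min(abs(t[troughs] - 1.30))
  expect_lt(d_deep, 0.03)
  expect_gt(d_shallow, 0.1)
  # alternation restored: trough/peak types strictly alternate
  expect_true(all(abs(diff(ext$type)) == 2))
})

test_that("phase assignment is linear from 0 at stance to 360 at next stance", {
  fx <- make_sinusoid_track()
  strides <- detect_strides(fx$track, fx$bouts)
  phase <- assign_phase(strides, fx$track)
  s <- strides[strides$limb == "LR", ][3, ]
  i0 <- which.min(abs(fx$track$frame_times - s$stance_onset))
  i1 <- which.min(abs(fx$track$frame_times - s$next_stance_onset))
  expect_equal(unname(phase[i0, "LR"]), 0)
  mid <- i0 + (i1 - i0) / 2
  expect_equal(unname(phase[mid, "LR"]), 180, tolerance = 360 / (i1 - i0))
  inc <- diff(phase[i0:(i1 - 1), "LR"])
  expect_equal(max(inc) - min(inc), 0, tolerance = 1e-9)  # constant slope
  expect_true(all(phase[i0:(i1 - 1), "LR"] < 360))
})

test_that("body speed: stationary ~0, uniform translation exact", {
  n <- 400
  coords <- array(50, c(n, 6, 2),
                  dimnames = list(NULL, gait_keypoints(), c("x", "y")))
  expect_lt(max(body_speed(pose_track(coords, 80))), 1e-9)
  drift <- (seq_len(n) - 1) * 100 / 80   # 100 mm/s
  coords[, , 1] <- coords[, , 1] + drift
  sp <- body_speed(pose_track(coords, 80))
  expect_true(all(abs(sp - 100) <= 1))
})

test_that("walking-bout acceptance requires rhythmic limbs; overrides work", {
  ds <- default_session()
  bouts <- ds$st$bouts
  expect_equal(nrow(bouts), 5)
  expect_true(all(bouts$accepted))
  expect_true(all(bouts$rhythmicity_score > 0.9))

  # same body translation but random limb jitter: candidates rejected
  set.seed(33)
  p <- ds$params
  tr <- generate_pose_track(p)
  jit <- tr
  for (l in gait_limbs()) {
    jit$coords[, l, 1] <- tr$coords[, "tail", 1] + 20 + rnorm(n_frames(tr), 0, 8)
    jit$coords[, l, 2] <- tr$coords[, "tail", 2] + rnorm(n_frames(tr), 0, 8)
  }
  b2 <- find_walking_bouts(jit, gait_config())
  expect_gt(nrow(b2), 0)
  expect_false(any(b2$accepted))
  expect_true(all(b2$rhythmicity_score < 0.5))

  # override file contract: force-reject an accepted bout
  b3 <- find_walking_bouts(ds$sm, gait_config(),
                           overrides = c("2" = FALSE))
  expect_false(b3$accepted[b3$bout_id == 2])
  expect_true(b3$accepted[b3$bout_id == 1])
})

test_that("relative limb phase recovers the lateral-sequence geometry", {
  ds <- default_session()
  rel <- relative_limb_phase(ds$st, ref = "LR")
  get <- function(l) rel$phase_offset_deg[rel$limb == l]
  expect_equal(get("LR"), 0)
  # diagonal partner near 0
  expect_lt(abs(((get("RF") + 180) %% 360) - 180), 15)
  # same-side front-rear near 180
  expect_lt(abs(get("LF") - 180), 15)
  expect_lt(abs(get("RR") - 180), 15)
  # the reference limb's own swing sits near mid-stride (stance ~ swing)
  sw <- setNames(rel$swing_offset_frac, rel$limb)
  expect_equal(sw[["LR"]], 0.5, tolerance = 0.1)
  expect_true(all(is.finite(sw)))
})

test_that("gait summary recovers generator stride length and straight heading", {
  ds <- default_session()
  gs <- gait_summary(ds$st, ds$sm)
  # ground truth stride length per bout = speed / stride_frequency,
  # averaged with the per-bout stride counts
  sched <- ds$params$bout_schedule
  expected <- mean(sched$speed / ds$params$stride_frequency)
  expect_equal(mean(gs$per_limb$length_mean), expected,
               tolerance = 0.05 * expected)
  expect_equal(mean(gs$per_limb$duration_mean), 0.4, tolerance = 0.02)
  expect_lt(abs(gs$totals$mean_heading_change_deg), 5)
  expect_equal(gs$totals$n_motion_bouts, 5)
  # all-identical strides give zero CVs
  st0 <- ds$st
  st0$strides <- data.frame(limb = "LR", bout_id = 1,
                            stance_onset = c(0, 1), swing_onset = c(0.5, 1.5),
                            next_stance_onset = c(1, 2), length = 30,
                            duration = 1, speed = 30, swing_stance_ratio = 1)
  gs0 <- gait_summary(st0, ds$sm)
  lr <- gs0$per_limb[gs0$per_limb$limb == "LR", ]
  expect_equal(lr$length_cv, 0)
  expect_equal(lr$duration_cv, 0)
})

test_that("rigid transforms leave stride metrics and phase unchanged", {
  ns <- noiseless_session()
  ang <- 37 * pi / 180
  rot <- ns$track
  xy <- ns$track$coords
  rot$coords[, , 1] <- xy[, , 1] * cos(ang) - xy[, , 2] * sin(ang) + 50
  rot$coords[, , 2] <- xy[, , 1] * sin(ang) + xy[, , 2] * cos(ang) - 20
  st2 <- segment_gait(rot)
  expect_equal(nrow(st2$strides), nrow(ns$st$strides))
  expect_equal(st2$strides$duration, ns$st$strides$duration)
  expect_equal(st2$strides$length, ns$st$strides$length, tolerance = 1e-8)
  expect_equal(st2$phase, ns$st$phase, tolerance = 1e-8)
})

test_that("missing keypoints: short gaps interpolated, long gaps survive", {
  fx <- make_sinusoid_track()
  tr <- fx$track
  tr$coords[800:803, "LR", 1] <- NA   # 4-frame gap, interpolated
  sm <- smooth_track(tr, 7)
  expect_false(anyNA(sm$coords[, "LR", 1]))
  strides <- detect_strides(sm, fx$bouts)
  expect_gt(nrow(strides[strides$limb == "LR", ]), 20)
})
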