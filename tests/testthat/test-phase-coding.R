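# A minimal phase series: 2400 frames cycling uniformly through [0, 360)
uniform_phase <- function(n = 2400, fr = 80, freq = 2.5) {
  t <- (seq_len(n) - 1) / fr
  (360 * freq * t) %% 360
}

test_that("rate_by_phase normalizes spike counts by bin occupancy", {
  fr <- 80
  ph <- uniform_phase()
  ft <- (seq_along(ph) - 1) / fr
  # spikes only in frames with phase in [0, 15): all mass in bin 1
  frames <- which(ph < 15)
  tun <- rate_by_phase(ft[frames] + 0.001, ph, ft, fr)
  expect_equal(which(tun$rate > 0), 1L)
  # doubling occupancy of a bin at fixed count halves its rate
  ph2 <- c(ph, rep(7, 100))            # extra occupancy in bin 1
  ft2 <- (seq_along(ph2) - 1) / fr
  tun1 <- rate_by_phase(ft[frames[1:20]] + 0.001, ph, ft, fr)
  tun2 <- rate_by_phase(ft2[frames[1:20]] + 0.001, ph2, ft2, fr)
  expect_equal(tun2$rate[1] / tun1$rate[1],
               tun1$occupancy[1] / tun2$occupancy[1])
  # homogeneous spikes: counts proportional to occupancy, chi-square sane
  set.seed(41)
  spk <- sort(runif(3000, 0, max(ft)))
  tun3 <- rate_by_phase(spk, ph, ft, fr)
  expected <- tun3$occupancy * sum(tun3$counts) / sum(tun3$occupancy)
  x2 <- sum((tun3$counts - expected)^2 / expected)
  expect_lt(x2, qchisq(0.999, 23))
  expect_error(rate_by_phase(spk, rep(NA_real_, length(ph)), ft, fr),
               "defined phase")
})

test_that("mean vector: flat 0, point mass ~1, von Mises matches Bessel ratio", {
  tun <- rate_by_phase(numeric(), uniform_phase(),
                       (0:2399) / 80, 80)
  tun$rate <- rep(4, 24)
  expect_equal(mean_vector(tun)$length, 0, tolerance = 1e-12)
  tun$rate <- c(9, rep(0, 23))
  mv <- mean_vector(tun)
  expect_equal(mv$length, 1, tolerance = 1e-12)
  expect_equal(mv$angle, 7.5)
  # von Mises kappa = 1 profile evaluated at bin centers
  tun$rate <- exp(cos((tun$bin_centers - 90) * pi / 180)) / besselI(1, 0)
  mv <- mean_vector(tun)
  expect_equal(mv$length, besselI(1, 1) / besselI(1, 0), tolerance = 0.01)
  expect_equal(mv$angle, 90, tolerance = 0.5)
})

test_that("mean vector is rotation-equivariant", {
  ph <- uniform_phase()
  ft <- (seq_along(ph) - 1) / 80
  set.seed(42)
  # inhomogeneous spikes concentrated near 120 degrees
  frames <- which(abs(((ph - 120 + 180) %% 360) - 180) < 60)
  spk <- sort(ft[sample(frames, 800, replace = TRUE)] + runif(800) / 80)
  mv1 <- mean_vector(rate_by_phase(spk, ph, ft, 80))
  delta <- 75
  mv2 <- mean_vector(rate_by_phase(spk, (ph + delta) %% 360, ft, 80))
  expect_equal(mv2$length, mv1$length, tolerance = 0.02)
  expect_lt(abs(((mv2$angle - mv1$angle - delta + 180) %% 360) - 180), 8)
})

test_that("under uniform occupancy the binned resultant matches the per-spike resultant", {
  # golden-angle phase sequence: equidistributed, so occupancy is flat
  # within and across bins (the 2.5 Hz/80 fps grid has only 32 phase
  # values, which would alias the bin centers)
  ph <- (seq_len(4800) * 360 * (sqrt(5) - 1) / 2) %% 360
  ft <- (seq_along(ph) - 1) / 80
  set.seed(43)
  frames <- sample(seq_along(ph), 2000, replace = TRUE,
                   prob = exp(1.2 * cos((ph - 200) * pi / 180)))
  spk <- sort(ft[frames] + runif(2000) / 80)
  binned <- mean_vector(rate_by_phase(spk, ph, ft, 80))
  direct <- circ_resultant(ph[frames])
  expect_equal(binned$length, direct$length, tolerance = 0.01)
  expect_lt(abs(((binned$angle - direct$angle + 180) %% 360) - 180), 2)
})

test_that("jitter test flags phase-locked units and passes zero-spike inputs", {
  ds <- default_session()
  sp <- generate_phase_locked_spikes(
    ds$track, ds$st,
    spike_gen_params(base_rate = 12, phase_kappa = 2, coupled_limb = "LR",
                     seed = 44))
  expect_gt(sum(ds$st$strides$limb == "LR"), 200)
  set.seed(44)
  jt <- jitter_test(sp, ds$st$phase[, "LR"], ds$st$frame_times, 80)
  expect_true(jt$significant)
  expect_equal(jt$jitter_p, 0)
  jt0 <- jitter_test(numeric(), ds$st$phase[, "LR"], ds$st$frame_times, 80)
  expect_false(jt0$significant)
  expect_equal(jt0$n_spikes_used, 0)
})

test_that("recovered vector length grows monotonically with kappa", {
  ds <- default_session()
  lens <- vapply(c(0, 0.5, 1, 2), function(k) {
    sp <- generate_phase_locked_spikes(
      ds$track, ds$st,
      spike_gen_params(base_rate = 15, phase_kappa = k, coupled_limb = "LR",
                       seed = 50 + round(10 * k)))
    mean_vector(rate_by_phase(sp, ds$st$phase[, "LR"], ds$st$frame_times,
                              80))$length
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("outlier exclusion removes units above 0.9 everywhere", {
  tun <- data.frame(
    unit_id = rep(c("a", "b", "c"), each = 4),
    limb = rep(gait_limbs(), 3),
    vector_length = c(0.95, 0.2, 0.1, 0.3,   # a: outlier on one limb
                      rep(0.89, 4),          # b: boundary, retained
                      rep(0.5, 4)),
    significant = TRUE)
  ex <- exclude_outliers(tun)
  expect_equal(ex$excluded, "a")
  expect_setequal(unique(ex$kept$unit_id), c("b", "c"))
  empty <- exclude_outliers(tun[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_length(empty$excluded, 0)
})

test_that("limb-coupling classes follow the diagonal geometry", {
  mk <- function(sig) data.frame(limb = gait_limbs(),
                                 vector_length = c(0.4, 0.3, 0.2, 0.1),
                                 significant = gait_limbs() %in% sig)
  expect_equal(limb_coupling_profile(mk("LR"))$class, "single")
  expect_equal(limb_coupling_profile(mk(c("LR", "RF")))$class,
               "pair-diagonal")
  expect_equal(limb_coupling_profile(mk(c("LF", "RR")))$class,
               "pair-diagonal")
  expect_equal(limb_coupling_profile(mk(c("LR", "LF")))$class, "pair-other")
  expect_equal(limb_coupling_profile(mk(character()))$class, "none")
  expect_equal(limb_coupling_profile(mk(c("LR", "LF", "RF")))$class, "3+")
  expect_equal(limb_coupling_profile(mk("LR"))$ranked_limbs[1], "LF")
})
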