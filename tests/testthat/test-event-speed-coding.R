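# Bouts far from session edges so every event has full windows
event_bouts <- function(starts, stops = starts + 3) {
  data.frame(start = starts, stop = stops, peak_speed = 80,
             truncated = FALSE)
}

test_that("start/stop test: flat rate is not significant", {
  bouts <- event_bouts(seq(20, 260, by = 40))
  spk <- regular_spikes(10, 0, 300)
  res <- start_stop_test(spk, bouts, "start", session_end = 300)
  expect_gt(res$p_value, 0.5)
  expect_false(res$significant)
  expect_equal(res$baseline_rate, res$event_rate, tolerance = 0.05)
})

test_that("start/stop test separates start-only and stop-only units", {
  ds <- default_session()
  mb <- detect_motion_bouts(ds$speed, 80)
  sp <- generate_phase_locked_spikes(
    ds$track, NULL,
    spike_gen_params(base_rate = 10, phase_kappa = 0, coupled_limb = NA,
                     start_transient_amp = 3, seed = 60))
  start <- start_stop_test(sp, mb, "start")
  expect_true(start$significant)
  expect_gt(start$event_rate, start$baseline_rate)

  # stop-only modulation, constructed: burst after each bout stop
  base <- regular_spikes(8, 0, 300)
  burst <- unlist(lapply(mb$stop, function(t0) seq(t0, t0 + 0.4, by = 0.01)))
  spk <- sort(c(base, burst))
  res_stop <- start_stop_test(spk, mb, "stop", session_end = 300)
  res_start <- start_stop_test(spk, mb, "start", session_end = 300)
  expect_true(res_stop$significant)
  expect_false(res_start$significant)
})

test_that("fewer than two usable events is flagged undefined", {
  bouts <- event_bouts(2)   # baseline window would start before 0
  res <- start_stop_test(regular_spikes(5, 0, 100), bouts, "start",
                         session_end = 100)
  expect_equal(res$n_events, 0)
  expect_true(is.na(res$p_value))
  expect_false(res$significant)
})

test_that("modulation index follows the normalized-peak formula", {
  bouts <- event_bouts(c(50, 150, 250))
  # flat 50 Hz everywhere: normalized peak 1, index 0
  flat <- regular_spikes(50, 0, 300)
  expect_equal(modulation_index(flat, bouts, "start", session_end = 300),
               0, tolerance = 1e-9)
  # 3x elevation inside the event window: normalized peak 3, index 2
  spk3 <- sort(c(flat, unlist(lapply(bouts$start, function(t0)
    c(regular_spikes(100, t0 - 0.5, t0 + 0.5))))))
  expect_equal(modulation_index(spk3, bouts, "start", session_end = 300),
               2, tolerance = 1e-9)
  # suppression to 0.5: two events with interleaved half-rate patterns so
  # the event-aligned average is 25 Hz in every 20 ms bin
  b2 <- event_bouts(c(50, 150))
  edges <- seq(-0.5, 0.48, by = 0.02)
  spk_sup <- sort(c(
    regular_spikes(50, 0, 49.5), regular_spikes(50, 50.5, 149.5),
    regular_spikes(50, 150.5, 300),
    50 + edges[seq(1, 50, by = 2)] + 0.01,
    150 + edges[seq(2, 50, by = 2)] + 0.01))
  expect_equal(modulation_index(spk_sup, b2, "start", session_end = 300),
               0.5, tolerance = 1e-9)
})

test_that("modulation index is invariant to uniform rate rescaling", {
  bouts <- event_bouts(c(60, 160, 260))
  mk <- function(base) {
    sort(c(regular_spikes(base, 0, 300),
           unlist(lapply(bouts$start, function(t0)
             regular_spikes(2 * base, t0 - 0.5, t0 + 0.5)))))
  }
  m1 <- modulation_index(mk(50), bouts, "start", session_end = 300)
  m2 <- modulation_index(mk(150), bouts, "start", session_end = 300)
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_equal(m1, 2, tolerance = 1e-9)
})

test_that("zero baseline rate leaves the modulation index undefined", {
  bouts <- event_bouts(100)
  spk <- seq(99.6, 100.4, by = 0.05)   # spikes only in the event window
  expect_true(is.na(modulation_index(spk, bouts, "start",
                                     session_end = 200)))
})

test_that("speed coding: exact linear tuning scores 1, mirrored the same", {
  fr <- 80
  # piecewise-constant speed blocks at bin centers; deterministic spikes
  # with rate a + b * speed give exactly linear bin rates
  centers <- c(5, 15, 25, 35, 45, 55)
  speed <- rep(centers, each = 10 * fr)
  ft <- (seq_along(speed) - 1) / fr
  rate_up <- 1 + 0.1 * centers
  spk_up <- sort(unlist(lapply(seq_along(centers), function(k)
    regular_spikes(rate_up[k], (k - 1) * 10, k * 10))))
  set.seed(61)
  up <- speed_coding(spk_up, speed, ft, fr)
  expect_equal(up$score, 1, tolerance = 1e-9)
  expect_true(up$significant)
  # decreasing unit scores identically (absolute correlation)
  rate_dn <- rev(rate_up)
  spk_dn <- sort(unlist(lapply(seq_along(centers), function(k)
    regular_spikes(rate_dn[k], (k - 1) * 10, k * 10))))
  set.seed(61)
  dn <- speed_coding(spk_dn, speed, ft, fr)
  expect_equal(dn$score, up$score, tolerance = 1e-9)
  # fewer than 3 occupied bins: undefined
  few <- speed_coding(spk_up, rep(5, length(speed)), ft, fr)
  expect_true(is.na(few$score))
  expect_false(few$significant)
})

test_that("speed-independent unit is usually not speed coding", {
  ds <- default_session()
  sp <- generate_phase_locked_spikes(
    ds$track, NULL,
    spike_gen_params(base_rate = 9, phase_kappa = 0, coupled_limb = NA,
                     seed = 62))
  set.seed(62)
  sc <- speed_coding(sp, ds$speed, ds$sm$frame_times, 80)
  expect_false(sc$significant)
  expect_gte(sc$n_bins, 5)
})

test_that("coding-category counts are mutually consistent", {
  set.seed(63)
  units <- data.frame(phase_coding = runif(120) < 0.45,
                      speed_coding = runif(120) < 0.8,
                      startstop_coding = runif(120) < 0.7)
  v <- coding_venn(units)
  expect_equal(sum(unlist(v$combinations)), v$n)
  combos <- v$combinations
  expect_equal(combos$PSE, v$all_three)
  expect_equal(combos[["P--"]] + combos$`PS-` + combos$`P-E` + combos$PSE,
               v$phase)
  expect_equal(combos[["-S-"]] + combos$`PS-` + combos$`-SE` + combos$PSE,
               v$speed)
})

test_that("session-wide rate is measured up to the first laser pulse", {
  u <- generate_tagged_unit(tag_gen_params(seed = 64, evoked_prob = 1),
                            spike_gen_params(base_rate = 6, seed = 64),
                            session_duration = 100)
  r <- session_firing_rate(u)
  expect_equal(r, sum(u$times < 110) / 110, tolerance = 1e-12)
  expect_equal(r, 6, tolerance = 1.5)
})
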