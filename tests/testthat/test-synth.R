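test_that("an effectively absorbing state yields an all-Wake hypnogram", {
  cfg <- sim_config(seed = 1, duration_s = 3600,
                    state_dwell_means = c(Wake = 1e9, NREM = 120, REM = 60))
  hyp <- simulate_hypnogram(cfg)
  expect_true(all(hyp$state == "Wake"))
  expect_equal(nrow(hyp), 720)
})

test_that("long-run NREM occupancy matches the renewal-theory proportion", {
  # strict cycle => equal visit rates => occupancy = dwell / sum(dwell)
  frac <- vapply(1:50, function(i) {
    cfg <- sim_config(seed = 1000 + i, duration_s = 3600,
                      state_dwell_means = c(Wake = 60, NREM = 120, REM = 30),
                      next_state_probs = cycle_probs())
    hyp <- simulate_hypnogram(cfg, init_state = "stationary")
    mean(hyp$state == "NREM")
  }, numeric(1))
  expect_lt(abs(mean(frac) - 120 / 210) / (120 / 210), 0.05)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, duration_s = 600)
  h1 <- simulate_hypnogram(cfg)
  h2 <- simulate_hypnogram(cfg)
  expect_identical(h1, h2)
  s1 <- simulate_eeg_emg(h1, cfg)
  s2 <- simulate_eeg_emg(h1, cfg)
  expect_identical(s1, s2)
  laser <- laser_trains(c(50, 140))
  expect_identical(simulate_spikes(h1, laser, cfg),
                   simulate_spikes(h1, laser, cfg))
  expect_identical(
    as.data.frame(simulate_updown_responses(cfg)),
    as.data.frame(simulate_updown_responses(cfg))
  )
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed = 1, state_dwell_means = c(Wake = -1, NREM = 120, REM = 60)),
               "positive")
  bad <- default_next_state_probs()
  bad["Wake", "NREM"] <- 0.5 # row no longer sums to 1
  expect_error(sim_config(seed = 1, next_state_probs = bad), "row-stochastic")
  expect_error(sim_config(seed = 1, eeg_fs = 1500.3), "integer number of samples")
  expect_error(sim_config(seed = 1, laser_effect = c("NREM-Wake" = 0.2)),
               "NREM->Wake")
  expect_error(sim_config(seed = 1,
                          unit_state_rates = list(u = c(Wake = -2, NREM = 1, REM = 1))),
               "rates")
})

test_that("expected_occupancy is a probability vector consistent with dwell means", {
  cfg <- sim_config(seed = 1, state_dwell_means = c(Wake = 60, NREM = 120, REM = 30),
                    next_state_probs = cycle_probs())
  occ <- expected_occupancy(cfg)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  # grid rounding perturbs the continuous-time ratio only slightly
  expect_equal(unname(occ["NREM"]), 120 / 210, tolerance = 0.02)
})

test_that("NREM epochs carry their power in the delta band", {
  cfg <- sim_config(seed = 5, duration_s = 50,
                    state_band_powers = list(
                      Wake = c(1, 1, 2),
                      NREM = c(delta = 10, theta = 0, broadband = 0.1),
                      REM = c(0.5, 8, 0.5)
                    ))
  hyp <- hypnogram(rep("NREM", 10), epoch_s = 5)
  sig <- simulate_eeg_emg(hyp, cfg)
  # independent periodogram oracle on one epoch
  for (e in c(1, 5)) {
    seg <- sig$eeg[((e - 1) * 7500 + 1):(e * 7500)]
    sp <- stats::spec.pgram(stats::ts(seg, frequency = 1500), plot = FALSE,
                            taper = 0, detrend = FALSE)
    in_delta <- sum(sp$spec[sp$freq <= 4]) / sum(sp$spec)
    expect_gte(in_delta, 0.8)
  }
})

test_that("EMG RMS scales with the configured state levels", {
  cfg <- sim_config(seed = 6, duration_s = 100,
                    emg_levels = c(Wake = 1, NREM = 0.1, REM = 0.1))
  hyp <- hypnogram(rep(c("Wake", "NREM"), each = 10), epoch_s = 5)
  sig <- simulate_eeg_emg(hyp, cfg)
  rms <- function(x) sqrt(mean(x^2))
  n <- 7500
  r_wake <- mean(vapply(1:10, function(e) {
    rms(sig$emg[((e - 1) * n + 1):(e * n)])
  }, numeric(1)))
  r_nrem <- mean(vapply(11:20, function(e) {
    rms(sig$emg[((e - 1) * n + 1):(e * n)])
  }, numeric(1)))
  expect_equal(r_wake / r_nrem, 10, tolerance = 0.15)
})

test_that("zero band powers and zero EMG level give all-zero signals", {
  cfg <- sim_config(seed = 7, duration_s = 20,
                    state_band_powers = list(Wake = c(0, 0, 0),
                                             NREM = c(0, 0, 0),
                                             REM = c(0, 0, 0)),
                    emg_levels = c(Wake = 0, NREM = 0, REM = 0))
  hyp <- hypnogram(rep("Wake", 4), epoch_s = 5)
  sig <- simulate_eeg_emg(hyp, cfg)
  expect_true(all(sig$eeg == 0))
  expect_true(all(sig$emg == 0))
  expect_length(sig$eeg, 4 * 5 * 1500)
})

test_that("an evoked-only unit spikes exactly once per pulse at the set latency", {
  cfg <- sim_config(
    seed = 8, duration_s = 200,
    unit_state_rates = list(u1 = c(Wake = 0, NREM = 0, REM = 0)),
    evoked_params = list(u1 = list(reliability = 1, latency_ms = 2,
                                   jitter_ms = 0))
  )
  hyp <- hypnogram(rep("Wake", 40), epoch_s = 5)
  laser <- laser_trains(100, n_pulses = 10, freq_hz = 10)
  spk <- simulate_spikes(hyp, laser, cfg)
  expect_equal(nrow(spk), 10)
  expect_equal(spk$t_s, laser$pulse_t_s + 0.002, tolerance = 1e-12)
})

test_that("background spike counts are Poisson at the state rate", {
  cfg <- sim_config(
    seed = 9, duration_s = 1000,
    state_dwell_means = c(Wake = 1e9, NREM = 120, REM = 60),
    unit_state_rates = list(u1 = c(Wake = 8, NREM = 1, REM = 1)),
    evoked_params = list()
  )
  hyp <- simulate_hypnogram(cfg) # all Wake (absorbing)
  spk <- simulate_spikes(hyp, laser = NULL, cfg = cfg)
  expect_lt(abs(nrow(spk) - 8000), 3 * sqrt(8000))
})

test_that("zero evoked reliability leaves post-pulse windows at chance level", {
  cfg <- sim_config(
    seed = 10, duration_s = 2000,
    state_dwell_means = c(Wake = 1e9, NREM = 120, REM = 60),
    unit_state_rates = list(u1 = c(Wake = 5, NREM = 5, REM = 5)),
    evoked_params = list(u1 = list(reliability = 0, latency_ms = 2,
                                   jitter_ms = 0.5))
  )
  hyp <- simulate_hypnogram(cfg)
  laser <- laser_trains(seq(10, 1900, by = 90), n_pulses = 10, freq_hz = 10)
  spk <- simulate_spikes(hyp, laser, cfg)
  n_in_window <- sum(vapply(laser$pulse_t_s, function(p) {
    sum(spk$t_s > p & spk$t_s <= p + 0.010)
  }, numeric(1)))
  expected <- length(laser$pulse_t_s) * 5 * 0.010 # background rate x window
  expect_lt(n_in_window, expected + 4 * sqrt(expected))
})

test_that("a step psychometric makes up-down responses deterministic", {
  cfg <- sim_config(seed = 11,
                    psychometric = c(threshold_g = 0.4, slope = Inf))
  ses <- simulate_updown_responses(cfg)
  expect_identical(ses$withdrew, ses$filament_g >= 0.4)
  ses2 <- simulate_updown_responses(cfg)
  expect_identical(as.data.frame(ses), as.data.frame(ses2))
})

test_that("laser hazard deltas drive NREM-to-Wake jumps during trains", {
  cfg <- sim_config(seed = 12, duration_s = 4000,
                    state_dwell_means = c(Wake = 60, NREM = 300, REM = 60),
                    laser_effect = c("NREM->Wake" = 0.6))
  onsets <- seq(500, 3500, by = 500)
  laser <- laser_protocol(onsets, 120,
                          data.frame(start = onsets, end = onsets + 120))
  hyp_on <- simulate_hypnogram(cfg, laser = laser)
  hyp_off <- simulate_hypnogram(cfg, laser = NULL)
  in_train <- function(h) {
    sel <- rep(FALSE, nrow(h))
    for (o in onsets) sel <- sel | (h$t_start_s >= o & h$t_start_s < o + 120)
    mean(h$state[sel] == "Wake")
  }
  expect_gt(in_train(hyp_on), in_train(hyp_off) + 0.2)
})
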