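test_that("evoked statistics match a hand-counted construction", {
  laser <- laser_trains(seq(0, 810, by = 90), n_pulses = 1) # 10 pulses
  spikes <- sort(laser$pulse_t_s[1:9] + 0.002) # respond to 9 of 10
  s <- evoked_spike_stats(spikes, laser)
  expect_equal(s$reliability, 0.9)
  expect_equal(s$latency_ms, 2, tolerance = 1e-9)
  expect_equal(s$jitter_ms, 0, tolerance = 1e-9)
  expect_equal(s$n_responding, 9L)
})

test_that("a silent unit gives zero reliability and undefined latency", {
  laser <- laser_trains(seq(0, 810, by = 90), n_pulses = 1)
  s <- evoked_spike_stats(numeric(0), laser)
  expect_equal(s$reliability, 0)
  expect_true(is.na(s$latency_ms))
  expect_true(is.na(s$jitter_ms))
  expect_error(evoked_spike_stats(1:3, laser_protocol(numeric(0))), "no pulses")
})

test_that("jitter estimates the latency SD", {
  withr::with_seed(4, {
    pulses <- seq(1, 200, by = 1)
    lat <- stats::rnorm(200, 2e-3, 0.5e-3)
    laser <- laser_protocol(pulses, 0.001,
                            data.frame(start = pulses, end = pulses + 0.01))
    s <- evoked_spike_stats(sort(pulses + lat), laser)
    expect_equal(s$jitter_ms, 0.5, tolerance = 0.3)
    expect_equal(s$latency_ms, 2, tolerance = 0.2)
  })
})

test_that("latency and jitter ignore spikes outside the response windows", {
  laser <- laser_trains(seq(0, 90 * 19, by = 90), n_pulses = 1) # 20 pulses
  base <- sort(laser$pulse_t_s + 0.0015)
  s1 <- evoked_spike_stats(base, laser)
  with_extra <- sort(c(base, laser$pulse_t_s + 45)) # mid-interval spikes
  s2 <- evoked_spike_stats(with_extra, laser)
  expect_equal(s1$latency_ms, s2$latency_ms)
  expect_equal(s1$jitter_ms, s2$jitter_ms)
  expect_equal(s1$reliability, s2$reliability)
})

test_that("waveform similarity is exact for identical and inverted templates", {
  laser <- laser_trains(0, n_pulses = 10, freq_hz = 1) # pulses at 0..9 s
  evoked_t <- laser$pulse_t_s + 0.002
  spont_t <- seq(20, 29)
  t_all <- sort(c(evoked_t, spont_t))
  template <- sin(seq(0, 2 * pi, length.out = 32)) * exp(-seq(0, 3, length.out = 32))
  same <- matrix(rep(template, length(t_all)), nrow = length(t_all), byrow = TRUE)
  expect_equal(waveform_similarity(t_all, same, laser), 1)
  flipped <- same
  flipped[t_all %in% spont_t, ] <- -same[t_all %in% spont_t, ]
  expect_equal(waveform_similarity(t_all, flipped, laser), -1)
  expect_error(waveform_similarity(t_all, NULL, laser), "unavailable")
})

test_that("noisy templates at SNR 10 stay above the 0.95 correlation bar", {
  laser <- laser_trains(0, n_pulses = 20, freq_hz = 1)
  template <- sin(seq(0, 2 * pi, length.out = 32)) *
    exp(-seq(0, 3, length.out = 32))
  noise_sd <- stats::sd(template) / sqrt(10)
  withr::with_seed(5, {
    ok <- vapply(1:500, function(i) {
      evoked_t <- laser$pulse_t_s + 0.002
      spont_t <- seq(40, 69)
      t_all <- c(evoked_t, spont_t)
      snips <- matrix(rep(template, length(t_all)), nrow = length(t_all),
                      byrow = TRUE) +
        matrix(stats::rnorm(length(t_all) * 32, sd = noise_sd),
               nrow = length(t_all))
      waveform_similarity(t_all, snips, laser) > 0.95
    }, logical(1))
    expect_gte(mean(ok), 0.95)
  })
})

test_that("tagging thresholds are strict and flip exactly at the boundary", {
  eps <- 1e-6
  base <- tibble::tibble(reliability = 0.9, latency_ms = 2, jitter_ms = 0.4,
                         waveform_corr = 0.99)
  expect_true(classify_tagged(base)$tagged)
  expect_false(classify_tagged(dplyr::mutate(base, reliability = 0.69))$tagged)
  # at the threshold the strict inequality fails; an epsilon inside passes
  cases <- list(
    list(col = "reliability", at = 0.7, pass = 0.7 + eps, fail = 0.7 - eps),
    list(col = "latency_ms", at = 3, pass = 3 - eps, fail = 3 + eps),
    list(col = "jitter_ms", at = 3, pass = 3 - eps, fail = 3 + eps),
    list(col = "waveform_corr", at = 0.95, pass = 0.95 + eps, fail = 0.95 - eps)
  )
  for (cs in cases) {
    at <- base
    at[[cs$col]] <- cs$at
    expect_false(classify_tagged(at)$tagged)
    good <- base
    good[[cs$col]] <- cs$pass
    expect_true(classify_tagged(good)$tagged)
    bad <- base
    bad[[cs$col]] <- cs$fail
    expect_false(classify_tagged(bad)$tagged)
  }
})

test_that("classification is monotone in every metric", {
  withr::with_seed(6, {
    for (i in 1:200) {
      s <- tibble::tibble(
        reliability = runif(1), latency_ms = runif(1, 0, 6),
        jitter_ms = runif(1, 0, 6), waveform_corr = runif(1, -1, 1)
      )
      better <- dplyr::mutate(
        s,
        reliability = pmin(1, reliability + runif(1, 0, 0.3)),
        latency_ms = pmax(0, latency_ms - runif(1, 0, 2)),
        jitter_ms = pmax(0, jitter_ms - runif(1, 0, 2)),
        waveform_corr = pmin(1, waveform_corr + runif(1, 0, 0.5))
      )
      if (classify_tagged(s)$tagged) {
        expect_true(classify_tagged(better)$tagged)
      }
    }
  })
})

test_that("a missing waveform correlation degrades to the 3-criterion rule", {
  s <- tibble::tibble(reliability = 0.9, latency_ms = 2, jitter_ms = 0.4)
  expect_warning(rep <- classify_tagged(s), "waveform_corr")
  expect_true(rep$tagged)
})

test_that("refractory violations count intervals against all spikes", {
  expect_equal(refractory_violation_fraction(seq(0, 1, by = 0.01)), 0)
  t_s <- c(seq(0.1, 49.9, by = 0.1), 49.9005) # 1 violation among 500 spikes
  expect_equal(refractory_violation_fraction(t_s), 1 / 500)
  expect_warning(z <- refractory_violation_fraction(c(1)), "fewer than 2")
  expect_equal(z, 0)
})

test_that("isolation distance reproduces closed-form Mahalanobis geometry", {
  n <- 500
  withr::with_seed(7, {
    x <- as.numeric(scale(stats::rnorm(n))) # mean 0, sd exactly 1
    cl <- matrix(x, ncol = 1)
    other <- matrix(as.numeric(scale(stats::rnorm(n))) + 5, ncol = 1)
    expect_equal(isolation_distance(cl, other), 5, tolerance = 1e-9)
    expect_equal(isolation_distance(cl, cl), 0, tolerance = 1e-9)
    # with three clusters the nearest centroid governs the minimum
    far <- matrix(as.numeric(scale(stats::rnorm(n))) + 12, ncol = 1)
    d_all <- isolation_distance(cl, list(other, far))
    d_pairs <- c(isolation_distance(cl, other), isolation_distance(cl, far))
    expect_equal(d_all, min(d_pairs))
  })
})

test_that("singular covariance is ridge-regularized instead of failing", {
  cl <- matrix(rep(c(1, 2), each = 10), ncol = 2) # zero variance
  other <- matrix(rep(c(3, 5), each = 10), ncol = 2)
  expect_message(d <- isolation_distance(cl, other), "ridge")
  expect_true(is.finite(d) && d > 0)
})
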