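test_that("state rates split spikes by scored state exactly", {
  hyp <- hypnogram(rep(c("Wake", "NREM", "REM"), times = 20), epoch_s = 5)
  # regular 5-Hz train: every epoch holds exactly 25 spikes
  t_s <- regular_spikes(5, 300)
  r <- state_rates(t_s, hyp)
  expect_equal(r$rate_hz, rep(5, 3))
  expect_equal(r$seconds, rep(100, 3))
  # no spikes at all
  r0 <- state_rates(numeric(0), hyp)
  expect_equal(r0$rate_hz, rep(0, 3))
  # spikes only during Wake epochs
  wake_only <- unlist(lapply(which(hyp$state == "Wake") - 1L, function(e) {
    e * 5 + c(1, 2.5, 4)
  }))
  rw <- state_rates(sort(wake_only), hyp)
  expect_equal(rw$rate_hz[rw$state == "NREM"], 0)
  expect_equal(rw$rate_hz[rw$state == "REM"], 0)
  expect_gt(rw$rate_hz[rw$state == "Wake"], 0)
})

test_that("a state absent from the hypnogram yields an NA rate", {
  hyp <- hypnogram(rep(c("Wake", "NREM"), each = 10), epoch_s = 5)
  r <- state_rates(regular_spikes(2, 100), hyp)
  expect_true(is.na(r$rate_hz[r$state == "REM"]))
})

test_that("spikes outside the hypnogram span are ignored with a note", {
  hyp <- hypnogram(rep("Wake", 10), epoch_s = 5)
  expect_message(r <- state_rates(c(1, 2, 100), hyp), "outside")
  expect_equal(r$n_spikes[r$state == "Wake"], 2L)
})

test_that("laser-train epochs can be excluded from rate estimates", {
  hyp <- hypnogram(rep("Wake", 20), epoch_s = 5)
  laser <- laser_protocol(10, 20, data.frame(start = 10, end = 30))
  t_s <- sort(c(regular_spikes(1, 100), seq(10.53, 29.53, by = 0.1))) # burst in train
  r_ex <- state_rates(t_s, hyp, laser = laser)
  r_in <- state_rates(t_s, hyp, laser = laser, exclude_laser = FALSE)
  expect_equal(r_ex$rate_hz[1], 1, tolerance = 0.05)
  expect_gt(r_in$rate_hz[1], 2)
  expect_equal(r_ex$seconds[1], 80) # 4 epochs removed
})

test_that("modulation indices follow the printed contrast formula", {
  mk <- function(w, n, r) {
    tibble::tibble(state = c("Wake", "NREM", "REM"), rate_hz = c(w, n, r))
  }
  expect_equal(modulation_indices(mk(3, 3, 1))$wake_nrem_mod, 0)
  expect_equal(modulation_indices(mk(6, 2, 1))$wake_nrem_mod, 0.5)
  expect_equal(modulation_indices(mk(1, 4, 0))$rem_nrem_mod, -1)
  expect_warning(m <- modulation_indices(mk(0, 0, 1)), "undefined")
  expect_true(is.nan(m$wake_nrem_mod))
  # bounded in [-1, 1] for arbitrary non-negative rates
  withr::with_seed(8, {
    for (i in 1:100) {
      m <- modulation_indices(mk(runif(1, 0, 20), runif(1, 0, 20),
                                 runif(1, 0, 20)))
      expect_true(abs(m$wake_nrem_mod) <= 1 && abs(m$rem_nrem_mod) <= 1)
    }
  })
})

test_that("rates and indices are invariant to a common time shift", {
  cfg <- sim_config(seed = 30, duration_s = 600)
  hyp0 <- simulate_hypnogram(cfg)
  t_s <- regular_spikes(3, 600)
  shift <- 1234
  hyp1 <- hypnogram(as.character(hyp0$state), epoch_s = 5, t0_s = shift)
  r0 <- state_rates(t_s, hyp0)
  r1 <- state_rates(t_s + shift, hyp1)
  expect_equal(r0$rate_hz, r1$rate_hz)
  expect_equal(modulation_indices(r0), modulation_indices(r1))
})

test_that("peri-transition histograms resolve a rate step at the boundary", {
  # NREM bouts of 12 epochs alternating with Wake bouts of 12 epochs
  hyp <- hypnogram(rep(rep(c("NREM", "Wake"), each = 12), times = 10),
                   epoch_s = 5)
  r <- rle(as.character(hyp$state))
  starts <- (cumsum(r$lengths) - r$lengths) * 5
  wake_onsets <- starts[r$values == "Wake"]
  # deterministic step train: 1 Hz before, 10 Hz after each NREM->Wake onset
  t_s <- sort(unlist(lapply(wake_onsets, function(T) {
    c(regular_spikes(1, 60, T - 60), regular_spikes(10, 60, T))
  })))
  h <- peri_transition_rates(t_s, hyp, "NREM", "Wake", window_s = 60, bin_s = 5)
  expect_equal(unique(h$rate_hz[h$bin_hi_s <= 0]), 1)
  expect_equal(unique(h$rate_hz[h$bin_lo_s >= 0]), 10)
  expect_gt(attr(h, "n_events"), 3)
})

test_that("a homogeneous train gives a flat histogram and n = 1 marks SEM NA", {
  hyp <- hypnogram(rep(rep(c("NREM", "Wake"), each = 12), times = 4),
                   epoch_s = 5)
  t_s <- regular_spikes(4, 480)
  h <- peri_transition_rates(t_s, hyp, "NREM", "Wake")
  expect_true(all(abs(h$rate_hz - 4) <= 0.5))
  # single qualifying transition
  hyp1 <- hypnogram(rep(c("NREM", "Wake"), each = 20), epoch_s = 5)
  h1 <- peri_transition_rates(regular_spikes(4, 200), hyp1, "NREM", "Wake",
                              window_s = 30)
  expect_equal(attr(h1, "n_events"), 1L)
  expect_true(all(is.na(h1$sem)))
  expect_false(anyNA(h1$rate_hz))
})

test_that("no qualifying transition returns an empty flagged histogram", {
  hyp <- hypnogram(rep("Wake", 50), epoch_s = 5)
  expect_warning(
    h <- peri_transition_rates(regular_spikes(2, 250), hyp, "NREM", "Wake"),
    "no qualifying"
  )
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "n_events"), 0L)
})

test_that("peri-stimulus rates recover a rate doubling at each event", {
  events <- seq(100, 900, by = 100)
  t_s <- sort(unlist(lapply(events, function(T) {
    c(regular_spikes(2, 10, T - 10), regular_spikes(4, 10, T))
  })))
  out <- peri_stimulus_rates(t_s, events, pre_s = 10, post_s = 10,
                             span_s = c(0, 1000))
  expect_equal(out$paired$after_rate_hz / out$paired$before_rate_hz,
               rep(2, length(events)))
  expect_equal(attr(out$psth, "n_events"), length(events))
})

test_that("edge and overlapping events are dropped with notice", {
  t_s <- regular_spikes(2, 200)
  expect_message(
    out <- peri_stimulus_rates(t_s, c(3, 100), pre_s = 10, post_s = 10,
                               span_s = c(0, 200)),
    "edge"
  )
  expect_equal(nrow(out$paired), 1)
  expect_warning(
    out2 <- peri_stimulus_rates(t_s, c(100, 105), pre_s = 10, post_s = 10,
                                span_s = c(0, 200)),
    "overlap"
  )
  expect_equal(nrow(out2$paired), 1)
  expect_error(peri_stimulus_rates(t_s, numeric(0), 10, 10), "no events")
})

test_that("the paired signed-rank comparison behaves at its edge cases", {
  expect_warning(res <- compare_transition_rates(rep(2, 6), rep(2, 6)),
                 "zero")
  expect_equal(res$p_value, 1)
  pre <- seq(1, 20) / 7
  res2 <- compare_transition_rates(pre, pre + 1)
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$direction, "increase")
  expect_error(compare_transition_rates(1:3, 2:4), "at least 5")
  expect_error(compare_transition_rates(1:6, 1:5), "paired")
})

test_that("the signed-rank test holds its size under a null of no change", {
  withr::with_seed(9, {
    p <- vapply(1:1000, function(i) {
      pre <- stats::rnorm(10)
      post <- pre + stats::rnorm(10) # exchangeable differences
      compare_transition_rates(pre, post)$p_value
    }, numeric(1))
    expect_lte(mean(p < 0.05), 0.06)
  })
})
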