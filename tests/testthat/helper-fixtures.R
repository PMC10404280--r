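# Shared fixture builders; everything is generated in code at test time.

# Strict Wake -> NREM -> REM -> Wake cycle: equal embedded visit rates, so
# long-run occupancy equals dwell / sum(dwell).
cycle_probs <- function() {
  m <- matrix(0, 3, 3, dimnames = list(c("Wake", "NREM", "REM"),
                                       c("Wake", "NREM", "REM")))
  m["Wake", "NREM"] <- 1
  m["NREM", "REM"] <- 1
  m["REM", "Wake"] <- 1
  m
}

# A deterministic regular spike train at `rate_hz` covering [0, t_end_s).
regular_spikes <- function(rate_hz, t_end_s, t0_s = 0) {
  seq(t0_s + 1 / (2 * rate_hz), t0_s + t_end_s - 1e-9, by = 1 / rate_hz)
}

# Build a trial_set directly from a trials x bins label matrix (or a list of
# such matrices, one per mouse).
ts_from_matrix <- function(mats, bins, n_laser_bins = 1L, bin_s = 60) {
  if (is.matrix(mats)) mats <- list(m1 = mats)
  out <- purrr::imap_dfr(mats, function(M, mouse) {
    purrr::map_dfr(seq_len(nrow(M)), function(tr) {
      tibble::tibble(
        mouse = mouse, trial = tr, bin = bins, t_rel_s = bins * bin_s,
        state = factor(M[tr, ], levels = c("Wake", "NREM", "REM"))
      )
    })
  })
  attr(out, "bin_s") <- bin_s
  attr(out, "n_laser_bins") <- as.integer(n_laser_bins)
  attr(out, "bins") <- bins
  class(out) <- c("trial_set", class(out))
  out
}

# Independent brute-force transition counter (double loop over trials and
# bins), used as the oracle for transition_probabilities().
brute_force_transitions <- function(trials) {
  states <- c("Wake", "NREM", "REM")
  bins <- sort(unique(trials$bin))
  key <- paste(trials$mouse, trials$trial)
  labs <- lapply(split(seq_len(nrow(trials)), key), function(ix) {
    stats::setNames(as.character(trials$state[ix]),
                    as.character(trials$bin[ix]))
  })
  out <- NULL
  for (j in seq_along(bins)[-1]) {
    for (x in states) {
      for (y in states) {
        m <- 0L
        n <- 0L
        for (lab in labs) {
          prev <- lab[[as.character(bins[j - 1])]]
          cur <- lab[[as.character(bins[j])]]
          if (!is.na(prev) && prev == x) {
            n <- n + 1L
            if (!is.na(cur) && cur == y) m <- m + 1L
          }
        }
        out <- rbind(out, data.frame(
          from = x, to = y, bin = bins[j], m = m, n = n,
          p = if (n > 0) m / n else NA_real_
        ))
      }
    }
  }
  out
}

# Random label matrix for transition tests.
random_label_matrix <- function(n_trials, n_bins) {
  matrix(sample(c("Wake", "NREM", "REM"), n_trials * n_bins, replace = TRUE),
         nrow = n_trials)
}
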