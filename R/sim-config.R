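#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-recording generator: the epoch
#' grid, state-dependent EEG band powers and EMG amplitudes, semi-Markov
#' dwell-time means and embedded next-state probabilities, per-unit
#' state-dependent firing rates and laser-evoked spike parameters, per-epoch
#' transition-hazard deltas applied while a laser train is active, and the
#' psychometric function driving simulated von Frey responses.
#'
#' Defaults mirror a standard mouse polysomnography setup: signals digitized
#' at 1500 Hz, scored in 5-s epochs, NREM dominated by 0.1--4 Hz (delta)
#' power, REM by 5--10 Hz (theta) power with low EMG, wakefulness by
#' broadband EEG with high EMG. Optogenetic tagging trains default to
#' 10 Hz x 1 s with 1-ms pulses.
#'
#' @param seed Integer seed; every stochastic generator draws from a
#'   sub-stream derived from it, so a fixed config reproduces byte-identical
#'   output.
#' @param duration_s Recording length, seconds.
#' @param epoch_s Epoch length, seconds (default 5).
#' @param eeg_fs EEG/EMG sampling rate, Hz (default 1500). `eeg_fs * epoch_s`
#'   must be an integer.
#' @param state_dwell_means Named numeric (Wake/NREM/REM), mean bout
#'   durations in seconds.
#' @param dwell_law `"exponential"` (memoryless, default) or `"gamma"`.
#' @param dwell_shape Gamma shape when `dwell_law = "gamma"`.
#' @param next_state_probs 3x3 row-stochastic matrix (zero diagonal) of
#'   conditional next-state probabilities of the embedded jump chain, rows
#'   and columns in Wake/NREM/REM order.
#' @param state_band_powers Named list per state of `c(delta, theta,
#'   broadband)` EEG component variances (arbitrary units).
#' @param emg_levels Named numeric per state: EMG RMS amplitude.
#' @param unit_state_rates Named list, one element per unit, each a named
#'   numeric of Wake/NREM/REM firing rates in Hz.
#' @param evoked_params Named list, one element per unit:
#'   `list(reliability = p, latency_ms = l, jitter_ms = j)`. Units absent
#'   from the list are untagged (no evoked spikes).
#' @param laser_effect Named numeric of per-epoch transition-probability
#'   deltas applied while a train is active; names like `"NREM->Wake"`.
#' @param psychometric `c(threshold_g, slope)`: logistic probability of paw
#'   withdrawal as a function of `log10` filament force; `slope = Inf` gives
#'   a step function (withdraw iff force >= threshold).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, duration_s = 600)
#' cfg$state_dwell_means
#' @export
sim_config <- function(
    seed,
    duration_s = 3600,
    epoch_s = 5,
    eeg_fs = 1500,
    state_dwell_means = c(Wake = 120, NREM = 150, REM = 60),
    dwell_law = c("exponential", "gamma"),
    dwell_shape = 2,
    next_state_probs = default_next_state_probs(),
    state_band_powers = list(
      Wake = c(delta = 1,   theta = 1,   broadband = 2),
      NREM = c(delta = 10,  theta = 0.5, broadband = 0.5),
      REM  = c(delta = 0.5, theta = 8,   broadband = 0.5)
    ),
    emg_levels = c(Wake = 1, NREM = 0.12, REM = 0.08),
    unit_state_rates = list(
      u1 = c(Wake = 8, NREM = 3, REM = 2),
      u2 = c(Wake = 4, NREM = 4, REM = 4)
    ),
    evoked_params = list(
      u1 = list(reliability = 0.9, latency_ms = 2, jitter_ms = 0.4)
    ),
    laser_effect = numeric(),
    psychometric = c(threshold_g = 0.4, slope = 10)) {
  dwell_law <- match.arg(dwell_law)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("sim_config requires a single integer seed")
  }
  if (duration_s < epoch_s) stop("duration_s must cover at least one epoch")
  if (abs(eeg_fs * epoch_s - round(eeg_fs * epoch_s)) > 1e-9) {
    stop("eeg_fs * epoch_s must be an integer number of samples per epoch")
  }
  state_dwell_means <- state_dwell_means[BRAIN_STATES]
  if (anyNA(state_dwell_means) || any(state_dwell_means <= 0)) {
    stop("state_dwell_means must be positive for Wake, NREM and REM")
  }
  next_state_probs <- as.matrix(next_state_probs)
  dimnames(next_state_probs) <- list(BRAIN_STATES, BRAIN_STATES)
  if (any(next_state_probs < 0) || any(next_state_probs > 1) ||
      any(abs(rowSums(next_state_probs) - 1) > 1e-9) ||
      any(diag(next_state_probs) != 0)) {
    stop("next_state_probs must be row-stochastic with zero diagonal")
  }
  for (s in BRAIN_STATES) {
    bp <- state_band_powers[[s]]
    if (is.null(bp) || length(bp) != 3L || any(bp < 0)) {
      stop("state_band_powers must give (delta, theta, broadband) >= 0 for ", s)
    }
  }
  emg_levels <- emg_levels[BRAIN_STATES]
  if (anyNA(emg_levels) || any(emg_levels < 0)) {
    stop("emg_levels must be >= 0 for all states")
  }
  for (u in names(unit_state_rates)) {
    r <- unit_state_rates[[u]][BRAIN_STATES]
    if (anyNA(r) || any(r < 0)) {
      stop("unit_state_rates must give finite rates >= 0 Hz for all states (", u, ")")
    }
    unit_state_rates[[u]] <- r
  }
  for (u in names(evoked_params)) {
    ev <- evoked_params[[u]]
    if (ev$reliability < 0 || ev$reliability > 1) {
      stop("evoked reliability must lie in [0, 1] (", u, ")")
    }
    if (ev$jitter_ms < 0) stop("evoked jitter must be >= 0 (", u, ")")
  }
  if (length(laser_effect)) {
    if (any(laser_effect < -1 | laser_effect > 1)) {
      stop("laser_effect deltas must lie in [-1, 1]")
    }
    pairs <- strsplit(names(laser_effect), "->", fixed = TRUE)
    ok <- vapply(pairs, function(p) {
      length(p) == 2L && all(p %in% BRAIN_STATES) && p[1] != p[2]
    }, logical(1))
    if (!all(ok)) {
      stop("laser_effect names must look like 'NREM->Wake' with distinct states")
    }
  }
  structure(
    list(
      seed = as.integer(seed), duration_s = duration_s, epoch_s = epoch_s,
      eeg_fs = eeg_fs, state_dwell_means = state_dwell_means,
      dwell_law = dwell_law, dwell_shape = dwell_shape,
      next_state_probs = next_state_probs,
      state_band_powers = state_band_powers, emg_levels = emg_levels,
      unit_state_rates = unit_state_rates, evoked_params = evoked_params,
      laser_effect = laser_effect, psychometric = psychometric
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_next_state_probs <- function() {
  m <- matrix(0, 3, 3, dimnames = list(BRAIN_STATES, BRAIN_STATES))
  m["Wake", "NREM"] <- 1
  m["NREM", c("Wake", "REM")] <- c(0.6, 0.4)
  m["REM", c("Wake", "NREM")] <- c(0.9, 0.1)
  m
}

## Seed sub-streams: one seeded generator per simulation component so that
## toggling one component leaves the others' draws unchanged.
sim_substream <- function(cfg, k) {
  (cfg$seed %% 1000000L) * 1000L + k
}

#' Expected long-run state occupancy of the generator
#'
#' Closed-form occupancy of the semi-Markov hypnogram generator, including
#' the effect of rounding dwell times to the epoch grid: each state's weight
#' is its embedded-chain visit rate times the expected number of epochs per
#' bout after grid rounding.
#'
#' @param cfg A [sim_config()].
#' @return Named numeric of Wake/NREM/REM occupancy fractions (sums to 1).
#' @export
expected_occupancy <- function(cfg) {
  P <- cfg$next_state_probs
  ## stationary distribution of the embedded jump chain
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  nu <- Re(e$vectors[, i])
  nu <- nu / sum(nu)
  epochs <- vapply(BRAIN_STATES, function(s) {
    expected_bout_epochs(cfg, cfg$state_dwell_means[[s]])
  }, numeric(1))
  w <- nu * epochs
  stats::setNames(w / sum(w), BRAIN_STATES)
}

## E[max(1, round(X / epoch_s))] for the configured dwell law.
expected_bout_epochs <- function(cfg, mean_s) {
  eps <- cfg$epoch_s
  cdf <- if (cfg$dwell_law == "exponential") {
    function(x) stats::pexp(x, rate = 1 / mean_s)
  } else {
    function(x) stats::pgamma(x, shape = cfg$dwell_shape,
                              rate = cfg$dwell_shape / mean_s)
  }
  kmax <- ceiling(30 * mean_s / eps) + 2
  k <- seq_len(kmax)
  ## P(round(X/eps) = k) = F((k+.5)eps) - F((k-.5)eps); k = 0 mapped to 1
  pk <- cdf((k + 0.5) * eps) - cdf((k - 0.5) * eps)
  p1extra <- cdf(0.5 * eps) # rounded to zero epochs -> floored at one
  sum(k * pk) + 1 * p1extra + kmax * (1 - cdf((kmax + 0.5) * eps))
}
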