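#' Simulate EEG and EMG signals for a hypnogram
#'
#' Per epoch, the EEG is a sum of three independent band-limited Gaussian
#' noise components whose variances are the state's configured `(delta,
#' theta, broadband)` powers: delta noise confined to 0.1--4 Hz, theta noise
#' to 5--10 Hz, and a broadband component spanning the full bandwidth. The
#' EMG is white Gaussian noise whose RMS amplitude is the state's configured
#' level. Band-limited components are synthesized by zeroing out-of-band
#' Fourier coefficients of white noise and rescaling to the target variance.
#'
#' @param hyp A [hypnogram()].
#' @param cfg A [sim_config()] whose `epoch_s` matches the hypnogram grid.
#' @return A list with elements `eeg`, `emg` (numeric vectors of exactly
#'   `nrow(hyp) * epoch_s * eeg_fs` samples) and `fs`.
#' @examples
#' cfg <- sim_config(seed = 1, duration_s = 60)
#' sig <- simulate_eeg_emg(simulate_hypnogram(cfg), cfg)
#' length(sig$eeg) / sig$fs
#' @export
simulate_eeg_emg <- function(hyp, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  eps <- hyp_epoch_s(hyp)
  if (abs(eps - cfg$epoch_s) > 1e-9) {
    stop("hypnogram epoch grid does not match cfg$epoch_s")
  }
  n_per <- cfg$eeg_fs * eps
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("eeg_fs * epoch_s must be an integer number of samples per epoch")
  }
  n_per <- as.integer(round(n_per))
  states <- as.character(hyp$state)
  withr::with_seed(sim_substream(cfg, 2L), {
    eeg <- numeric(nrow(hyp) * n_per)
    emg <- numeric(nrow(hyp) * n_per)
    for (e in seq_len(nrow(hyp))) {
      bp <- cfg$state_band_powers[[states[e]]]
      seg <- band_noise(n_per, cfg$eeg_fs, 0.1, 4, bp[[1]]) +
        band_noise(n_per, cfg$eeg_fs, 5, 10, bp[[2]]) +
        band_noise(n_per, cfg$eeg_fs, 0.1, cfg$eeg_fs / 2, bp[[3]])
      idx <- ((e - 1L) * n_per + 1L):(e * n_per)
      eeg[idx] <- seg
      lvl <- cfg$emg_levels[[states[e]]]
      emg[idx] <- if (lvl > 0) stats::rnorm(n_per, sd = lvl) else numeric(n_per)
    }
    list(eeg = eeg, emg = emg, fs = cfg$eeg_fs)
  })
}

## Gaussian noise with all spectral power inside [f_lo, f_hi], variance =
## `power`. Zero power short-circuits to an all-zero segment.
band_noise <- function(n, fs, f_lo, f_hi, power) {
  if (power <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f, fs - f) # two-sided spectrum folded to [0, fs/2]
  keep <- f_fold >= f_lo & f_fold <= f_hi
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * sqrt(power) / s
}
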