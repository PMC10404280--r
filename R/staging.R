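#' Per-epoch spectral and EMG features
#'
#' Cuts EEG and EMG into consecutive epochs (trailing partial epoch
#' discarded) and computes, per epoch, FFT periodogram band powers in the
#' staging bands — delta 0.1--4 Hz, theta 5--10 Hz, total 0.1--30 Hz — and
#' the EMG root-mean-square amplitude.
#'
#' @param eeg,emg Numeric signal vectors sampled at `fs`.
#' @param fs Sampling rate, Hz (> 20 Hz so the 10-Hz theta edge resolves).
#' @param epoch_s Epoch length, seconds (default 5); `fs * epoch_s` must be
#'   an integer.
#' @return A tibble of class `epoch_features` with columns `epoch`,
#'   `t_start_s`, `delta_power`, `theta_power`, `total_power`, `emg_rms`.
#' @examples
#' t <- seq(0, 10 - 1 / 100, by = 1 / 100)
#' f <- compute_epoch_features(sin(2 * pi * 2 * t), rep(0.1, length(t)), 100)
#' f$delta_power / f$total_power
#' @export
compute_epoch_features <- function(eeg, emg, fs, epoch_s = 5) {
  if (fs <= 20) stop("fs must exceed 20 Hz (2 x the 10-Hz theta edge)")
  if (length(eeg) != length(emg)) {
    stop("eeg and emg must have equal length (same stream duration)")
  }
  bad <- which(!is.finite(eeg) | !is.finite(emg))
  if (length(bad)) {
    stop("non-finite sample(s) in input; first offending index: ", bad[1])
  }
  n_per <- fs * epoch_s
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("fs * epoch_s must be an integer number of samples per epoch")
  }
  n_per <- as.integer(round(n_per))
  n_ep <- length(eeg) %/% n_per
  if (n_ep < 1L) stop("signal shorter than one epoch")

  eeg_m <- matrix(eeg[seq_len(n_ep * n_per)], nrow = n_per)
  emg_m <- matrix(emg[seq_len(n_ep * n_per)], nrow = n_per)
  f <- (seq_len(n_per) - 1L) * fs / n_per
  f_fold <- pmin(f, fs - f)
  pgram <- abs(stats::mvfft(eeg_m))^2 / n_per # per-epoch periodogram columns
  band_power <- function(lo, hi) {
    sel <- f_fold >= lo & f_fold <= hi
    colSums(pgram[sel, , drop = FALSE]) / n_per
  }
  out <- tibble(
    epoch = seq_len(n_ep) - 1L,
    t_start_s = (seq_len(n_ep) - 1L) * epoch_s,
    delta_power = band_power(0.1, 4),
    theta_power = band_power(5, 10),
    total_power = band_power(0.1, 30),
    emg_rms = sqrt(colMeans(emg_m^2))
  )
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("epoch_features", class(out))
  out
}

#' Staging thresholds
#'
#' @param emg_thresh EMG RMS above which an epoch is scored Wake.
#' @param theta_ratio_thresh theta/delta power ratio at or above which a
#'   low-EMG epoch is scored REM.
#' @param min_bout_epochs Minimum bout length (epochs) used by the optional
#'   smoothing pass (default 2, i.e. 10 s at 5-s epochs).
#' @return A list of class `staging_params`.
#' @export
staging_params <- function(emg_thresh, theta_ratio_thresh,
                           min_bout_epochs = 2L) {
  stopifnot(is.numeric(emg_thresh), is.numeric(theta_ratio_thresh))
  structure(
    list(
      emg_thresh = emg_thresh, theta_ratio_thresh = theta_ratio_thresh,
      min_bout_epochs = as.integer(min_bout_epochs)
    ),
    class = "staging_params"
  )
}

#' Calibrate staging thresholds from a recording
#'
#' Data-driven thresholds for [stage_epochs()]: the EMG threshold is placed
#' at the geometric midpoint between the two modes of the (log) EMG-RMS
#' distribution, found by a deterministic 2-means split; the theta/delta
#' ratio threshold is the analogous midpoint among low-EMG (sleep) epochs.
#' If a distribution fails the bimodality check (modes closer than a factor
#' `min_mode_ratio`), a quantile fallback is used and a warning emitted.
#'
#' @param features An [compute_epoch_features()] result with >= 100 epochs.
#' @param min_mode_ratio Required ratio of upper/lower mode (default 2).
#' @param emg_fallback_q,ratio_fallback_q Fallback quantiles for unimodal
#'   EMG (0.75) and theta-ratio (0.85) distributions.
#' @param min_bout_epochs Passed through to [staging_params()].
#' @return A [staging_params()] object.
#' @export
calibrate_thresholds <- function(features, min_mode_ratio = 2,
                                 emg_fallback_q = 0.75,
                                 ratio_fallback_q = 0.85,
                                 min_bout_epochs = 2L) {
  if (nrow(features) < 100L) {
    stop("threshold calibration needs at least 100 epochs")
  }
  emg_thresh <- bimodal_split(
    features$emg_rms, min_mode_ratio, emg_fallback_q, "EMG RMS"
  )
  low_emg <- features$emg_rms < emg_thresh
  ratio <- features$theta_power / pmax(features$delta_power, 1e-12)
  ratio_thresh <- bimodal_split(
    ratio[low_emg], min_mode_ratio, ratio_fallback_q, "theta/delta ratio"
  )
  staging_params(emg_thresh, ratio_thresh, min_bout_epochs)
}

## Deterministic 2-means on the log scale; midpoint of the two centers, or
## a quantile fallback (with warning) when the modes are not separated.
bimodal_split <- function(x, min_mode_ratio, fallback_q, what) {
  x <- x[is.finite(x) & x > 0]
  fallback <- function() {
    warning(what, " distribution looks unimodal; falling back to the ",
            fallback_q, " quantile")
    as.numeric(stats::quantile(x, fallback_q, names = FALSE))
  }
  if (length(x) < 10L || diff(range(x)) < 1e-12) return(fallback())
  lx <- log(x)
  init <- stats::quantile(lx, c(0.1, 0.9), names = FALSE)
  if (diff(init) < 1e-9) return(fallback())
  km <- stats::kmeans(lx, centers = matrix(init, ncol = 1))
  ctr <- sort(km$centers[, 1])
  if (exp(ctr[2] - ctr[1]) < min_mode_ratio) return(fallback())
  exp(mean(ctr))
}

#' Stage epochs into Wake/NREM/REM
#'
#' Decision rule per epoch, mirroring standard rodent criteria: high EMG
#' activity scores Wake regardless of the spectrum; among low-EMG epochs, a
#' dominant theta/delta power ratio (regular 5--10 Hz rhythm) scores REM,
#' and the remainder — high-amplitude low-frequency EEG with low EMG —
#' scores NREM. An optional smoothing pass merges bouts shorter than
#' `min_bout_epochs` into the preceding bout.
#'
#' @param features An [compute_epoch_features()] result.
#' @param params A [staging_params()] (or from [calibrate_thresholds()]).
#' @param smooth Apply the minimum-bout smoothing pass (default TRUE).
#' @return A [hypnogram()] with one label per feature row.
#' @export
stage_epochs <- function(features, params, smooth = TRUE) {
  if (missing(params) || !inherits(params, "staging_params")) {
    stop("staging thresholds missing; supply staging_params() or run ",
         "calibrate_thresholds() on this recording first")
  }
  ratio <- features$theta_power / pmax(features$delta_power, 1e-12)
  labels <- ifelse(
    features$emg_rms >= params$emg_thresh, "Wake",
    ifelse(ratio >= params$theta_ratio_thresh, "REM", "NREM")
  )
  if (smooth && params$min_bout_epochs > 1L) {
    labels <- smooth_min_bout(labels, params$min_bout_epochs)
  }
  hypnogram(labels, epoch_s = attr(features, "epoch_s") %||% 5)
}

## Merge runs shorter than min_bout into the preceding run (following run
## at the start of the recording). Iterated until stable.
smooth_min_bout <- function(labels, min_bout) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_bout)
    if (!length(short)) break
    i <- short[1L]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    labels <- inverse.rle(r)
  }
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Epoch-label agreement between two hypnograms
#'
#' @param hyp,reference Hypnograms on the same epoch grid.
#' @return Fraction of epochs with identical labels.
#' @export
staging_accuracy <- function(hyp, reference) {
  n <- min(nrow(hyp), nrow(reference))
  if (nrow(hyp) != nrow(reference)) {
    warning("hypnograms differ in length; comparing the first ", n, " epochs")
  }
  mean(as.character(hyp$state[seq_len(n)]) ==
         as.character(reference$state[seq_len(n)]))
}
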