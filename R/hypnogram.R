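#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr mutate filter group_by ungroup summarise arrange select
#' @importFrom tibble tibble as_tibble
NULL

## The three scored brain states, in canonical order.
BRAIN_STATES <- c("Wake", "NREM", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is a tibble of per-epoch brain-state labels on a fixed epoch
#' grid. Epochs are half-open intervals `[t0 + i * epoch_s, t0 + (i+1) *
#' epoch_s)` with 0-based `epoch` indices.
#'
#' @param states Character or factor vector of labels, each one of
#'   `"Wake"`, `"NREM"`, `"REM"`.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param t0_s Recording-relative start time of epoch 0, seconds.
#' @return A tibble of class `hypnogram` with columns `epoch`, `t_start_s`
#'   and `state` (factor with the three state levels), plus `epoch_s` and
#'   `t0_s` attributes.
#' @examples
#' hypnogram(c("Wake", "Wake", "NREM", "NREM", "REM"))
#' @export
hypnogram <- function(states, epoch_s = 5, t0_s = 0) {
  states <- as.character(states)
  if (length(states) == 0L) stop("hypnogram needs at least one epoch label")
  if (!all(states %in% BRAIN_STATES)) {
    bad <- setdiff(unique(states), BRAIN_STATES)
    stop("unknown brain state label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(epoch_s) || length(epoch_s) != 1L || epoch_s <= 0) {
    stop("epoch_s must be a single positive number")
  }
  out <- tibble(
    epoch = seq_along(states) - 1L,
    t_start_s = t0_s + (seq_along(states) - 1L) * epoch_s,
    state = factor(states, levels = BRAIN_STATES)
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "t0_s") <- t0_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram: %d epochs x %g s, %.1f min>\n",
    nrow(x), hyp_epoch_s(x), nrow(x) * hyp_epoch_s(x) / 60
  ))
  NextMethod()
}

hyp_epoch_s <- function(hyp) {
  e <- attr(hyp, "epoch_s")
  if (is.null(e)) {
    if (nrow(hyp) < 2L) stop("hypnogram has no epoch_s attribute")
    e <- diff(hyp$t_start_s[1:2])
  }
  e
}

hyp_t0_s <- function(hyp) {
  t0 <- attr(hyp, "t0_s")
  if (is.null(t0)) t0 <- hyp$t_start_s[1L]
  t0
}

## Map times (seconds) to 0-based epoch indices; NA outside the hypnogram.
hyp_epoch_of <- function(hyp, t_s) {
  eps <- hyp_epoch_s(hyp)
  idx <- floor((t_s - hyp_t0_s(hyp)) / eps)
  idx[idx < 0 | idx >= nrow(hyp)] <- NA_integer_
  as.integer(idx)
}

#' Laser stimulation protocol
#'
#' Holds pulse onset times, pulse width and train bounds for an optogenetic
#' stimulation protocol (e.g. 10 Hz trains of 1-ms pulses).
#'
#' @param pulse_t_s Numeric vector of pulse onset times, seconds, increasing.
#' @param pulse_width_s Pulse width in seconds (default 0.001, i.e. 1 ms).
#' @param train_bounds Optional two-column data frame / matrix of train
#'   `(start, end)` times in seconds. If `NULL`, pulses separated by more
#'   than `gap_s` are split into trains and bounds derived from the pulses.
#' @param freq_hz Nominal intra-train pulse rate, Hz.
#' @param gap_s Gap used to split pulses into trains when `train_bounds` is
#'   not given (default 1 s).
#' @param label Free-text tag (wavelength/power).
#' @return An object of class `laser_protocol`.
#' @examples
#' # three 1-s trains of 10 pulses at 10 Hz, 90 s apart
#' laser_trains(c(0, 90, 180), n_pulses = 10, freq_hz = 10)
#' @export
laser_protocol <- function(pulse_t_s, pulse_width_s = 0.001,
                           train_bounds = NULL, freq_hz = NA_real_,
                           gap_s = 1, label = "") {
  pulse_t_s <- as.numeric(pulse_t_s)
  if (is.unsorted(pulse_t_s, strictly = TRUE)) {
    stop("pulse_t_s must be strictly increasing")
  }
  if (!is.numeric(pulse_width_s) || pulse_width_s <= 0) {
    stop("pulse_width_s must be > 0")
  }
  if (is.null(train_bounds)) {
    if (length(pulse_t_s)) {
      grp <- cumsum(c(1, diff(pulse_t_s) > gap_s))
      start <- tapply(pulse_t_s, grp, min)
      end <- tapply(pulse_t_s, grp, max) + pulse_width_s
      train_bounds <- tibble(start = as.numeric(start), end = as.numeric(end))
    } else {
      train_bounds <- tibble(start = numeric(), end = numeric())
    }
  } else {
    train_bounds <- as_tibble(as.data.frame(train_bounds))
    names(train_bounds)[1:2] <- c("start", "end")
  }
  if (length(pulse_t_s)) {
    in_train <- vapply(pulse_t_s, function(t) {
      any(t >= train_bounds$start - 1e-9 & t <= train_bounds$end + 1e-9)
    }, logical(1))
    if (!all(in_train)) stop("every pulse must lie within a train bound")
  }
  structure(
    list(
      pulse_t_s = pulse_t_s, pulse_width_s = pulse_width_s,
      train_bounds = train_bounds, freq_hz = freq_hz, label = label
    ),
    class = "laser_protocol"
  )
}

#' @rdname laser_protocol
#' @param onset_t_s Train onset times, seconds.
#' @param n_pulses Pulses per train.
#' @export
laser_trains <- function(onset_t_s, n_pulses = 10, freq_hz = 10,
                         pulse_width_s = 0.001, label = "") {
  onset_t_s <- sort(as.numeric(onset_t_s))
  pulses <- as.numeric(vapply(
    onset_t_s,
    function(t0) t0 + (seq_len(n_pulses) - 1) / freq_hz,
    numeric(n_pulses)
  ))
  bounds <- tibble(
    start = onset_t_s,
    end = onset_t_s + (n_pulses - 1) / freq_hz + pulse_width_s
  )
  laser_protocol(sort(pulses), pulse_width_s, bounds, freq_hz, label = label)
}

#' @export
print.laser_protocol <- function(x, ...) {
  cat(sprintf(
    "<laser_protocol: %d pulses in %d train(s), width %g ms%s>\n",
    length(x$pulse_t_s), nrow(x$train_bounds), x$pulse_width_s * 1000,
    if (nzchar(x$label)) paste0(", ", x$label) else ""
  ))
  invisible(x)
}

## TRUE for times lying inside any laser train.
in_any_train <- function(t_s, laser) {
  if (is.null(laser) || nrow(laser$train_bounds) == 0L) {
    return(rep(FALSE, length(t_s)))
  }
  out <- rep(FALSE, length(t_s))
  for (k in seq_len(nrow(laser$train_bounds))) {
    out <- out | (t_s >= laser$train_bounds$start[k] &
                    t_s < laser$train_bounds$end[k])
  }
  out
}
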