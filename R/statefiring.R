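#' Brain-state-dependent firing rates
#'
#' Rate per state = spikes falling in that state's epochs / total scored
#' time in that state, with half-open epoch membership. Spikes outside the
#' hypnogram span are ignored (count reported via message). Epochs
#' overlapping a laser train can be excluded from both numerator and
#' denominator so stimulation-evoked spikes do not contaminate spontaneous
#' rates.
#'
#' @param t_s Spike times (seconds) or a single-unit data frame with `t_s`.
#' @param hyp A [hypnogram()].
#' @param laser Optional [laser_protocol()].
#' @param exclude_laser Drop epochs overlapping any laser train (default:
#'   TRUE whenever `laser` is supplied).
#' @param min_state_s States scored for less than this (default 30 s) are
#'   flagged `reliable = FALSE`.
#' @return A tibble of class `state_rates`: `state`, `n_spikes`,
#'   `seconds`, `rate_hz`, `reliable`. States absent from the hypnogram get
#'   `rate_hz = NA`.
#' @export
state_rates <- function(t_s, hyp, laser = NULL,
                        exclude_laser = !is.null(laser), min_state_s = 30) {
  t_s <- spike_times(t_s)
  eps <- hyp_epoch_s(hyp)
  keep_epoch <- rep(TRUE, nrow(hyp))
  if (exclude_laser && !is.null(laser)) {
    keep_epoch <- !(in_any_train(hyp$t_start_s, laser) |
                      in_any_train(hyp$t_start_s + eps - 1e-9, laser))
  }
  ep <- hyp_epoch_of(hyp, t_s)
  n_outside <- sum(is.na(ep))
  if (n_outside > 0L) {
    message(n_outside, " spike(s) outside the hypnogram span ignored")
  }
  ep <- ep[!is.na(ep)]
  ep <- ep[keep_epoch[ep + 1L]]
  spike_state <- as.character(hyp$state[ep + 1L])
  out <- purrr::map_dfr(BRAIN_STATES, function(s) {
    secs <- sum(as.character(hyp$state) == s & keep_epoch) * eps
    n <- sum(spike_state == s)
    tibble(
      state = s, n_spikes = n, seconds = secs,
      rate_hz = if (secs > 0) n / secs else NA_real_,
      reliable = secs >= min_state_s
    )
  })
  out$state <- factor(out$state, levels = BRAIN_STATES)
  class(out) <- c("state_rates", class(out))
  out
}

#' Brain-state modulation indices
#'
#' Normalized rate contrasts between brain states:
#' `wake_nrem_mod = (R_wake - R_NREM) / (R_wake + R_NREM)` and
#' `rem_nrem_mod = (R_REM - R_NREM) / (R_REM + R_NREM)`, where `R` is the
#' average firing rate within each state. Both indices are bounded in
#' `[-1, 1]`; a 0/0 contrast yields `NaN` with a warning.
#'
#' @param rates A [state_rates()] result (or any data frame with `state`
#'   and `rate_hz`).
#' @return A one-row tibble with `wake_nrem_mod` and `rem_nrem_mod`.
#' @examples
#' r <- tibble::tibble(state = c("Wake", "NREM", "REM"), rate_hz = c(6, 2, 1))
#' modulation_indices(r)
#' @export
modulation_indices <- function(rates) {
  get_rate <- function(s) {
    r <- rates$rate_hz[as.character(rates$state) == s]
    if (length(r) != 1L) stop("rates must contain exactly one row for ", s)
    r
  }
  mod <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (a + b == 0) {
      warning("both rates zero; modulation index undefined (NaN)")
      return(NaN)
    }
    (a - b) / (a + b)
  }
  tibble(
    wake_nrem_mod = mod(get_rate("Wake"), get_rate("NREM")),
    rem_nrem_mod = mod(get_rate("REM"), get_rate("NREM"))
  )
}

#' Firing around brain-state transitions
#'
#' Locates epoch boundaries where the hypnogram switches `from -> to` with
#' both flanking bouts at least `min_bout_epochs` long, bins spikes relative
#' to each transition time, and averages across transitions. The SEM is
#' computed across transitions (events), not across time bins.
#'
#' @param t_s Spike times, seconds.
#' @param hyp A [hypnogram()].
#' @param from,to Brain states defining the transition.
#' @param window_s Half-window around the transition, seconds (default 60).
#' @param bin_s Histogram bin width, seconds (default 5).
#' @param min_bout_epochs Minimum flanking bout length in epochs (default 3)
#'   to exclude flicker transitions.
#' @return A tibble of class `psth`: `bin_lo_s`, `bin_hi_s`, `t_mid_s`,
#'   `rate_hz`, `sem`, with attributes `n_events` and `alignment`. Zero
#'   qualifying transitions give a zero-row result with a warning.
#' @export
peri_transition_rates <- function(t_s, hyp, from, to, window_s = 60,
                                  bin_s = 5, min_bout_epochs = 3L) {
  stopifnot(from %in% BRAIN_STATES, to %in% BRAIN_STATES, from != to)
  t_s <- spike_times(t_s)
  eps <- hyp_epoch_s(hyp)
  r <- rle(as.character(hyp$state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(
    r$values[-length(r$values)] == from & r$values[-1] == to &
      r$lengths[-length(r$lengths)] >= min_bout_epochs &
      r$lengths[-1] >= min_bout_epochs
  )
  event_t <- hyp_t0_s(hyp) + (starts[qual + 1L] - 1L) * eps
  span <- c(hyp_t0_s(hyp), hyp_t0_s(hyp) + nrow(hyp) * eps)
  inside <- event_t - window_s >= span[1] & event_t + window_s <= span[2]
  if (any(!inside)) {
    message(sum(!inside), " transition(s) too close to the recording edge dropped")
  }
  event_t <- event_t[inside]
  psth_from_events(t_s, event_t, -window_s, window_s, bin_s,
                   alignment = paste0(from, "->", to))
}

psth_from_events <- function(t_s, event_t, lo_s, hi_s, bin_s, alignment) {
  edges <- seq(lo_s, hi_s, by = bin_s)
  n_bins <- length(edges) - 1L
  out <- tibble(
    bin_lo_s = edges[-length(edges)], bin_hi_s = edges[-1],
    t_mid_s = (edges[-length(edges)] + edges[-1]) / 2
  )
  if (length(event_t) == 0L) {
    warning("no qualifying events; returning an empty histogram")
    out$rate_hz <- numeric(n_bins) * NA_real_
    out$sem <- NA_real_
    out <- out[0, ]
  } else {
    counts <- vapply(event_t, function(t0) {
      rel <- t_s - t0
      graphics::hist(rel[rel >= lo_s & rel < hi_s],
                     breaks = edges, right = FALSE, plot = FALSE)$counts
    }, numeric(n_bins))
    counts <- matrix(counts, nrow = n_bins)
    rates <- counts / bin_s
    out$rate_hz <- rowMeans(rates)
    out$sem <- if (length(event_t) >= 2L) {
      apply(rates, 1, stats::sd) / sqrt(length(event_t))
    } else {
      NA_real_ # SEM undefined for a single event
    }
  }
  attr(out, "n_events") <- length(event_t)
  attr(out, "alignment") <- alignment
  class(out) <- c("psth", class(out))
  out
}

#' Firing before and after discrete stimuli
#'
#' Per-event mean rates in the `pre_s` window before and `post_s` window
#' after each event (e.g. von Frey applications), plus the across-event
#' peri-stimulus time histogram. Events whose windows overlap a neighbour
#' are dropped with a warning; events extending past the recording edge are
#' dropped with a message.
#'
#' @param t_s Spike times, seconds.
#' @param event_t_s Event times, seconds.
#' @param pre_s,post_s Window lengths, seconds.
#' @param bin_s PSTH bin width, seconds (default 1).
#' @param span_s Optional recording span `c(start, end)` for edge checks;
#'   defaults to the spike-time range.
#' @return A list with `paired` (tibble: `event_t_s`, `before_rate_hz`,
#'   `after_rate_hz`) and `psth` (a `psth` tibble).
#' @export
peri_stimulus_rates <- function(t_s, event_t_s, pre_s, post_s, bin_s = 1,
                                span_s = NULL) {
  t_s <- spike_times(t_s)
  event_t_s <- sort(as.numeric(event_t_s))
  if (length(event_t_s) == 0L) stop("no events supplied")
  if (is.null(span_s)) span_s <- range(t_s)
  inside <- event_t_s - pre_s >= span_s[1] & event_t_s + post_s <= span_s[2]
  if (any(!inside)) {
    message(sum(!inside), " event(s) extending past the recording edge dropped")
    event_t_s <- event_t_s[inside]
  }
  if (length(event_t_s) > 1L) {
    overlap <- c(FALSE, diff(event_t_s) < pre_s + post_s)
    if (any(overlap)) {
      warning(sum(overlap), " overlapping event(s) dropped")
      event_t_s <- event_t_s[!overlap]
    }
  }
  if (length(event_t_s) == 0L) stop("no usable events after edge/overlap filtering")
  paired <- tibble(
    event_t_s = event_t_s,
    before_rate_hz = vapply(event_t_s, function(t0) {
      sum(t_s >= t0 - pre_s & t_s < t0) / pre_s
    }, numeric(1)),
    after_rate_hz = vapply(event_t_s, function(t0) {
      sum(t_s >= t0 & t_s < t0 + post_s) / post_s
    }, numeric(1))
  )
  list(
    paired = paired,
    psth = psth_from_events(t_s, event_t_s, -pre_s, post_s, bin_s, "event")
  )
}

#' Paired comparison of pre/post firing rates
#'
#' Two-sided Wilcoxon signed-rank test on paired rates (e.g. before/after a
#' stimulus, or pre/post a state transition, across units or events).
#'
#' @param pre_rates,post_rates Paired numeric vectors, equal length >= 5.
#' @return A one-row tibble: `n`, `median_diff`, `direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `statistic`, `p_value`.
#' @export
compare_transition_rates <- function(pre_rates, post_rates) {
  if (length(pre_rates) != length(post_rates)) {
    stop("pre and post must be paired (equal length)")
  }
  if (length(pre_rates) < 5L) stop("need at least 5 pairs")
  d <- post_rates - pre_rates
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(tibble(
      n = length(d), median_diff = 0, direction = "none",
      statistic = NA_real_, p_value = 1
    ))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(post_rates, pre_rates, paired = TRUE,
                       alternative = "two.sided")
  )
  md <- stats::median(d)
  tibble(
    n = length(d), median_diff = md,
    direction = if (md > 0) "increase" else if (md < 0) "decrease" else "none",
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}
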