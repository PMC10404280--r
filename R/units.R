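#' Laser-evoked spike statistics for one unit
#'
#' For every laser pulse, the first spike in the half-open window
#' `(onset, onset + window_ms]` counts as the evoked response. Reliability
#' is the fraction of pulses with a response; latency is the median
#' first-spike latency; jitter is the SD of first-spike latencies over
#' responding pulses.
#'
#' @param t_s Spike times in seconds (strictly increasing), or a data frame
#'   with a `t_s` column.
#' @param laser A [laser_protocol()] with at least one pulse (>= 10 for a
#'   stable estimate; fewer triggers a warning).
#' @param window_ms Response window after pulse onset, ms (default 10).
#' @return A one-row tibble: `reliability`, `latency_ms`, `jitter_ms`,
#'   `n_pulses`, `n_responding`. With zero responding pulses, reliability is
#'   0 and latency/jitter are `NA`.
#' @export
evoked_spike_stats <- function(t_s, laser, window_ms = 10) {
  t_s <- spike_times(t_s)
  if (length(laser$pulse_t_s) == 0L) stop("laser protocol has no pulses")
  if (length(laser$pulse_t_s) < 10L) {
    warning("fewer than 10 pulses; evoked statistics will be noisy")
  }
  if (window_ms / 1000 < laser$pulse_width_s) {
    stop("response window must be at least as long as the pulse width")
  }
  lat <- first_spike_latency_ms(t_s, laser$pulse_t_s, window_ms)
  resp <- !is.na(lat)
  tibble(
    reliability = mean(resp),
    latency_ms = if (any(resp)) stats::median(lat[resp]) else NA_real_,
    jitter_ms = if (sum(resp) >= 2L) stats::sd(lat[resp])
                else if (sum(resp) == 1L) 0 else NA_real_,
    n_pulses = length(laser$pulse_t_s),
    n_responding = sum(resp)
  )
}

## Latency (ms) of the first spike in (pulse, pulse + window]; NA if none.
first_spike_latency_ms <- function(t_s, pulse_t_s, window_ms) {
  w <- window_ms / 1000
  idx <- findInterval(pulse_t_s, t_s, left.open = FALSE) + 1L
  lat <- rep(NA_real_, length(pulse_t_s))
  has <- idx <= length(t_s)
  dt <- t_s[idx[has]] - pulse_t_s[has]
  ok <- dt > 0 & dt <= w
  lat[which(has)[ok]] <- dt[ok] * 1000
  lat
}

#' Waveform similarity of evoked and spontaneous spikes
#'
#' Pearson correlation between the mean laser-evoked spike waveform (first
#' spikes in the post-pulse window) and the mean spontaneous waveform
#' (spikes outside all laser trains).
#'
#' @param t_s Spike times, seconds.
#' @param snippets Numeric matrix, one row per spike (aligned with `t_s`),
#'   columns = waveform samples.
#' @param laser A [laser_protocol()].
#' @param window_ms Evoked response window, ms.
#' @param min_spikes Minimum evoked and spontaneous spike count (default 5).
#' @return Pearson r between the two mean waveforms.
#' @export
waveform_similarity <- function(t_s, snippets, laser, window_ms = 10,
                                min_spikes = 5L) {
  t_s <- spike_times(t_s)
  if (is.null(snippets)) {
    stop("waveform snippets missing: waveform-based tagging unavailable")
  }
  snippets <- as.matrix(snippets)
  if (nrow(snippets) != length(t_s)) {
    stop("snippets must have one row per spike")
  }
  lat <- first_spike_latency_ms(t_s, laser$pulse_t_s, window_ms)
  resp_pulse <- which(!is.na(lat))
  evoked_t <- laser$pulse_t_s[resp_pulse] + lat[resp_pulse] / 1000
  evoked_idx <- match(round(evoked_t, 9), round(t_s, 9))
  spont_idx <- which(!in_any_train(t_s, laser))
  spont_idx <- setdiff(spont_idx, evoked_idx)
  if (length(evoked_idx) < min_spikes || length(spont_idx) < min_spikes) {
    stop("need at least ", min_spikes, " evoked and ", min_spikes,
         " spontaneous spikes with snippets")
  }
  stats::cor(colMeans(snippets[evoked_idx, , drop = FALSE]),
             colMeans(snippets[spont_idx, , drop = FALSE]))
}

#' Optotagging decision thresholds
#'
#' Defaults as used for in vivo channelrhodopsin tagging: response
#' reliability > 0.7, first-spike latency < 3 ms, jitter < 3 ms, and (when
#' waveforms are available) evoked/spontaneous waveform correlation > 0.95.
#' All comparisons are strict.
#'
#' @param reliability_min,latency_max_ms,jitter_max_ms,waveform_corr_min
#'   Threshold values.
#' @return A list of class `tag_thresholds`.
#' @export
tag_thresholds <- function(reliability_min = 0.7, latency_max_ms = 3,
                           jitter_max_ms = 3, waveform_corr_min = 0.95) {
  structure(
    list(
      reliability_min = reliability_min, latency_max_ms = latency_max_ms,
      jitter_max_ms = jitter_max_ms, waveform_corr_min = waveform_corr_min
    ),
    class = "tag_thresholds"
  )
}

#' Classify a unit as optogenetically tagged
#'
#' A unit is tagged when reliability, latency and jitter all pass their
#' strict thresholds and, when a waveform correlation is available, the
#' evoked/spontaneous correlation does too. A missing `waveform_corr`
#' degrades to the three-criterion rule with a warning.
#'
#' @param stats A data frame with columns `reliability`, `latency_ms`,
#'   `jitter_ms` (e.g. from [evoked_spike_stats()]), one row per unit;
#'   optional columns `unit_id`, `waveform_corr`,
#'   `refractory_violation_frac`, `isolation_distance` are carried through.
#' @param thresholds A [tag_thresholds()].
#' @return A tibble of class `tag_report`: the input metrics plus a logical
#'   `tagged` column.
#' @export
classify_tagged <- function(stats, thresholds = tag_thresholds()) {
  stats <- as_tibble(stats)
  need <- c("reliability", "latency_ms", "jitter_ms")
  if (!all(need %in% names(stats))) {
    stop("stats must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"unit_id" %in% names(stats)) {
    stats$unit_id <- paste0("u", seq_len(nrow(stats)))
  }
  if (!"waveform_corr" %in% names(stats)) {
    stats$waveform_corr <- NA_real_
  }
  if (anyNA(stats$waveform_corr)) {
    warning("waveform_corr missing for ", sum(is.na(stats$waveform_corr)),
            " unit(s); applying the three-criterion rule for those")
  }
  core <- !is.na(stats$reliability) &
    stats$reliability > thresholds$reliability_min &
    !is.na(stats$latency_ms) & stats$latency_ms < thresholds$latency_max_ms &
    !is.na(stats$jitter_ms) & stats$jitter_ms < thresholds$jitter_max_ms
  wf_ok <- is.na(stats$waveform_corr) |
    stats$waveform_corr > thresholds$waveform_corr_min
  out <- dplyr::relocate(mutate(stats, tagged = core & wf_ok), "unit_id")
  class(out) <- c("tag_report", class(out))
  out
}

#' Refractory-period violation fraction
#'
#' Fraction of inter-spike intervals shorter than the refractory period,
#' with the total spike count as denominator: `#\{ISI < refractory\} /
#' #spikes`. A well-isolated unit keeps this below 0.2% at a 2-ms
#' refractory period.
#'
#' @param t_s Spike times, seconds.
#' @param refractory_ms Refractory period, ms (default 2).
#' @return The violation fraction (0 with a warning for < 2 spikes).
#' @export
refractory_violation_fraction <- function(t_s, refractory_ms = 2) {
  t_s <- spike_times(t_s)
  if (length(t_s) < 2L) {
    warning("fewer than 2 spikes; violation fraction undefined, returning 0")
    return(0)
  }
  sum(diff(t_s) < refractory_ms / 1000) / length(t_s)
}

#' Cluster isolation distance
#'
#' Separation of a sorted unit's cluster in spike-feature space. The default
#' (`method = "centroid"`) is the Mahalanobis distance from the cluster's
#' centroid to the nearest other cluster's centroid, under the cluster's own
#' covariance — taking the minimum over other clusters. The alternative
#' (`method = "nearest-spike"`) is the conventional isolation distance: the
#' squared Mahalanobis distance of the n-th closest non-cluster spike, n
#' being the cluster size.
#'
#' @param cluster_features Numeric matrix (spikes x features) of the unit's
#'   cluster.
#' @param other_clusters Matrix, or list of matrices, of the other clusters'
#'   features.
#' @param method `"centroid"` (default) or `"nearest-spike"`.
#' @param ridge Relative ridge added to a singular covariance (with a
#'   message).
#' @return The isolation distance (numeric scalar).
#' @export
isolation_distance <- function(cluster_features, other_clusters,
                               method = c("centroid", "nearest-spike"),
                               ridge = 1e-8) {
  method <- match.arg(method)
  X <- as.matrix(cluster_features)
  if (is.matrix(other_clusters) || is.data.frame(other_clusters)) {
    other_clusters <- list(as.matrix(other_clusters))
  }
  other_clusters <- lapply(other_clusters, as.matrix)
  S <- stats::cov(X)
  if (inherits(try(solve(S), silent = TRUE), "try-error")) {
    eps <- ridge * mean(diag(S))
    if (eps <= 0) eps <- ridge
    S <- S + diag(eps, ncol(S))
    message("singular cluster covariance; ridge-regularized with epsilon = ",
            signif(eps, 3))
  }
  ctr <- colMeans(X)
  if (method == "centroid") {
    d <- vapply(other_clusters, function(Y) {
      sqrt(stats::mahalanobis(colMeans(Y), center = ctr, cov = S))
    }, numeric(1))
    min(d)
  } else {
    noise <- do.call(rbind, other_clusters)
    if (nrow(noise) < nrow(X)) {
      warning("fewer non-cluster spikes than cluster spikes; ",
              "nearest-spike isolation distance is undefined, returning NA")
      return(NA_real_)
    }
    d2 <- stats::mahalanobis(noise, center = ctr, cov = S)
    sort(d2)[nrow(X)]
  }
}

## Accept a bare numeric vector or any data frame with a t_s column.
spike_times <- function(t_s) {
  if (is.data.frame(t_s)) {
    if (!"t_s" %in% names(t_s)) stop("data frame input needs a t_s column")
    if ("unit_id" %in% names(t_s) && length(unique(t_s$unit_id)) > 1L) {
      stop("multiple units in input; filter to a single unit_id first")
    }
    t_s <- t_s$t_s
  }
  t_s <- as.numeric(t_s)
  if (length(t_s) > 1L && is.unsorted(t_s, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  t_s
}
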