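#' Simulate state-dependent spike trains with laser-evoked spikes
#'
#' Background activity of each unit is an inhomogeneous Poisson process
#' whose rate is piecewise constant at the unit's configured rate for the
#' current brain state. For units with `evoked_params`, every laser pulse
#' independently adds one evoked spike with probability `reliability` at
#' `latency_ms + Normal(0, jitter_ms)` after pulse onset. Background and
#' evoked spikes are merged, sorted, and any spike closer than an absolute
#' refractory period (1 ms) to its predecessor is dropped, keeping the
#' earlier spike.
#'
#' @param hyp A [hypnogram()] giving the state timeline.
#' @param laser A [laser_protocol()] or `NULL` for no stimulation.
#' @param cfg A [sim_config()] supplying `unit_state_rates` and
#'   `evoked_params`.
#' @return A tibble with columns `unit_id` and `t_s` (strictly increasing
#'   within each unit), one row per spike.
#' @examples
#' cfg <- sim_config(seed = 1, duration_s = 300)
#' spk <- simulate_spikes(simulate_hypnogram(cfg), laser = NULL, cfg = cfg)
#' dplyr::count(spk, unit_id)
#' @export
simulate_spikes <- function(hyp, laser = NULL, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  eps <- hyp_epoch_s(hyp)
  states <- as.character(hyp$state)
  t0 <- hyp_t0_s(hyp)
  withr::with_seed(sim_substream(cfg, 3L), {
    out <- purrr::imap(cfg$unit_state_rates, function(rates, uid) {
      bg <- poisson_epoch_spikes(states, rates, eps, t0)
      ev <- numeric(0)
      ep <- cfg$evoked_params[[uid]]
      if (!is.null(ep) && !is.null(laser) && length(laser$pulse_t_s)) {
        hit <- stats::runif(length(laser$pulse_t_s)) < ep$reliability
        lat <- ep$latency_ms / 1000 +
          stats::rnorm(sum(hit), sd = ep$jitter_ms / 1000)
        ev <- laser$pulse_t_s[hit] + lat
      }
      t_all <- sort(c(bg, ev))
      if (length(t_all) > 1L) {
        keep <- c(TRUE, diff(t_all) >= 1e-3) # 1-ms absolute refractory merge
        t_all <- t_all[keep]
      }
      tibble(unit_id = uid, t_s = t_all)
    })
    dplyr::bind_rows(out)
  })
}

## Homogeneous Poisson within each epoch at the state's rate.
poisson_epoch_spikes <- function(states, rates, eps, t0) {
  lam <- unname(rates[states]) * eps
  counts <- stats::rpois(length(states), lam)
  if (sum(counts) == 0L) return(numeric(0))
  epoch_idx <- rep(seq_along(states) - 1L, counts)
  sort(t0 + (epoch_idx + stats::runif(sum(counts))) * eps)
}
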