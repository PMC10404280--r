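#' Simulate a multi-mouse laser-stimulation cohort
#'
#' Convenience wrapper for transition-probability studies: for each mouse,
#' simulates a hypnogram (started at stationarity) with repeated laser
#' trains, builds trials aligned to the train onsets, and binds the
#' per-mouse trial sets. Mouse `i` draws from the sub-stream `seed + i` of
#' the base configuration, so cohorts are reproducible and mice mutually
#' independent.
#'
#' @param cfg A [sim_config()]; its `laser_effect` (if any) acts during the
#'   trains.
#' @param n_mice Number of mice.
#' @param trials_per_mouse Laser trains (= trials) per mouse.
#' @param pre_s,post_s Trial window around each train onset, seconds
#'   (multiples of `bin_s`; `post_s` counted from onset).
#' @param bin_s Bin width, seconds (default 60).
#' @param laser_duration_s Stimulation duration per train, seconds
#'   (default 120, e.g. 10 Hz x 2 min).
#' @param inter_trial_gap_s Recovery time between the end of one trial
#'   window and the next train's pre-window, seconds (default 600).
#'   Stimulation protocols space trains several minutes apart so that each
#'   trial samples independent sleep dynamics; with bout durations of a few
#'   minutes, a 10-min gap makes consecutive trials effectively
#'   uncorrelated.
#' @return A multi-mouse `trial_set` (see [build_trials()]).
#' @examples
#' cfg <- sim_config(seed = 1)
#' tr <- simulate_cohort(cfg, n_mice = 2, trials_per_mouse = 2,
#'                       pre_s = 180, post_s = 240)
#' dplyr::count(tr, mouse, trial)
#' @export
simulate_cohort <- function(cfg, n_mice, trials_per_mouse, pre_s, post_s,
                            bin_s = 60, laser_duration_s = 120,
                            inter_trial_gap_s = 600) {
  stopifnot(inherits(cfg, "sim_config"), n_mice >= 1, trials_per_mouse >= 1)
  spacing <- pre_s + post_s + inter_trial_gap_s
  onsets <- pre_s + (seq_len(trials_per_mouse) - 1L) * spacing
  duration <- max(onsets) + post_s
  laser <- laser_protocol(
    pulse_t_s = onsets, pulse_width_s = laser_duration_s,
    train_bounds = tibble(start = onsets, end = onsets + laser_duration_s)
  )
  sets <- lapply(seq_len(n_mice), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    cfg_i$duration_s <- duration
    hyp <- simulate_hypnogram(cfg_i, laser = laser, init_state = "stationary")
    build_trials(hyp, laser, pre_s = pre_s, post_s = post_s, bin_s = bin_s,
                 mouse = sprintf("m%02d", i))
  })
  bind_trial_sets(sets)
}
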