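#' Simulate an up-down von Frey session
#'
#' Drives the up-down rule ([next_filament()]) with responses drawn from a
#' logistic psychometric function of `log10` filament force:
#' `P(withdraw | g) = plogis(slope * log10(g / threshold))`. With
#' `slope = Inf` the psychometric is a step function and the animal
#' withdraws exactly when `g >= threshold`, making the whole sequence
#' deterministic.
#'
#' @param cfg A [sim_config()]; `cfg$psychometric` supplies
#'   `c(threshold_g, slope)` and `cfg$seed` the random stream.
#' @param filament_set Ascending filament series (grams).
#' @param start_g Starting filament (default 0.16 g).
#' @param max_trials Safety bound on session length.
#' @return A terminated [updown_session()]; the termination flag
#'   (`"none"`, `"floor"`, `"ceiling"`) is stored in the `flag` attribute.
#' @examples
#' cfg <- sim_config(seed = 3, psychometric = c(threshold_g = 0.4, slope = Inf))
#' simulate_updown_responses(cfg)
#' @export
simulate_updown_responses <- function(cfg, filament_set = vonfrey_set_mouse(),
                                      start_g = 0.16, max_trials = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(filament_set) == 0L) stop("filament_set must be non-empty")
  thr <- cfg$psychometric[[1]]
  slope <- cfg$psychometric[[2]]
  withr::with_seed(sim_substream(cfg, 4L), {
    g <- numeric(0)
    r <- logical(0)
    flag <- "none"
    for (i in seq_len(max_trials)) {
      ses <- updown_session(g, r, filament_set, start_g, validate = FALSE)
      nxt <- next_filament(ses)
      if (nxt$action == "stop") {
        flag <- nxt$flag
        break
      }
      p <- if (is.infinite(slope)) {
        as.numeric(nxt$filament_g >= thr)
      } else {
        stats::plogis(slope * log10(nxt$filament_g / thr))
      }
      g <- c(g, nxt$filament_g)
      r <- c(r, stats::runif(1) < p)
    }
    out <- updown_session(g, r, filament_set, start_g)
    attr(out, "flag") <- flag
    out
  })
}
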