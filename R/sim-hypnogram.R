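#' Simulate a hypnogram from a semi-Markov state process
#'
#' Draws Wake/NREM/REM bouts from the configured dwell-time law (exponential
#' by default, optionally gamma), rounds each bout to the 5-s epoch grid
#' (minimum one epoch), and chains bouts through the embedded next-state
#' matrix. While a laser train is active, the per-epoch transition hazard is
#' perturbed: at each epoch boundary falling inside a train, the state jumps
#' `X -> Y` with the extra probability configured in `cfg$laser_effect`,
#' pre-empting the running bout.
#'
#' @param cfg A [sim_config()].
#' @param laser Optional [laser_protocol()]; required for `laser_effect` to
#'   act.
#' @param init_state Starting state; `"stationary"` samples it from the
#'   generator's long-run occupancy ([expected_occupancy()]), which for the
#'   default exponential dwell law starts the chain at stationarity.
#' @return A [hypnogram()] covering `floor(duration_s / epoch_s)` epochs.
#' @examples
#' hyp <- simulate_hypnogram(sim_config(seed = 1, duration_s = 600))
#' table(hyp$state)
#' @export
simulate_hypnogram <- function(cfg, laser = NULL, init_state = "Wake") {
  stopifnot(inherits(cfg, "sim_config"))
  n_epochs <- floor(cfg$duration_s / cfg$epoch_s)
  if (n_epochs < 1L) stop("duration_s must cover at least one epoch")
  withr::with_seed(sim_substream(cfg, 1L), {
    if (identical(init_state, "stationary")) {
      init_state <- sample(BRAIN_STATES, 1L, prob = expected_occupancy(cfg))
    }
    labels <- simulate_hypnogram_labels(cfg, n_epochs, laser, init_state)
  })
  hypnogram(labels, epoch_s = cfg$epoch_s, t0_s = 0)
}

simulate_hypnogram_labels <- function(cfg, n_epochs, laser, init_state) {
  eps <- cfg$epoch_s
  draw_bout_epochs <- function(state) {
    mu <- cfg$state_dwell_means[[state]]
    d <- if (cfg$dwell_law == "exponential") {
      stats::rexp(1, rate = 1 / mu)
    } else {
      stats::rgamma(1, shape = cfg$dwell_shape, rate = cfg$dwell_shape / mu)
    }
    max(1L, as.integer(round(d / eps)))
  }
  draw_next <- function(state) {
    sample(BRAIN_STATES, 1L, prob = cfg$next_state_probs[state, ])
  }
  ## laser deltas indexed by from-state
  eff_from <- list()
  if (length(cfg$laser_effect)) {
    pairs <- strsplit(names(cfg$laser_effect), "->", fixed = TRUE)
    for (i in seq_along(pairs)) {
      f <- pairs[[i]][1]
      eff_from[[f]] <- rbind(
        eff_from[[f]],
        data.frame(to = pairs[[i]][2], delta = cfg$laser_effect[[i]])
      )
    }
  }
  epoch_in_train <- if (is.null(laser)) {
    rep(FALSE, n_epochs)
  } else {
    t_start <- (seq_len(n_epochs) - 1L) * eps
    starts_in <- in_any_train(t_start, laser)
    ends_in <- in_any_train(t_start + eps - 1e-9, laser)
    starts_in | ends_in
  }

  labels <- character(n_epochs)
  state <- init_state
  remaining <- draw_bout_epochs(state)
  for (e in seq_len(n_epochs)) {
    labels[e] <- state
    if (e == n_epochs) break
    jumped <- FALSE
    ## extra hazard applied to the transition into epoch e + 1
    if (epoch_in_train[e + 1L] && !is.null(eff_from[[state]])) {
      tab <- eff_from[[state]]
      u <- stats::runif(1)
      cum <- cumsum(tab$delta)
      hit <- which(u < cum)
      if (length(hit)) {
        state <- tab$to[hit[1L]]
        remaining <- draw_bout_epochs(state)
        jumped <- TRUE
      }
    }
    if (!jumped) {
      remaining <- remaining - 1L
      if (remaining <= 0L) {
        state <- draw_next(state)
        remaining <- draw_bout_epochs(state)
      }
    }
  }
  labels
}
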