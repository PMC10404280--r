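#' Build laser-aligned trials from a hypnogram
#'
#' Cuts a recording into trials aligned to laser-train onsets on a 60-s bin
#' grid. Each bin is labeled by the majority state of its constituent 5-s
#' epochs (epoch starts falling inside the bin); ties go to the state of the
#' earliest epoch in the bin. Bin 0 starts at train onset; pre-stimulation
#' bins carry negative indices. Trials whose windows overlap the recording
#' edge are dropped with a message; trials overlapping a previous trial's
#' window are dropped with a warning.
#'
#' @param hyp A [hypnogram()] for one animal.
#' @param laser A [laser_protocol()] with at least one train.
#' @param pre_s Window before train onset, seconds (multiple of `bin_s`).
#' @param post_s Window after train onset, seconds (multiple of `bin_s`);
#'   includes the stimulation period itself.
#' @param bin_s Bin width, seconds (default 60).
#' @param mouse Animal identifier attached to every trial.
#' @return A tibble of class `trial_set`: `mouse`, `trial`, `bin`,
#'   `t_rel_s`, `state`; attributes `bin_s`, `n_laser_bins` (bins covered by
#'   the train) and `bins` (the common bin grid).
#' @export
build_trials <- function(hyp, laser, pre_s, post_s, bin_s = 60,
                         mouse = "m1") {
  if (is.null(laser) || nrow(laser$train_bounds) == 0L) {
    stop("laser protocol has no trains")
  }
  eps <- hyp_epoch_s(hyp)
  if (abs(bin_s / eps - round(bin_s / eps)) > 1e-9) {
    stop("bin_s must be an integer number of epochs")
  }
  if (abs(pre_s %% bin_s) > 1e-9 || abs(post_s %% bin_s) > 1e-9) {
    stop("pre_s and post_s must be multiples of bin_s")
  }
  onsets <- laser$train_bounds$start
  dur <- laser$train_bounds$end - laser$train_bounds$start
  n_laser_bins <- max(1L, as.integer(ceiling(max(dur) / bin_s - 1e-9)))
  bins <- seq.int(-pre_s / bin_s, post_s / bin_s - 1L)
  span <- c(hyp_t0_s(hyp), hyp_t0_s(hyp) + nrow(hyp) * eps)

  inside <- onsets - pre_s >= span[1] - 1e-9 &
    onsets + post_s <= span[2] + 1e-9
  if (any(!inside)) {
    message(sum(!inside), " train(s) with windows outside the recording dropped")
  }
  onsets <- onsets[inside]
  if (length(onsets) > 1L) {
    keep <- c(TRUE, diff(onsets) >= pre_s + post_s - 1e-9)
    if (any(!keep)) {
      warning(sum(!keep), " train(s) overlapping the previous trial window dropped")
      onsets <- onsets[keep]
    }
  }
  if (length(onsets) == 0L) stop("no usable trains after window filtering")

  states <- as.character(hyp$state)
  trials <- purrr::imap_dfr(onsets, function(o, k) {
    lab <- vapply(bins, function(b) {
      lo <- o + b * bin_s
      sel <- which(hyp$t_start_s >= lo - 1e-9 &
                     hyp$t_start_s < lo + bin_s - 1e-9)
      majority_state(states[sel])
    }, character(1))
    tibble(
      mouse = mouse, trial = k, bin = bins, t_rel_s = bins * bin_s,
      state = factor(lab, levels = BRAIN_STATES)
    )
  })
  attr(trials, "bin_s") <- bin_s
  attr(trials, "n_laser_bins") <- n_laser_bins
  attr(trials, "bins") <- bins
  class(trials) <- c("trial_set", class(trials))
  trials
}

## Majority vote; ties resolved by the state of the earliest epoch in the
## bin among the tied states.
majority_state <- function(s) {
  if (length(s) == 0L) return(NA_character_)
  counts <- table(factor(s, levels = BRAIN_STATES))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  s[s %in% top][1L]
}

#' Combine per-mouse trial sets
#'
#' @param trial_sets A list of [build_trials()] results (one per mouse);
#'   names, when given, override the `mouse` column.
#' @return A single `trial_set` tibble on the shared bin grid.
#' @export
bind_trial_sets <- function(trial_sets) {
  stopifnot(length(trial_sets) >= 1L)
  a1 <- attributes(trial_sets[[1]])
  for (ts in trial_sets[-1]) {
    if (!identical(attr(ts, "bins"), a1$bins) ||
        !identical(attr(ts, "bin_s"), a1$bin_s)) {
      stop("all trial sets must share the same bin grid and alignment")
    }
  }
  nm <- names(trial_sets)
  out <- purrr::map_dfr(seq_along(trial_sets), function(i) {
    ts <- as_tibble(trial_sets[[i]])
    if (!is.null(nm) && nzchar(nm[i])) ts$mouse <- nm[i]
    ts
  })
  attr(out, "bin_s") <- a1$bin_s
  attr(out, "n_laser_bins") <- a1$n_laser_bins
  attr(out, "bins") <- a1$bins
  class(out) <- c("trial_set", class(out))
  out
}

#' Brain-state transition probabilities on the bin grid
#'
#' For every ordered state pair `(X, Y)` and bin `i`: among the `n` trials
#' in state `X` at bin `i - 1`, the `m` trials that are in state `Y` at bin
#' `i` define the transition probability `p = m / n` (NA where `n = 0`).
#' Trials are pooled across mice.
#'
#' @param trials A `trial_set`.
#' @return A tibble: `from`, `to`, `bin`, `m`, `n`, `p`.
#' @export
transition_probabilities <- function(trials) {
  bins <- sort(unique(trials$bin))
  if (nrow(trials) == 0L) stop("empty trial set")
  wide <- tidyr::pivot_wider(
    mutate(trials, key = paste(.data$mouse, .data$trial)),
    id_cols = "key", names_from = "bin", values_from = "state"
  )
  S <- as.matrix(wide[, as.character(bins)])
  out <- purrr::map_dfr(seq_along(bins)[-1], function(j) {
    prev <- S[, j - 1L]
    cur <- S[, j]
    purrr::map_dfr(BRAIN_STATES, function(x) {
      n <- sum(prev == x, na.rm = TRUE)
      purrr::map_dfr(BRAIN_STATES, function(y) {
        m <- sum(prev == x & cur == y, na.rm = TRUE)
        tibble(
          from = x, to = y, bin = bins[j], m = m, n = n,
          p = if (n > 0) m / n else NA_real_
        )
      })
    })
  })
  out
}

#' Percent time in each state per bin
#'
#' @param trials A `trial_set`.
#' @return A tibble `bin`, `state`, `pct` (per-bin percentages sum to 100).
#' @export
occupancy_timecourse <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial set")
  trials |>
    group_by(.data$bin, state = factor(.data$state, levels = BRAIN_STATES)) |>
    summarise(k = dplyr::n(), .groups = "drop_last") |>
    mutate(pct = 100 * .data$k / sum(.data$k)) |>
    ungroup() |>
    tidyr::complete(
      bin = unique(trials$bin),
      state = factor(BRAIN_STATES, levels = BRAIN_STATES),
      fill = list(k = 0L, pct = 0)
    ) |>
    select("bin", "state", "pct") |>
    arrange(.data$bin, .data$state)
}

## ---- hierarchical bootstrap internals --------------------------------

## trials -> list of per-mouse state matrices (trial x bin, integer codes)
trial_matrices <- function(trials) {
  bins <- sort(unique(trials$bin))
  split(as_tibble(trials), trials$mouse) |>
    lapply(function(df) {
      wide <- tidyr::pivot_wider(df, id_cols = "trial", names_from = "bin",
                                 values_from = "state")
      m <- as.matrix(wide[, as.character(bins)])
      matrix(match(m, BRAIN_STATES), nrow = nrow(m),
             dimnames = list(NULL, as.character(bins)))
    })
}

## n_boot x m count matrix of with-replacement resamples of m trials
resample_counts <- function(m, n_boot) {
  C <- matrix(0L, n_boot, m)
  for (j in seq_len(m)) {
    idx <- sample.int(m, n_boot, replace = TRUE)
    C[cbind(seq_len(n_boot), idx)] <- C[cbind(seq_len(n_boot), idx)] + 1L
  }
  C
}

#' Hierarchical bootstrap confidence intervals
#'
#' Two-level bootstrap respecting the nesting of trials within mice: each
#' iteration redraws, for every mouse `i`, `m_i` of its trials with
#' replacement, recomputes the statistic per mouse (occupancy fraction, or
#' transition probability pooled over the mouse's trials), and averages the
#' per-mouse values across mice with equal weights. Percentile confidence
#' intervals are taken from the `n_boot` resampled means. Point estimates
#' use the same across-mouse mean on the original trials.
#'
#' @param trials A `trial_set` (>= 2 mice recommended; a single mouse is
#'   allowed with a warning).
#' @param statistic `"occupancy"` (per bin and state), `"transition"`
#'   (per ordered state pair and bin), or `"occupancy_mean"` (per state,
#'   each trial's occupancy averaged over all its bins — one value per
#'   state).
#' @param n_boot Bootstrap iterations (default 10000; < 100 warns).
#' @param seed Integer seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return A tibble of class `transition_boot` with `point`, `lo`, `hi` per
#'   bin and state (or state pair), a `ci_ordered` flag (percentile CIs of
#'   sparse ratios need not bracket the point estimate), and attributes
#'   `n_boot`, `conf`, `statistic`, `n_mice`.
#' @export
bootstrap_ci <- function(trials,
                         statistic = c("occupancy", "transition",
                                       "occupancy_mean"),
                         n_boot = 10000, seed = 1, conf = 0.95) {
  statistic <- match.arg(statistic)
  if (n_boot < 100) warning("n_boot < 100 gives unstable percentile CIs")
  mats <- trial_matrices(trials)
  if (length(mats) < 2L) {
    warning("single-mouse trial set: the bootstrap captures only ",
            "within-mouse trial variability")
  }
  bins <- sort(unique(trials$bin))
  alpha <- (1 - conf) / 2

  per_mouse <- function(M, C) { # C: n_iter x n_trials counts
    if (statistic == "occupancy") {
      vals <- lapply(seq_along(BRAIN_STATES), function(s) {
        (C %*% (M == s)) / rowSums(C)
      })
      do.call(cbind, vals) # n_iter x (bins * 3 states)
    } else if (statistic == "occupancy_mean") {
      vals <- lapply(seq_along(BRAIN_STATES), function(s) {
        (C %*% rowMeans(M == s)) / rowSums(C)
      })
      do.call(cbind, vals) # n_iter x 3 states
    } else {
      nb <- ncol(M)
      num <- NULL
      den <- NULL
      for (x in seq_along(BRAIN_STATES)) {
        prev <- (M[, -nb, drop = FALSE] == x) * 1L
        dx <- C %*% prev
        for (y in seq_along(BRAIN_STATES)) {
          tr <- prev * (M[, -1, drop = FALSE] == y)
          num <- cbind(num, C %*% tr)
          den <- cbind(den, dx)
        }
      }
      out <- num / den
      out[den == 0] <- NA_real_
      out # n_iter x (3 from x 3 to x (bins - 1)) -- column blocks by (x, y)
    }
  }

  combine <- function(Cs) { # list over mice of n_iter x K -> mean across mice
    arr <- simplify2array(Cs) # n_iter x K x mice
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  }

  point_rows <- lapply(mats, function(M) {
    per_mouse(M, matrix(1L, 1L, nrow(M)))
  })
  point <- as.numeric(combine(point_rows))

  boot <- withr::with_seed(seed, {
    rows <- lapply(mats, function(M) per_mouse(M, resample_counts(nrow(M), n_boot)))
    combine(rows)
  })
  lo <- apply(boot, 2, stats::quantile, probs = alpha, na.rm = TRUE,
              names = FALSE)
  hi <- apply(boot, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE,
              names = FALSE)

  out <- if (statistic == "occupancy") {
    tidyr::expand_grid(
      state = factor(BRAIN_STATES, levels = BRAIN_STATES), bin = bins
    )[, c("state", "bin")] |> arrange(.data$state, .data$bin)
  } else if (statistic == "occupancy_mean") {
    tibble(state = factor(BRAIN_STATES, levels = BRAIN_STATES),
           bin = NA_integer_)
  } else {
    tidyr::expand_grid(from = BRAIN_STATES, to = BRAIN_STATES,
                       bin = bins[-1])
  }
  out$point <- point
  out$lo <- lo
  out$hi <- hi
  out$ci_ordered <- !is.na(out$point) & !is.na(out$lo) & !is.na(out$hi) &
    out$lo <= out$point & out$point <= out$hi
  attr(out, "n_boot") <- n_boot
  attr(out, "conf") <- conf
  attr(out, "statistic") <- statistic
  attr(out, "n_mice") <- length(mats)
  class(out) <- c("transition_boot", class(out))
  out
}

#' Bootstrap test of a laser effect on brain states
#'
#' Tests whether laser stimulation changes a state's occupancy (give
#' `state`) or a transition probability (give `from` and `to`). Each
#' bootstrap iteration resamples trials within every mouse, computes the
#' mean statistic during the stimulation bins and during the immediately
#' preceding period of identical duration, and records the difference
#' (laser minus pre). The two-sided p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` with add-one smoothing; the effect
#' is significant when the percentile CI of the difference excludes zero.
#'
#' @param trials A `trial_set` whose pre-window covers at least the
#'   stimulation duration (one extra bin for transition statistics, whose
#'   bins condition on the preceding bin).
#' @param state Brain state for an occupancy test (exclusive with
#'   `from`/`to`).
#' @param from,to Ordered state pair for a transition-probability test.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level for the difference CI (default 0.95).
#' @return A one-row tibble of class `laser_effect`: `target`, `diff`
#'   (laser minus pre, point estimate), `lo`, `hi`, `p_value`,
#'   `significant`, `n_boot`.
#' @export
laser_effect_test <- function(trials, state = NULL, from = NULL, to = NULL,
                              n_boot = 10000, seed = 1, conf = 0.95) {
  occ <- !is.null(state)
  if (occ == (!is.null(from) || !is.null(to))) {
    stop("give either `state` (occupancy) or `from` and `to` (transition)")
  }
  k <- attr(trials, "n_laser_bins")
  if (is.null(k)) stop("trial set lacks the n_laser_bins attribute")
  bins <- sort(unique(trials$bin))
  laser_bins <- 0:(k - 1L)
  pre_bins <- (-k):(-1L)
  need <- if (occ) pre_bins else c(min(pre_bins) - 1L, pre_bins)
  if (!all(need %in% bins)) {
    stop("pre-stimulation window shorter than the stimulation period; ",
         "rebuild trials with a larger pre_s")
  }
  mats <- trial_matrices(trials)

  ## per-trial sufficient statistics for (laser, pre)
  suff <- lapply(mats, function(M) {
    bj <- as.integer(colnames(M))
    if (occ) {
      s <- match(state, BRAIN_STATES)
      cbind(
        laser = rowMeans(M[, bj %in% laser_bins, drop = FALSE] == s),
        pre = rowMeans(M[, bj %in% pre_bins, drop = FALSE] == s)
      )
    } else {
      x <- match(from, BRAIN_STATES)
      y <- match(to, BRAIN_STATES)
      count_pair <- function(target_bins) {
        jj <- which(bj %in% target_bins)
        prev <- M[, jj - 1L, drop = FALSE] == x
        tr <- prev & (M[, jj, drop = FALSE] == y)
        cbind(m = rowSums(tr), n = rowSums(prev))
      }
      cbind(laser = count_pair(laser_bins), pre = count_pair(pre_bins))
    }
  })

  mouse_diff <- function(S, C) { # C: n_iter x trials
    if (occ) {
      (C %*% S[, "laser"] - C %*% S[, "pre"]) / rowSums(C)
    } else {
      pl <- (C %*% S[, 1]) / (C %*% S[, 2])
      pp <- (C %*% S[, 3]) / (C %*% S[, 4])
      d <- pl - pp
      d[!is.finite(d)] <- NA_real_
      d
    }
  }

  point <- mean(vapply(suff, function(S) {
    mouse_diff(S, matrix(1L, 1L, nrow(S)))[1, 1]
  }, numeric(1)), na.rm = TRUE)

  d_boot <- withr::with_seed(seed, {
    per <- lapply(suff, function(S) mouse_diff(S, resample_counts(nrow(S), n_boot)))
    rowMeans(do.call(cbind, per), na.rm = TRUE)
  })
  d_boot <- d_boot[is.finite(d_boot)]
  B <- length(d_boot)
  alpha <- (1 - conf) / 2
  lo <- stats::quantile(d_boot, alpha, names = FALSE)
  hi <- stats::quantile(d_boot, 1 - alpha, names = FALSE)
  p <- min(1, 2 * min((1 + sum(d_boot <= 0)) / (B + 1),
                      (1 + sum(d_boot >= 0)) / (B + 1)))
  out <- tibble(
    target = if (occ) state else paste0(from, "->", to),
    diff = point, lo = lo, hi = hi, p_value = p,
    significant = lo > 0 | hi < 0, n_boot = n_boot
  )
  class(out) <- c("laser_effect", class(out))
  out
}
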