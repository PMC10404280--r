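#' Standard mouse von Frey filament series
#'
#' The calibrated 0.008--2 g filament forces commonly used for mouse
#' mechanical-threshold testing.
#'
#' @return Ascending numeric vector of filament forces in grams.
#' @export
vonfrey_set_mouse <- function() {
  c(0.008, 0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0)
}

#' Up-down von Frey testing session
#'
#' Records an ordered sequence of (filament, response) pairs produced by the
#' up-down method: testing starts at `start_g` (0.16 g by default), steps
#' down one filament after a withdrawal (positive response) and up one after
#' no withdrawal, and terminates four responses after the first change in
#' response direction. Sessions that run off the top (all-negative) or
#' bottom (all-positive) of the filament set before any direction change
#' terminate at the boundary and are flagged.
#'
#' @param filament_g Numeric vector of tested filament forces, grams, in
#'   test order.
#' @param withdrew Logical vector of responses (TRUE = paw withdrawal).
#' @param filament_set Ascending filament series; every tested filament must
#'   belong to it.
#' @param start_g Starting filament (default 0.16 g).
#' @param validate Check that the sequence obeys the up-down rule.
#' @return A tibble of class `updown_session` with columns `trial`,
#'   `filament_g`, `withdrew`.
#' @examples
#' s <- updown_session(c(0.16, 0.4, 0.16, 0.07, 0.16, 0.07),
#'                     c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
#' pwt_50(s)
#' @export
updown_session <- function(filament_g, withdrew,
                           filament_set = vonfrey_set_mouse(),
                           start_g = 0.16, validate = TRUE) {
  if (length(filament_set) == 0L) stop("filament_set must be non-empty")
  if (is.unsorted(filament_set, strictly = TRUE)) {
    stop("filament_set must be sorted ascending")
  }
  if (length(filament_g) != length(withdrew)) {
    stop("filament_g and withdrew must have equal length")
  }
  idx <- match_filament(filament_g, filament_set)
  if (anyNA(idx)) {
    stop("tested filament not in filament_set: ",
         filament_g[which(is.na(idx))[1]])
  }
  out <- tibble(
    trial = seq_along(filament_g),
    filament_g = filament_set[idx],
    withdrew = as.logical(withdrew)
  )
  attr(out, "filament_set") <- filament_set
  attr(out, "start_g") <- start_g
  class(out) <- c("updown_session", class(out))
  if (validate && nrow(out) > 1L) {
    for (i in seq_len(nrow(out) - 1L)) {
      step <- if (out$withdrew[i]) -1L else 1L
      expect_idx <- min(max(idx[i] + step, 1L), length(filament_set))
      if (idx[i + 1L] != expect_idx) {
        stop(sprintf(
          "response sequence violates the up-down rule at trial %d: after a %s response at %g g the next filament must be %g g, not %g g",
          i, if (out$withdrew[i]) "positive" else "negative",
          out$filament_g[i], filament_set[expect_idx], out$filament_g[i + 1L]
        ))
      }
    }
  }
  out
}

## Tolerant match of forces against the set (filament forces are nominal).
match_filament <- function(g, set) {
  vapply(g, function(x) {
    d <- abs(set - x)
    i <- which.min(d)
    if (d[i] <= 1e-6 + 1e-3 * set[i]) i else NA_integer_
  }, integer(1))
}

#' Next filament under the up-down rule
#'
#' Given the responses recorded so far, returns the next filament to test,
#' or the termination decision: the session stops four responses after the
#' first change in response direction, or at a boundary of the filament set
#' when all responses so far agree (flagged `"floor"`/`"ceiling"`).
#'
#' @param session An [updown_session()] (possibly with zero rows).
#' @return A list with `action` (`"test"` or `"stop"`), `filament_g` (next
#'   force when testing), and `flag` (`"none"`, `"floor"`, `"ceiling"`).
#' @export
next_filament <- function(session) {
  set <- attr(session, "filament_set")
  start_g <- attr(session, "start_g")
  if (nrow(session) == 0L) {
    i0 <- match_filament(start_g, set)
    if (is.na(i0)) stop("start_g is not in the filament set")
    return(list(action = "test", filament_g = set[i0], flag = "none"))
  }
  r <- session$withdrew
  k <- length(r)
  change_at <- if (k >= 2L) which(r[-1] != r[-k])[1] + 1L else NA_integer_
  if (!is.na(change_at) && k >= change_at + 4L) {
    return(list(action = "stop", filament_g = NA_real_, flag = "none"))
  }
  i <- match_filament(session$filament_g[k], set)
  step <- if (r[k]) -1L else 1L
  nxt <- i + step
  if (nxt < 1L || nxt > length(set)) {
    if (is.na(change_at)) {
      ## monotone run off the end of the set: assign boundary threshold
      return(list(
        action = "stop", filament_g = NA_real_,
        flag = if (nxt < 1L) "floor" else "ceiling"
      ))
    }
    nxt <- min(max(nxt, 1L), length(set)) # saturate, keep testing
  }
  list(action = "test", filament_g = set[nxt], flag = "none")
}

#' 50% paw-withdrawal threshold from an up-down session
#'
#' Computes the 50% mechanical withdrawal threshold in grams as
#' `10^(X_f + kappa * delta) / 10^4`, where `X_f` is the `log10` of the
#' final tested filament force expressed in 10^-4 g units, `delta` is the
#' mean `log10` spacing of the configured filament set, and `kappa` is the
#' pattern correction: the maximum-likelihood location offset of a normal
#' tolerance distribution with SD `delta` fitted to the full response
#' sequence. Boundary (all-positive / all-negative) sessions return the
#' floor or ceiling of the filament set, flagged.
#'
#' @param session A terminated [updown_session()].
#' @param delta Mean `log10` filament spacing; computed from the session's
#'   filament set when `NULL`.
#' @return The threshold in grams, with attributes `x_f`, `kappa`, `delta`
#'   and `flag` (`"none"`, `"floor"`, `"ceiling"`).
#' @export
pwt_50 <- function(session, delta = NULL) {
  stopifnot(inherits(session, "updown_session"))
  if (nrow(session) == 0L) stop("session has no responses")
  set <- attr(session, "filament_set")
  if (is.null(delta)) delta <- mean(diff(log10(set)))
  r <- session$withdrew
  nxt <- next_filament(session)
  if (nxt$flag %in% c("floor", "ceiling") ||
      (all(r) && isTRUE(all.equal(session$filament_g[nrow(session)], set[1]))) ||
      (all(!r) && isTRUE(all.equal(session$filament_g[nrow(session)],
                                   set[length(set)])))) {
    bound <- if (all(r)) set[1] else set[length(set)]
    flag <- if (all(r)) "floor" else "ceiling"
    return(structure(bound, x_f = log10(bound * 1e4), kappa = NA_real_,
                     delta = delta, flag = flag))
  }
  if (length(unique(r)) < 2L) {
    stop("cannot resolve a threshold: response pattern '",
         paste(ifelse(r, "X", "O"), collapse = ""),
         "' has no direction change and did not reach a set boundary")
  }
  x <- log10(session$filament_g * 1e4)
  kappa <- updown_kappa(x, r, delta)
  x_f <- x[length(x)]
  structure(10^(x_f + kappa * delta) / 1e4,
            x_f = x_f, kappa = kappa, delta = delta, flag = "none")
}

#' Pattern correction value for the up-down estimator
#'
#' The correction `kappa` such that the 50% threshold (in log10 stimulus
#' units) is `x_f + kappa * delta`: obtained by maximizing the likelihood of
#' the observed response sequence under a cumulative-normal psychometric
#' function with SD equal to `delta`, the assumption underlying the
#' published small-sample up-down tables.
#'
#' @param levels_log Numeric, `log10` stimulus levels of the tested trials.
#' @param responses Logical responses (TRUE = positive).
#' @param delta Mean `log10` stimulus spacing (also the assumed SD).
#' @return `kappa = (mu_hat - x_f) / delta`.
#' @export
updown_kappa <- function(levels_log, responses, delta) {
  stopifnot(length(levels_log) == length(responses), delta > 0)
  if (length(unique(responses)) < 2L) {
    stop("kappa requires both positive and negative responses")
  }
  nll <- function(mu) {
    p <- stats::pnorm(levels_log, mean = mu, sd = delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(responses, log(p), log1p(-p)))
  }
  rng <- range(levels_log) + c(-5, 5) * delta
  mu_hat <- stats::optimize(nll, interval = rng, tol = 1e-9)$minimum
  (mu_hat - levels_log[length(levels_log)]) / delta
}

#' Paw-withdrawal latency: session mean
#'
#' The thermal withdrawal latency (PWL) is the arithmetic mean of three
#' radiant-heat applications. Fewer than three latencies are averaged with a
#' warning; latencies at or above the hardware cutoff are flagged.
#'
#' @param latencies_s Numeric vector of per-application latencies, seconds.
#' @param cutoff_s Optional cutoff time; trials at/above it are capped.
#' @return Mean latency in seconds with attribute `capped` (logical, TRUE if
#'   any trial hit the cutoff).
#' @examples
#' pwl_mean(c(3, 4, 5))
#' @export
pwl_mean <- function(latencies_s, cutoff_s = NULL) {
  if (any(latencies_s <= 0)) stop("latencies must be positive")
  if (length(latencies_s) != 3L) {
    warning("PWL is defined as the mean of three applications; got ",
            length(latencies_s))
  }
  capped <- FALSE
  if (!is.null(cutoff_s)) {
    capped <- any(latencies_s >= cutoff_s)
    latencies_s <- pmin(latencies_s, cutoff_s)
  }
  structure(mean(latencies_s), capped = capped)
}
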