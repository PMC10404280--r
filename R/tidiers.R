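#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy bootstrap transition results
#'
#' @param x A `transition_boot` from [bootstrap_ci()].
#' @param ... Unused.
#' @return A plain tibble with one row per bin and state (or state pair):
#'   `estimate`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.transition_boot <- function(x, ...) {
  out <- as_tibble(x)
  dplyr::rename(out, estimate = "point", conf.low = "lo", conf.high = "hi")
}

#' @rdname tidy.transition_boot
#' @exportS3Method generics::glance
glance.transition_boot <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic"),
    n_boot = attr(x, "n_boot"),
    conf = attr(x, "conf"),
    n_mice = attr(x, "n_mice")
  )
}

#' Tidy a laser-effect test
#'
#' @param x A `laser_effect` from [laser_effect_test()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.laser_effect <- function(x, ...) {
  tibble(
    term = x$target, estimate = x$diff,
    conf.low = x$lo, conf.high = x$hi, p.value = x$p_value
  )
}

#' Tidy an optotagging report
#'
#' @param x A `tag_report` from [classify_tagged()].
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @exportS3Method generics::tidy
tidy.tag_report <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.tag_report
#' @exportS3Method generics::glance
glance.tag_report <- function(x, ...) {
  tibble(n_units = nrow(x), n_tagged = sum(x$tagged))
}

#' Tidy an up-down session into its threshold estimate
#'
#' @param x An [updown_session()].
#' @param ... Passed to [pwt_50()].
#' @return A one-row tibble: `pwt_g`, `x_f`, `kappa`, `delta`, `flag`,
#'   `n_trials`.
#' @exportS3Method generics::tidy
tidy.updown_session <- function(x, ...) {
  p <- pwt_50(x, ...)
  tibble(
    pwt_g = as.numeric(p), x_f = attr(p, "x_f"), kappa = attr(p, "kappa"),
    delta = attr(p, "delta"), flag = attr(p, "flag"), n_trials = nrow(x)
  )
}
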