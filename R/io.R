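## File contracts: UTF-8 CSV with a header row, '.' decimal separator, all
## times in seconds from recording start, 0-based epoch indices, half-open
## intervals throughout.

#' Read and write hypnogram CSV files
#'
#' Columns: `epoch_index` (0-based), `t_start_s`, `state`.
#'
#' @param path File path.
#' @param hyp A [hypnogram()].
#' @return `read_hypnogram()` returns a [hypnogram()];
#'   `write_hypnogram()` returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "t_start_s", "state")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(df$epoch_index, seq_len(nrow(df)) - 1L)) {
    bad <- which(df$epoch_index != seq_len(nrow(df)) - 1L)[1]
    stop("epoch_index must be contiguous from 0; line ", bad + 1L)
  }
  eps <- if (nrow(df) > 1L) df$t_start_s[2] - df$t_start_s[1] else 5
  hypnogram(df$state, epoch_s = eps, t0_s = df$t_start_s[1])
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(
    data.frame(
      epoch_index = hyp$epoch, t_start_s = hyp$t_start_s,
      state = as.character(hyp$state)
    ),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write spike-time CSV files
#'
#' Columns: `unit_id`, `t_s`; times strictly increasing within each unit.
#'
#' @param path File path.
#' @param spikes Tibble with `unit_id`, `t_s`.
#' @return `read_spikes()` returns a tibble (`unit_id`, `t_s`).
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "t_s") %in% names(df))) {
    stop("spikes CSV must have columns: unit_id, t_s")
  }
  for (u in unique(df$unit_id)) {
    tt <- df$t_s[df$unit_id == u]
    if (is.unsorted(tt, strictly = TRUE)) {
      row <- which(df$unit_id == u)[which(diff(tt) <= 0)[1] + 1L]
      stop("spike times not strictly increasing for unit ", u,
           " at line ", row + 1L)
    }
  }
  as_tibble(df)
}

#' @rdname read_spikes
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("unit_id", "t_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write laser-protocol CSV files
#'
#' Columns: `train_id`, `pulse_t_s`, `pulse_width_s`.
#'
#' @param path File path.
#' @param laser A [laser_protocol()].
#' @return `read_laser()` returns a [laser_protocol()].
#' @export
read_laser <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("train_id", "pulse_t_s", "pulse_width_s")
  if (!all(need %in% names(df))) {
    stop("laser CSV must have columns: ", paste(need, collapse = ", "))
  }
  w <- unique(df$pulse_width_s)
  if (length(w) != 1L) stop("pulse_width_s must be constant")
  bounds <- df |>
    group_by(.data$train_id) |>
    summarise(start = min(.data$pulse_t_s),
              end = max(.data$pulse_t_s) + w, .groups = "drop")
  laser_protocol(df$pulse_t_s, w, bounds[, c("start", "end")])
}

#' @rdname read_laser
#' @export
write_laser <- function(laser, path) {
  train_id <- findInterval(laser$pulse_t_s, laser$train_bounds$start)
  utils::write.csv(
    data.frame(
      train_id = train_id, pulse_t_s = laser$pulse_t_s,
      pulse_width_s = laser$pulse_width_s
    ),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write EEG/EMG signal files
#'
#' Plain-text signal container: a CSV with `eeg` and `emg` columns plus a
#' JSON sidecar (`<path>.json`) recording the sampling rate.
#'
#' @param path CSV file path.
#' @param signals List with `eeg`, `emg`, `fs` (as from
#'   [simulate_eeg_emg()]).
#' @param expect_fs Optional required sampling rate; on mismatch the reader
#'   fails (no silent resampling).
#' @return `read_signals()` returns a list with `eeg`, `emg`, `fs`.
#' @export
read_signals <- function(path, expect_fs = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expect_fs) && !isTRUE(all.equal(meta$fs, expect_fs))) {
    stop("sampling rate mismatch: file has fs = ", meta$fs,
         " Hz, expected ", expect_fs, " Hz")
  }
  df <- utils::read.csv(path)
  list(eeg = df$eeg, emg = df$emg, fs = meta$fs)
}

#' @rdname read_signals
#' @export
write_signals <- function(signals, path) {
  utils::write.csv(
    data.frame(eeg = signals$eeg, emg = signals$emg),
    path, row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(list(fs = signals$fs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read and write up-down response CSV files
#'
#' Columns: `animal_id`, `trial_index` (1-based), `filament_g`, `withdrew`
#' (0/1).
#'
#' @param path File path.
#' @param sessions Named list of [updown_session()] objects (names =
#'   animal ids).
#' @param filament_set Filament series used to validate the sequences.
#' @return `read_updown()` returns a named list of [updown_session()]s.
#' @export
read_updown <- function(path, filament_set = vonfrey_set_mouse()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "trial_index", "filament_g", "withdrew")
  if (!all(need %in% names(df))) {
    stop("up-down CSV must have columns: ", paste(need, collapse = ", "))
  }
  split(df, df$animal_id) |>
    lapply(function(d) {
      d <- d[order(d$trial_index), ]
      updown_session(d$filament_g, as.logical(d$withdrew), filament_set)
    })
}

#' @rdname read_updown
#' @export
write_updown <- function(sessions, path) {
  df <- purrr::imap_dfr(sessions, function(s, id) {
    tibble(animal_id = id, trial_index = s$trial,
           filament_g = s$filament_g, withdrew = as.integer(s$withdrew))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
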