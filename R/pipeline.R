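#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end chain on a simulated recording: synthesis
#' (hypnogram, EEG/EMG, laser protocol, spike trains, up-down session) ->
#' sleep staging -> optotagging -> state-dependent firing -> transition
#' bootstrap -> behavioral endpoints. Every stage's output is written to
#' `out_dir` in the package's text formats, and a JSON manifest records the
#' configuration, seed, package version and per-file MD5 checksums, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   `seed` (required), and optionally `duration_s`, `epoch_s`, `eeg_fs`,
#'   `tag_train_onsets_s`, `effect_train_onsets_s`, `pre_s`, `post_s`,
#'   `bin_s`, `n_boot` — plus any [sim_config()] argument under `sim`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfgv <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_args <- c(
    list(
      seed = cfgv$seed, duration_s = cfgv$duration_s,
      epoch_s = cfgv$epoch_s, eeg_fs = cfgv$eeg_fs
    ),
    cfgv$sim
  )
  cfg <- do.call(sim_config, sim_args)

  ## --- synth ---------------------------------------------------------
  res <- stage("synth", function() {
    tag_laser <- laser_trains(cfgv$tag_train_onsets_s, n_pulses = 10,
                              freq_hz = 10, label = "473nm tagging")
    eff_laser <- laser_protocol(
      pulse_t_s = cfgv$effect_train_onsets_s,
      pulse_width_s = cfgv$laser_duration_s,
      train_bounds = tibble(
        start = cfgv$effect_train_onsets_s,
        end = cfgv$effect_train_onsets_s + cfgv$laser_duration_s
      ),
      label = "effect trains"
    )
    hyp <- simulate_hypnogram(cfg, laser = eff_laser)
    sig <- simulate_eeg_emg(hyp, cfg)
    spk <- simulate_spikes(hyp, laser = tag_laser, cfg = cfg)
    ud <- simulate_updown_responses(cfg)
    outputs["hypnogram_true.csv"] <<-
      write_hypnogram(hyp, file.path(out_dir, "hypnogram_true.csv"))
    outputs["signals.csv"] <<-
      write_signals(sig, file.path(out_dir, "signals.csv"))
    outputs["spikes.csv"] <<-
      write_spikes(spk, file.path(out_dir, "spikes.csv"))
    outputs["laser_tag.csv"] <<-
      write_laser(tag_laser, file.path(out_dir, "laser_tag.csv"))
    outputs["updown.csv"] <<-
      write_updown(list(sim = ud), file.path(out_dir, "updown.csv"))
    list(hyp = hyp, sig = sig, spk = spk, ud = ud,
         tag_laser = tag_laser, eff_laser = eff_laser)
  })

  ## --- staging -------------------------------------------------------
  hyp_est <- stage("staging", function() {
    feats <- compute_epoch_features(res$sig$eeg, res$sig$emg, res$sig$fs,
                                    cfgv$epoch_s)
    params <- calibrate_thresholds(feats)
    hyp_est <- stage_epochs(feats, params)
    outputs["hypnogram_staged.csv"] <<-
      write_hypnogram(hyp_est, file.path(out_dir, "hypnogram_staged.csv"))
    hyp_est
  })

  ## --- units ---------------------------------------------------------
  tags <- stage("units", function() {
    st <- res$spk |>
      dplyr::group_split(.data$unit_id) |>
      purrr::map_dfr(function(df) {
        s <- evoked_spike_stats(df$t_s, res$tag_laser)
        s$unit_id <- df$unit_id[1]
        s$refractory_violation_frac <- refractory_violation_fraction(df$t_s)
        s
      })
    tags <- suppressWarnings(classify_tagged(st))
    utils::write.table(tags, file.path(out_dir, "tag_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs["tag_report.tsv"] <<- file.path(out_dir, "tag_report.tsv")
    tags
  })

  ## --- statefiring ---------------------------------------------------
  firing <- stage("statefiring", function() {
    firing <- res$spk |>
      dplyr::group_split(.data$unit_id) |>
      purrr::map_dfr(function(df) {
        r <- state_rates(df$t_s, hyp_est, laser = res$tag_laser)
        mutate(dplyr::bind_cols(tibble(unit_id = df$unit_id[1]),
                                modulation_indices(r)),
               wake_rate_hz = r$rate_hz[r$state == "Wake"],
               nrem_rate_hz = r$rate_hz[r$state == "NREM"],
               rem_rate_hz = r$rate_hz[r$state == "REM"])
      })
    utils::write.table(firing, file.path(out_dir, "state_firing.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs["state_firing.tsv"] <<- file.path(out_dir, "state_firing.tsv")
    firing
  })

  ## --- transitions ---------------------------------------------------
  boot <- stage("transitions", function() {
    trials <- build_trials(res$hyp, res$eff_laser, pre_s = cfgv$pre_s,
                           post_s = cfgv$post_s, bin_s = cfgv$bin_s)
    boot <- bootstrap_ci(trials, "occupancy", n_boot = cfgv$n_boot,
                         seed = cfgv$seed)
    effects <- purrr::map_dfr(BRAIN_STATES, function(s) {
      laser_effect_test(trials, state = s, n_boot = cfgv$n_boot,
                        seed = cfgv$seed)
    })
    utils::write.table(boot, file.path(out_dir, "occupancy_ci.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(effects, file.path(out_dir, "laser_effects.json"),
                         digits = NA)
    outputs["occupancy_ci.tsv"] <<- file.path(out_dir, "occupancy_ci.tsv")
    outputs["laser_effects.json"] <<- file.path(out_dir, "laser_effects.json")
    boot
  })

  ## --- behavior ------------------------------------------------------
  stage("behavior", function() {
    pwt <- pwt_50(res$ud)
    beh <- tibble(
      animal_id = "sim", pwt_g = as.numeric(pwt),
      pwt_flag = attr(pwt, "flag")
    )
    utils::write.table(beh, file.path(out_dir, "behavior.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs["behavior.tsv"] <<- file.path(out_dir, "behavior.tsv")
    beh
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("somnotag")),
    r_version = R.version.string,
    seed = cfgv$seed,
    config = cfgv,
    outputs = as.list(tools::md5sum(unlist(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## Fill defaults and fail early on inconsistent requests.
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config$seed is mandatory")
  d <- list(
    seed = as.integer(config$seed),
    duration_s = config$duration_s %||% 3600,
    epoch_s = config$epoch_s %||% 5,
    eeg_fs = config$eeg_fs %||% 1500,
    tag_train_onsets_s = config$tag_train_onsets_s %||% seq(10, 3500, by = 90),
    effect_train_onsets_s = config$effect_train_onsets_s %||% c(900, 2400),
    laser_duration_s = config$laser_duration_s %||% 120,
    pre_s = config$pre_s %||% 240,
    post_s = config$post_s %||% 360,
    bin_s = config$bin_s %||% 60,
    n_boot = config$n_boot %||% 1000,
    sim = config$sim %||% list()
  )
  known <- c(names(d), "sim")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
  if (d$pre_s < d$laser_duration_s + d$bin_s) {
    stop("pre_s must cover the laser duration plus one bin for transition tests")
  }
  if (max(d$tag_train_onsets_s) > d$duration_s ||
      max(d$effect_train_onsets_s) + d$post_s > d$duration_s) {
    stop("stimulation trains extend past the recording duration")
  }
  d
}
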