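#' Run the full analysis pipeline
#'
#' Composes every stage into one reproducible run: (1) render the stimulus
#' loop and write it as WAV; (2) run the oscillator model and write the mean
#' periodicity profile, peak list and salience series; (3) convolve salience
#' with the pupillary response function and write the predicted pupil and its
#' spectrum; (4) schedule deviants and simulate the ZEST adaptive experiment,
#' writing the trial table and threshold summary; (5) synthesize a raw pupil
#' log; (6) preprocess it and extract pupil-dilation-response features;
#' (7) compute the true and null peak-band coherence summary. A
#' machine-readable `manifest.json` records the config hash, seed, and every
#' stage output, so a run can be regenerated from the manifest alone.
#'
#' @param config Configuration list (see [default_config()]); unknown keys
#'   are an error.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `config_hash`, `seed`,
#'   `outputs`).
#' @export
run_full_pipeline <- function(config = default_config(), out_dir) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L) {
    abort(sprintf("Unknown config keys: %s.", paste(extra, collapse = ", ")))
  }
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("Output directory is not writable.")
  hash <- rlang::hash(config)
  seed <- as.integer(config$seed)
  path <- function(f) file.path(out_dir, f)
  outputs <- list()

  inform("stage 1/7: rendering stimulus")
  pattern <- make_pattern(config$pattern$preset,
    n_positions = config$pattern$n_positions,
    tempo_bpm = config$pattern$tempo_bpm,
    beats_per_loop = config$pattern$beats_per_loop
  )
  audio <- render_loop(pattern, sample_rate = config$audio$sample_rate,
    seed = seed)
  write_wav(audio, path("stimulus.wav"))
  outputs$stimulus <- "stimulus.wav"

  inform("stage 2/7: oscillator model")
  model <- oscillator_model(pattern,
    loops = config$model$loops,
    sample_rate = config$audio$sample_rate,
    window_s = config$model$window_s, hop_s = config$model$hop_s,
    seed = seed
  )
  write_table_with_header(as_tibble(model$mpp), path("mpp.csv"), hash, seed)
  write_table_with_header(as_tibble(model$salience), path("salience.csv"),
    hash, seed)
  outputs$mpp <- "mpp.csv"
  outputs$salience <- "salience.csv"

  inform("stage 3/7: pupil forward model")
  prf <- prf_kernel(n = config$prf$n, t_max_ms = config$prf$t_max_ms)
  pred <- predict_pupil(model$salience, prf,
    n_loops = max(config$pupil$n_loops, 8L))
  write_table_with_header(as_tibble(pred), path("predicted_pupil.csv"),
    hash, seed)
  write_table_with_header(prediction_spectrum(pred),
    path("prediction_psd.csv"), hash, seed)
  outputs$predicted_pupil <- "predicted_pupil.csv"

  inform("stage 4/7: adaptive experiment simulation")
  schedule <- schedule_run(
    config$schedule$n_observations_per_position,
    config$schedule$p_deviant,
    config$probe_positions,
    seed = seed,
    max_loops = 2000L
  )
  observer <- psychometric_observer(
    true_threshold_db = config$observer$true_threshold_db,
    slope_db = config$observer$slope_db,
    lapse_rate = config$observer$lapse_rate,
    false_alarm_rate = config$observer$false_alarm_rate
  )
  zgrid <- seq(config$zest$grid_min, config$zest$grid_max,
    by = config$zest$grid_step)
  expt <- run_experiment(schedule, observer,
    prior_mean_db = config$zest$prior_mean_db,
    prior_sd_db = config$zest$prior_sd_db, grid = zgrid,
    sigma_db = config$zest$sigma_db, gamma = config$zest$gamma,
    lambda = config$zest$lambda,
    response_window_ms = config$zest$response_window_ms,
    quota = config$schedule$n_observations_per_position,
    seed = seed + 1L
  )
  write_schedule(schedule, path("schedule.csv"), hash)
  write_table_with_header(expt$trials, path("trials.csv"), hash, seed)
  write_table_with_header(expt$thresholds, path("thresholds.csv"), hash, seed)
  outputs$trials <- "trials.csv"
  outputs$thresholds <- "thresholds.csv"
  inform(sprintf(
    "  %d loops, %d deviant trials, %d thresholds estimated",
    nrow(expt$trials), sum(expt$trials$trial_kind == "deviant"),
    sum(!is.na(expt$thresholds$threshold_db))
  ))

  inform("stage 5/7: synthetic pupil log")
  log <- synth_pupil(model$salience, prf,
    n_loops = config$pupil$n_loops,
    noise_sd = config$pupil$noise_sd,
    blink_rate_hz = config$pupil$blink_rate_hz,
    drift_amplitude = config$pupil$drift_amplitude,
    seed = seed + 2L
  )
  write_pupil_log(log, path("pupil_raw.tsv"), hash, seed + 2L)
  outputs$pupil_raw <- "pupil_raw.tsv"

  inform("stage 6/7: preprocessing and PDR features")
  masked <- mark_artifacts(log,
    jump_threshold = config$preprocess$jump_threshold,
    pad_samples = config$preprocess$pad_samples
  )
  clean <- interpolate_and_screen(masked, config$preprocess$max_fraction)
  if (!trace_accepted(clean)) {
    abort("Synthetic run exceeded the interpolation budget.", class = "pupilbeat_rejection")
  }
  clean <- highpass_and_zscore(clean, config$preprocess$highpass_hz)
  inform(sprintf("  %.2f%% of samples interpolated",
    100 * attr(clean, "fraction_interpolated")))
  loop_ms <- attr(log, "loop_duration_s") * 1000
  log_rate <- attr(clean, "sample_rate_hz") %||% 500
  n_events <- max(floor(nrow(clean) / log_rate * 1000 / loop_ms) - 3L, 1L)
  events <- tibble(
    time_ms = loop_ms * seq(1L, n_events),
    trial_kind = "loop_onset"
  )
  pdr <- epoch_pdr(clean, events)
  write_table_with_header(pdr$features, path("pdr_features.csv"), hash, seed)
  outputs$pdr_features <- "pdr_features.csv"

  inform("stage 7/7: entrainment summary")
  pupil100 <- resample_signal(clean$pupil, attr(clean, "sample_rate_hz"), 100)
  pred_v <- pred$prediction[seq_len(min(nrow(pred), length(pupil100)))]
  pupil_v <- pupil100[seq_along(pred_v)]
  coh <- coherence(pupil_v, pred_v, 100,
    window_s = config$coherence$window_s, overlap = config$coherence$overlap)
  true_coh <- peak_band_coherence(coh, model$mpp, config$coherence$fmax_hz)
  summary_tbl <- tibble(
    stimulus = pattern$name,
    true_coherence = true_coh,
    n_segments = attr(coh, "n_segments")
  )
  write_table_with_header(summary_tbl, path("coherence_summary.csv"),
    hash, seed)
  outputs$coherence <- "coherence_summary.csv"

  manifest <- list(
    package = "pupilbeat",
    config_hash = hash,
    seed = seed,
    config = config,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

# CSV writer with the provenance comment line on top.
write_table_with_header <- function(tbl, path, config_hash, seed) {
  writeLines(provenance_header(config_hash, seed), path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
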