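# Broom-style tidiers for the package's fitted/derived objects.

#' Tidy a ZEST experiment into its threshold table
#'
#' @param x A `zest_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return One row per probed position: `probe_position`, `threshold_db`,
#'   `n_obs`, `posterior_sd`.
#' @export
tidy.zest_experiment <- function(x, ...) {
  x$thresholds
}

#' One-row summary of a ZEST experiment
#'
#' @param x A `zest_experiment`.
#' @param ... Unused.
#' @return A tibble with loop/trial counts, hit rate over deviants, and the
#'   mean estimated threshold.
#' @export
glance.zest_experiment <- function(x, ...) {
  dev <- x$trials[x$trials$trial_kind == "deviant", ]
  tibble(
    n_loops = nrow(x$trials),
    n_deviants = nrow(dev),
    n_positions = nrow(x$thresholds),
    hit_rate = mean(dev$response == "hit"),
    mean_threshold_db = mean(x$thresholds$threshold_db),
    quota = x$quota
  )
}

#' Tidy a ZEST posterior state
#'
#' @param x A `zest_state`.
#' @param ... Unused.
#' @return A tibble (`threshold_db`, `density`).
#' @export
tidy.zest_state <- function(x, ...) {
  tibble(threshold_db = x$grid, density = x$pdf)
}

#' @export
glance.zest_state <- function(x, ...) {
  tibble(
    posterior_mean_db = next_level(x),
    posterior_sd_db = zest_posterior_sd(x),
    n_observations = x$n_observations
  )
}

#' Tidy an oscillator model into its mean periodicity profile
#'
#' @param x An `oscillator_model`.
#' @param ... Unused.
#' @return The MPP tibble (`frequency_hz`, `energy`, `is_peak`).
#' @export
tidy.oscillator_model <- function(x, ...) {
  as_tibble(x$mpp)
}

#' @export
glance.oscillator_model <- function(x, ...) {
  pk <- peak_frequencies(x$mpp)
  tibble(
    loop_duration_s = x$loop_duration_s,
    n_peaks = length(pk),
    lowest_peak_hz = if (length(pk)) min(pk) else NA_real_,
    highest_peak_hz = if (length(pk)) max(pk) else NA_real_,
    mean_salience = mean(x$salience$salience)
  )
}

#' @export
glance.coherence_result <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_segments = attr(x, "n_segments"),
    window_s = attr(x, "window_s"),
    overlap = attr(x, "overlap"),
    mean_coherence = mean(x$coherence, na.rm = TRUE)
  )
}
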