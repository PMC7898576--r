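# autoplot() methods for the main result types.

#' @export
autoplot.salience_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$salience)) +
    geom_line(color = "#2c7fb8") +
    labs(
      x = "time (s)", y = "salience",
      title = sprintf("Temporal salience (%s)", attr(object, "variant"))
    ) +
    theme_minimal()
}

#' @export
autoplot.mpp <- function(object, ...) {
  pk <- dplyr::filter(object, .data$is_peak)
  ggplot(object, aes(x = .data$frequency_hz, y = .data$energy)) +
    geom_line(color = "grey40") +
    geom_segment(
      data = pk,
      aes(xend = .data$frequency_hz, yend = min(object$energy)),
      color = "black", linewidth = 1
    ) +
    scale_x_log10() +
    labs(
      x = "periodicity frequency (Hz, log)", y = "energy",
      title = "Mean periodicity profile",
      subtitle = "dark lines: peak periodicities (> 5% of amplitude range)"
    ) +
    theme_minimal()
}

#' @export
autoplot.prf_kernel <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$h)) +
    geom_line(color = "#d95f02") +
    geom_vline(xintercept = attr(object, "t_max_ms"), linetype = "dashed") +
    labs(
      x = "time (ms)", y = "h(t) (peak-normalized)",
      title = "Pupillary response function",
      subtitle = sprintf(
        "Erlang gamma, n = %.1f, t_max = %g ms",
        attr(object, "n"), attr(object, "t_max_ms")
      )
    ) +
    theme_minimal()
}

#' @export
autoplot.predicted_pupil <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$prediction)) +
    geom_line(color = "#1b9e77") +
    labs(
      x = "time (s)", y = "predicted pupil (a.u., mean-centered)",
      title = sprintf("Forward-model pupil prediction (%s salience)",
        attr(object, "variant") %||% "")
    ) +
    theme_minimal()
}

#' @export
autoplot.coherence_result <- function(object, ..., fmax_hz = 5) {
  d <- dplyr::filter(object, .data$frequency_hz <= fmax_hz)
  ggplot(d, aes(x = .data$frequency_hz, y = .data$coherence)) +
    geom_line(color = "#7570b3") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(
      x = "frequency (Hz)", y = "magnitude-squared coherence",
      title = "Pupil-model coherence",
      subtitle = sprintf("Welch %.1f s windows, %d%% overlap, %d segments",
        attr(object, "window_s"), round(100 * attr(object, "overlap")),
        attr(object, "n_segments"))
    ) +
    theme_minimal()
}

#' @export
autoplot.zest_experiment <- function(object, ...) {
  dev <- dplyr::filter(object$trials, .data$trial_kind == "deviant") |>
    dplyr::group_by(.data$probe_position) |>
    dplyr::mutate(observation = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot(dev, aes(
    x = .data$observation, y = .data$level_db,
    color = factor(.data$probe_position)
  )) +
    geom_line() +
    geom_point(aes(shape = .data$response), size = 2) +
    geom_hline(
      data = object$thresholds,
      aes(yintercept = .data$threshold_db,
          color = factor(.data$probe_position)),
      linetype = "dotted"
    ) +
    labs(
      x = "observation", y = "deviant level (dB)",
      color = "probe position", shape = "response",
      title = "ZEST adaptive tracks"
    ) +
    theme_minimal()
}

#' Mean pupil dilation response by trial kind
#'
#' @param pdr A `pdr_epochs` object from [epoch_pdr()].
#' @return A ggplot of the trial-kind mean evoked responses.
#' @export
plot_pdr <- function(pdr) {
  stopifnot(inherits(pdr, "pdr_epochs"))
  avg <- pdr$epochs |>
    dplyr::group_by(.data$trial_kind, .data$time_ms) |>
    dplyr::summarise(pupil = mean(.data$pupil), .groups = "drop")
  ggplot(avg, aes(x = .data$time_ms, y = .data$pupil,
    color = .data$trial_kind)) +
    geom_line() +
    labs(
      x = "time from event onset (ms)", y = "evoked pupil (baseline-corrected)",
      color = "trial kind", title = "Pupil dilation response"
    ) +
    theme_minimal()
}
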