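#' Amplitude envelope of an audio signal
#'
#' The model-free alternative salience predictor: a sliding-window RMS
#' envelope of the waveform (upper envelope), low-pass filtered and
#' down-sampled to the model rate. The low-pass is applied forward-backward
#' (zero phase) so envelope peaks stay aligned with event times.
#'
#' @param audio An [audio_signal()].
#' @param rms_window_ms RMS window length (default 50 ms).
#' @param lp_cutoff_hz Low-pass cutoff (default 50 Hz).
#' @param lp_order Butterworth order (default 3).
#' @param out_rate_hz Output rate (default 100 Hz; audio rate must be an
#'   integer multiple).
#' @return A `salience_series` tibble (variant `"amplitude_envelope"`).
#' @export
amplitude_envelope <- function(audio, rms_window_ms = 50, lp_cutoff_hz = 50,
                               lp_order = 3, out_rate_hz = 100) {
  stopifnot(inherits(audio, "audio_signal"))
  sr <- audio$sample_rate
  width <- round(rms_window_ms / 1000 * sr)
  if (width > length(audio$samples)) {
    abort("RMS window is longer than the signal.")
  }
  factor <- sr / out_rate_hz
  if (abs(factor - round(factor)) > 1e-9) {
    abort("Audio rate must be an integer multiple of `out_rate_hz`.")
  }
  env <- moving_rms(audio$samples, width)
  bf <- signal::butter(lp_order, lp_cutoff_hz / (sr / 2), type = "low")
  env <- as.numeric(signal::filtfilt(bf, env))
  env <- pmax(env[seq(1L, length(env), by = as.integer(round(factor)))], 0)
  new_salience_series(env, out_rate_hz, "amplitude_envelope")
}
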