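#' Audio signal container
#'
#' @param samples Numeric vector of mono samples in [-1, 1].
#' @param sample_rate Sampling rate in Hz.
#' @return An `audio_signal` (list with `samples`, `sample_rate`,
#'   `duration_s`).
#' @export
audio_signal <- function(samples, sample_rate = 44100) {
  if (!all(is.finite(samples))) abort("Audio samples must be finite.")
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = sample_rate,
      duration_s = length(samples) / sample_rate
    ),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %.3f s at %g Hz (%d samples), peak %.3f>\n",
    x$duration_s, x$sample_rate, length(x$samples), max(abs(x$samples))
  ))
  invisible(x)
}

# One percussive burst per timbre: exponentially decaying band-limited noise
# (snap, shaker) or a damped low tone (conga). Spectral centroids ~2 kHz /
# ~6 kHz / ~200 Hz drive the cochlear bands differentially, standing in for
# the distinct sampled instruments of a multi-timbre drum loop.
timbre_params <- function() {
  list(
    snap   = list(center_hz = 2000, bw_hz = 1500, decay_s = 0.015, tonal = FALSE),
    shaker = list(center_hz = 6000, bw_hz = 3000, decay_s = 0.040, tonal = FALSE),
    conga  = list(center_hz = 200,  bw_hz = 150,  decay_s = 0.080, tonal = TRUE)
  )
}

# A single burst waveform for `timbre` at `sample_rate`. Every onset of a
# timbre within a render reuses the same waveform (like a sampler retriggering
# one recording), which also guarantees exact loop periodicity.
timbre_burst <- function(timbre, sample_rate) {
  p <- timbre_params()[[timbre]]
  if (is.null(p)) abort(sprintf("Unknown timbre '%s'.", timbre))
  n <- round(6 * p$decay_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- exp(-t / p$decay_s)
  if (p$tonal) {
    carrier <- sin(2 * pi * p$center_hz * t) + 0.2 * rnorm(n)
  } else {
    lo <- max(p$center_hz - p$bw_hz / 2, 20) / (sample_rate / 2)
    hi <- min(p$center_hz + p$bw_hz / 2, 0.45 * sample_rate) / (sample_rate / 2)
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    carrier <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  }
  burst <- env * carrier
  burst / max(abs(burst))
}

#' Render one loop of a rhythm pattern as audio
#'
#' Synthesizes every onset as a short percussive burst (one fixed waveform per
#' timbre, scaled by onset velocity) and sums them into a single loop.
#' Rendering is circular: a burst tail that would extend past the loop end
#' wraps around to the loop start, so the rendered loop is the steady state of
#' continuous looping and concatenated copies are seamless.
#'
#' @param pattern A [make_pattern()] object.
#' @param sample_rate Output rate in Hz (>= 8000).
#' @param seed Integer seed for the burst noise carriers; rendering is
#'   deterministic given `(pattern, seed)`.
#' @param gain Fixed master gain applied to the summed bursts. Output is
#'   rescaled only if the peak would exceed `headroom`, so amplitude remains
#'   monotone in onset velocity under normal conditions.
#' @param headroom Maximum peak amplitude allowed in the output.
#' @return An [audio_signal()] of one loop.
#' @export
render_loop <- function(pattern, sample_rate = 44100, seed = 1L,
                        gain = 0.3, headroom = 0.95) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  if (sample_rate < 8000) abort("`sample_rate` must be at least 8000 Hz.")
  n <- round(pattern$loop_duration_s * sample_rate)
  out <- numeric(n)
  with_seed(seed, {
    bursts <- lapply(
      setNames(nm = sort(unique(pattern$tracks$timbre))),
      timbre_burst,
      sample_rate = sample_rate
    )
    onset_samples <- round(pattern_onset_times(pattern) * sample_rate)
    for (i in seq_len(nrow(pattern$tracks))) {
      b <- bursts[[pattern$tracks$timbre[i]]] * pattern$tracks$velocity[i]
      idx <- (onset_samples[i] + seq_along(b) - 1L) %% n + 1L
      out[idx] <- out[idx] + b
    }
  })
  out <- out * gain
  peak <- max(abs(out))
  if (peak > headroom) out <- out * headroom / peak
  audio_signal(out, sample_rate)
}

#' Insert a fixed-duration intensity deviant into a loop
#'
#' Scales the samples in `[probe_time_s, probe_time_s + duration_ms)` by
#' `10^(delta_db / 20)`; every other sample is returned bit-identical. The
#' window must fit inside the loop (no wrap-around), so probe positions are
#' restricted to `probe_time_s + duration <= loop end`.
#'
#' @param audio An [audio_signal()] loop.
#' @param probe_time_s Deviant onset within the loop, seconds.
#' @param duration_ms Deviant duration (default 200 ms).
#' @param delta_db Intensity increment in dB (>= 0).
#' @return The modified [audio_signal()].
#' @export
insert_deviant <- function(audio, probe_time_s, duration_ms = 200,
                           delta_db) {
  stopifnot(inherits(audio, "audio_signal"))
  if (delta_db < 0) abort("`delta_db` must be >= 0.")
  sr <- audio$sample_rate
  i0 <- round(probe_time_s * sr) + 1L
  len <- round(duration_ms / 1000 * sr)
  if (i0 < 1L || i0 + len - 1L > length(audio$samples)) {
    abort("Deviant window exceeds the loop; it must not wrap across the loop boundary.")
  }
  idx <- i0:(i0 + len - 1L)
  out <- audio$samples
  out[idx] <- out[idx] * 10^(delta_db / 20)
  audio_signal(out, sr)
}
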