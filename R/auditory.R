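#' Band envelope / onset matrices
#'
#' Internal constructor for the bands-by-time matrices produced by the
#' auditory front end: `values` is an `n_bands x n_frames` matrix at the
#' model rate (nonnegative), with one center frequency per band.
#' @noRd
band_matrix <- function(values, band_centers_hz, rate_hz, kind) {
  structure(
    list(
      values = values,
      band_centers_hz = band_centers_hz,
      rate_hz = rate_hz,
      kind = kind
    ),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf(
    "<band_matrix (%s): %d bands x %d frames at %g Hz, centers %.0f-%.0f Hz>\n",
    x$kind, nrow(x$values), ncol(x$values), x$rate_hz,
    min(x$band_centers_hz), max(x$band_centers_hz)
  ))
  invisible(x)
}

# ERB-rate scale (Glasberg & Moore): number of ERBs below frequency f.
erb_rate <- function(f_hz) 21.4 * log10(1 + 0.00437 * f_hz)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Cochlear band decomposition
#'
#' Splits mono audio into `n_bands` frequency channels with center frequencies
#' spaced on an ERB (auditory) scale between `freq_range[1]` and
#' `freq_range[2]` Hz, and returns the RMS amplitude envelope of each channel
#' framed at the model rate (100 Hz). Channels are 2nd-order Butterworth
#' band-passes between the ERB midpoints of neighbouring centers, applied
#' forward-backward (zero phase).
#'
#' @param audio An [audio_signal()]; rate must be at least 8 kHz and above
#'   twice the top band edge.
#' @param n_bands Number of channels (default 40).
#' @param freq_range Centers of the lowest and highest bands, Hz.
#' @param model_rate_hz Envelope frame rate (default 100 Hz; audio rate must
#'   be an integer multiple).
#' @return A band envelope matrix (`band_matrix`, kind `"envelope"`).
#' @export
cochlear_bands <- function(audio, n_bands = 40L, freq_range = c(141, 8877),
                           model_rate_hz = 100) {
  stopifnot(inherits(audio, "audio_signal"))
  if (length(audio$samples) == 0L) abort("Audio is empty.")
  sr <- audio$sample_rate
  if (sr < 8000) abort("Audio sample rate must be at least 8000 Hz.")
  frame <- sr / model_rate_hz
  if (abs(frame - round(frame)) > 1e-9) {
    abort("Audio rate must be an integer multiple of the model rate.")
  }
  frame <- as.integer(round(frame))
  centers <- erb_rate_inv(seq(erb_rate(freq_range[1]), erb_rate(freq_range[2]),
    length.out = n_bands
  ))
  # band edges at ERB midpoints between adjacent centers
  mids <- erb_rate_inv((erb_rate(centers[-1]) + erb_rate(centers[-n_bands])) / 2)
  lo <- c(erb_rate_inv(2 * erb_rate(centers[1]) - erb_rate(mids[1])), mids)
  hi <- c(mids, erb_rate_inv(2 * erb_rate(centers[n_bands]) - erb_rate(mids[n_bands - 1])))
  if (max(hi) >= sr / 2) {
    abort("Top band edge reaches Nyquist; increase the audio sample rate.")
  }
  n_frames <- floor(length(audio$samples) / frame)
  x <- audio$samples[seq_len(n_frames * frame)]
  vals <- matrix(0, nrow = n_bands, ncol = n_frames)
  for (b in seq_len(n_bands)) {
    bf <- signal::butter(2, c(lo[b], hi[b]) / (sr / 2), type = "pass")
    y <- signal::filtfilt(bf, x)
    # frame RMS at the model rate
    vals[b, ] <- sqrt(colMeans(matrix(y^2, nrow = frame)))
  }
  band_matrix(vals, centers, model_rate_hz, "envelope")
}

#' Per-band onset detection
#'
#' The half-wave rectified first-order difference of each band's RMS
#' envelope: `max(0, x[t] - x[t-1])`, with the first frame set to zero.
#'
#' @param envelopes A `band_matrix` of envelopes at the model rate.
#' @return A `band_matrix` of onset signals (kind `"onsets"`).
#' @export
detect_onsets <- function(envelopes) {
  stopifnot(inherits(envelopes, "band_matrix"))
  v <- envelopes$values
  d <- cbind(0, pmax(v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE], 0))
  band_matrix(d, envelopes$band_centers_hz, envelopes$rate_hz, "onsets")
}

#' Reduce adjacent bands by averaging
#'
#' Averages contiguous groups of `group_size` adjacent bands (40 channels ->
#' 5 bands with the defaults) to reduce redundancy before the oscillator
#' bank.
#'
#' @param bands A `band_matrix`.
#' @param group_size Bands per group; must divide the band count.
#' @return A `band_matrix` with `n_bands / group_size` bands; each center is
#'   the geometric mean of its group's centers.
#' @export
reduce_bands <- function(bands, group_size = 8L) {
  stopifnot(inherits(bands, "band_matrix"))
  nb <- nrow(bands$values)
  if (nb %% group_size != 0L) {
    abort("Band count is not divisible by `group_size`.")
  }
  groups <- rep(seq_len(nb / group_size), each = group_size)
  vals <- unname(rowsum(bands$values, groups)) / group_size
  centers <- exp(as.numeric(rowsum(log(bands$band_centers_hz), groups)) / group_size)
  band_matrix(vals, centers, bands$rate_hz, bands$kind)
}
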