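# Welch cross-spectral machinery and the entrainment statistics built on it.

# Segment starts for Welch averaging; errors if the signal is too short.
welch_starts <- function(n, L, step) {
  if (n < L) abort("Signal is shorter than one Welch window.")
  seq(1L, n - L + 1L, by = step)
}

# Averaged one-sided cross-spectral density of x and y (x = y gives the PSD).
# Hann taper, per-segment demeaning, density scaling 1 / (rate * sum(w^2)).
welch_cross_spectrum <- function(x, y, rate_hz, window_s = 4.4,
                                 overlap = 0.75) {
  if (length(x) != length(y)) abort("Signals must have equal length.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  L <- round(window_s * rate_hz)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- welch_starts(length(x), L, step)
  w <- hann_window(L)
  scale <- 1 / (rate_hz * sum(w^2))
  acc <- complex(real = numeric(L), imaginary = numeric(L))
  for (s in starts) {
    idx <- s:(s + L - 1L)
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    X <- fft(w * xs)
    Y <- fft(w * ys)
    acc <- acc + Conj(X) * Y
  }
  sxy <- acc * scale / length(starts)
  half <- floor(L / 2) + 1L
  sxy <- sxy[seq_len(half)]
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, half)
  dbl[1L] <- 1
  if (L %% 2 == 0L) dbl[half] <- 1
  list(
    frequency_hz = (seq_len(half) - 1L) * rate_hz / L,
    sxy = sxy * dbl,
    n_segments = length(starts),
    window_s = window_s, overlap = overlap
  )
}

#' Welch power spectral density
#'
#' Averaged, Hann-tapered, 75\%-overlapped windowed periodogram (4.4 s
#' windows by default, i.e. ~0.227 Hz resolution at 100 Hz).
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate.
#' @param window_s Window length in seconds.
#' @param overlap Fractional window overlap.
#' @return A tibble (`frequency_hz`, `psd`) with attribute `n_segments`.
#' @export
welch_psd <- function(x, rate_hz, window_s = 4.4, overlap = 0.75) {
  cs <- welch_cross_spectrum(x, x, rate_hz, window_s, overlap)
  out <- tibble(frequency_hz = cs$frequency_hz, psd = Re(cs$sxy))
  attr(out, "n_segments") <- cs$n_segments
  out
}

#' Magnitude-squared coherence between two signals
#'
#' \deqn{C(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))}
#' estimated with Welch's method (4.4 s windows, 75\% overlap, Hann taper).
#' Coherence is bounded in [0, 1]; bins where either auto-spectrum is zero
#' are returned as `NA` (coherence undefined there). Note the estimate is
#' biased upward for few segments (expectation ~ 1/n_segments for
#' independent signals) and is identically 1 when only one segment fits.
#'
#' @param x,y Equal-length signals at the same rate.
#' @param rate_hz Common sampling rate.
#' @param window_s,overlap Welch parameters.
#' @return A `coherence_result` tibble (`frequency_hz`, `coherence`) with
#'   attributes `n_segments`, `window_s`, `overlap`.
#' @export
coherence <- function(x, y, rate_hz, window_s = 4.4, overlap = 0.75) {
  cxy <- welch_cross_spectrum(x, y, rate_hz, window_s, overlap)
  cxx <- welch_cross_spectrum(x, x, rate_hz, window_s, overlap)
  cyy <- welch_cross_spectrum(y, y, rate_hz, window_s, overlap)
  denom <- Re(cxx$sxy) * Re(cyy$sxy)
  coh <- ifelse(denom > 0, Mod(cxy$sxy)^2 / denom, NA_real_)
  coh <- pmin(pmax(coh, 0), 1) # clip floating-point excursions
  out <- tibble(frequency_hz = cxy$frequency_hz, coherence = coh)
  class(out) <- c("coherence_result", class(out))
  attr(out, "n_segments") <- cxy$n_segments
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  out
}

#' Mean coherence at model-predicted peak frequencies
#'
#' Averages the coherence at the Welch bin nearest each peak periodicity
#' below `fmax_hz` (default 3 Hz, beyond which the pupil spectrum carries
#' little power).
#'
#' @param coh A [coherence()] result.
#' @param peaks Peak frequencies in Hz, or an `mpp` object.
#' @param fmax_hz Upper frequency limit for qualifying peaks.
#' @return Scalar mean coherence.
#' @export
peak_band_coherence <- function(coh, peaks, fmax_hz = 3) {
  stopifnot(inherits(coh, "coherence_result"))
  if (inherits(peaks, "mpp") || is.data.frame(peaks)) {
    peaks <- peak_frequencies(peaks)
  }
  peaks <- peaks[peaks < fmax_hz]
  if (length(peaks) == 0L) abort("No peak frequencies below `fmax_hz`.")
  bins <- vapply(peaks, function(f) {
    which.min(abs(coh$frequency_hz - f))
  }, integer(1))
  mean(coh$coherence[bins], na.rm = TRUE)
}

#' Null coherence against the other stimuli's predictions
#'
#' The shuffled-stimulus null: the pupil trace is compared against the model
#' prediction for every *other* stimulus, each evaluated at that stimulus's
#' own peak frequencies (or at the pupil's own stimulus's peaks with
#' `peaks = "own"`), and the peak-band coherences are averaged.
#'
#' @param pupil Numeric pupil signal at `rate_hz`.
#' @param predictions Named list of numeric prediction signals (equal length
#'   to `pupil`), one per stimulus.
#' @param peaks_by_stimulus Named list of peak-frequency vectors (or `mpp`
#'   objects), same names as `predictions`.
#' @param own_id Name of the stimulus the pupil was recorded to.
#' @param rate_hz Common sampling rate.
#' @param peaks `"other"` (default) evaluates each null pairing at the other
#'   stimulus's peaks; `"own"` always uses `own_id`'s peaks.
#' @param window_s,overlap,fmax_hz Passed through to [coherence()] /
#'   [peak_band_coherence()].
#' @return Scalar mean null coherence.
#' @export
null_coherence <- function(pupil, predictions, peaks_by_stimulus, own_id,
                           rate_hz, peaks = c("other", "own"),
                           window_s = 4.4, overlap = 0.75, fmax_hz = 3) {
  peaks <- match.arg(peaks)
  others <- setdiff(names(predictions), own_id)
  if (length(others) == 0L) {
    abort("Need at least one other stimulus for the null.")
  }
  vals <- map_dbl(others, function(id) {
    coh <- coherence(pupil, predictions[[id]], rate_hz, window_s, overlap)
    pk <- if (peaks == "other") peaks_by_stimulus[[id]] else peaks_by_stimulus[[own_id]]
    peak_band_coherence(coh, pk, fmax_hz)
  })
  mean(vals)
}

#' Paired t-test of true vs null coherence
#'
#' Standard paired-samples t-test on the per-run (true - null) differences.
#'
#' @param true_values,null_values Paired coherence summaries (length >= 3).
#' @param alternative Passed to [stats::t.test()]; `"greater"` tests
#'   true > null.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p_value`.
#' @export
paired_true_null_test <- function(true_values, null_values,
                                  alternative = "greater") {
  if (length(true_values) != length(null_values) || length(true_values) < 3L) {
    abort("Need at least 3 paired values.")
  }
  d <- true_values - null_values
  if (var(d) == 0) abort("Zero variance of paired differences; t is undefined.")
  tt <- t.test(true_values, null_values, paired = TRUE,
    alternative = alternative
  )
  tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Rescale AIC values to information-loss differences
#'
#' \deqn{\Delta_i = AIC_i - AIC_{min}} so the best model maps to exactly 0
#' and every other model is expressed as information lost relative to it.
#'
#' @param aic_values Numeric vector of AIC values (length >= 2, finite).
#' @return Numeric vector of deltas, minimum exactly 0.
#' @examples
#' delta_aic(c(2082.857, 2125.737, 2090.672)) # 0, 42.88, 7.815
#' @export
delta_aic <- function(aic_values) {
  if (length(aic_values) < 2L) abort("Need at least 2 AIC values.")
  if (!all(is.finite(aic_values))) abort("AIC values must be finite.")
  aic_values - min(aic_values)
}

#' Average the pupil over consecutive multi-loop epochs
#'
#' Segments the trace into consecutive `loops_per_epoch`-loop windows (8 by
#' default) starting at loop onsets, averages them point-wise, and returns
#' the averaged epoch with its Welch PSD. Averaging across epochs suppresses
#' activity not phase-locked to the loop.
#'
#' @param pupil Numeric pupil signal.
#' @param loop_onsets Sample indices (1-based) of loop onsets.
#' @param loops_per_epoch Loops per epoch (default 8).
#' @param rate_hz Sampling rate of `pupil`.
#' @param window_s,overlap Welch parameters for the PSD of the average.
#' @return List: `epoch` (tibble `time_s`, `pupil`), `psd` (tibble), and
#'   `n_epochs`.
#' @export
loop_epoch_average <- function(pupil, loop_onsets, loops_per_epoch = 8L,
                               rate_hz = 100, window_s = 4.4,
                               overlap = 0.75) {
  loop_onsets <- sort(as.integer(loop_onsets))
  if (length(loop_onsets) < 2L) abort("Need at least 2 loop onsets.")
  if (any(loop_onsets < 1L) || any(loop_onsets > length(pupil))) {
    abort("Loop onsets fall outside the trace.")
  }
  L <- round(median(diff(loop_onsets)) * loops_per_epoch)
  starts <- loop_onsets[seq(1L, length(loop_onsets), by = loops_per_epoch)]
  starts <- starts[starts + L - 1L <= length(pupil)]
  if (length(starts) < 1L) abort("Trace holds fewer than one full epoch.")
  seg <- vapply(starts, function(s) pupil[s:(s + L - 1L)], numeric(L))
  avg <- rowMeans(seg)
  list(
    epoch = tibble(time_s = (seq_len(L) - 1L) / rate_hz, pupil = avg),
    psd = if (L >= round(window_s * rate_hz)) {
      welch_psd(avg, rate_hz, window_s, overlap)
    } else {
      NULL
    },
    n_epochs = length(starts)
  )
}
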