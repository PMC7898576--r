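#' Windowed-RMS periodicity surfaces
#'
#' Slides an RMS window along every filter output, giving the energy at each
#' reson-filter periodicity as a function of time — one periodicity surface
#' per band.
#'
#' @param reson_out A `reson_output` from [reson_bank_apply()].
#' @param window_s RMS window length in seconds (default 2 s, covering at
#'   least one cycle of most metrical periodicities).
#' @param hop_s Hop between successive windows (default 10 ms = one frame at
#'   the 100 Hz model rate).
#' @return A `periodicity_surface`: list with `energy` — an array
#'   `n_bands x n_filters x n_windows` (or a matrix `n_filters x n_windows`
#'   after [average_surface()]) — plus `frequencies_hz`, `times_s`,
#'   `window_s`, `hop_s`.
#' @export
periodicity_surface <- function(reson_out, window_s = 2, hop_s = 0.01) {
  stopifnot(inherits(reson_out, "reson_output"))
  rate <- reson_out$rate_hz
  L <- round(window_s * rate)
  hop <- round(hop_s * rate)
  if (hop < 1L) abort("`hop_s` must be at least one frame.")
  if (L < hop) abort("RMS window must be at least one hop long.")
  d <- dim(reson_out$values)
  nt <- d[3]
  if (nt < L) abort("Signal shorter than one RMS window.")
  starts <- seq(1L, nt - L + 1L, by = hop)
  # windowed mean square via cumulative sums, per (band, filter)
  flat <- matrix(aperm(reson_out$values, c(3, 1, 2)), nrow = nt)
  cs <- rbind(0, apply(flat^2, 2, cumsum))
  ms <- (cs[starts + L, , drop = FALSE] - cs[starts, , drop = FALSE]) / L
  energy <- aperm(
    array(sqrt(pmax(t(ms), 0)), dim = c(d[1], d[2], length(starts))),
    c(1, 2, 3)
  )
  structure(
    list(
      energy = energy,
      frequencies_hz = reson_out$frequencies_hz,
      times_s = (starts - 1 + L / 2) / rate,
      window_s = window_s, hop_s = hop_s, rate_hz = rate
    ),
    class = "periodicity_surface"
  )
}

#' Average periodicity surfaces across bands
#'
#' Point-wise mean of the per-band surfaces, yielding the Average Periodicity
#' Surface.
#'
#' @param surface A `periodicity_surface` with a band dimension, or a list of
#'   single-band surfaces on identical grids.
#' @return A `periodicity_surface` whose `energy` is `n_filters x n_windows`.
#' @export
average_surface <- function(surface) {
  if (inherits(surface, "periodicity_surface")) {
    if (length(dim(surface$energy)) == 2L) {
      return(surface)
    }
    avg <- apply(surface$energy, c(2, 3), mean)
    out <- surface
    out$energy <- avg
    return(out)
  }
  stopifnot(is.list(surface), length(surface) >= 1L)
  mats <- purrr::map(surface, function(s) {
    e <- s$energy
    if (length(dim(e)) == 3L) e <- e[1, , ]
    e
  })
  out <- surface[[1]]
  out$energy <- Reduce(`+`, mats) / length(mats)
  out
}

#' Mean periodicity profile and peak periodicities
#'
#' Averages the Average Periodicity Surface over time to get the energy at
#' each periodicity frequency, then marks peak periodicities: strict local
#' maxima of the profile whose value exceeds 5\% of the profile's amplitude
#' range above its minimum (plateaus take the lowest-frequency sample). An
#' all-flat profile yields an empty peak set.
#'
#' @param aps An averaged `periodicity_surface` (see [average_surface()]).
#' @return An `mpp` tibble with columns `frequency_hz`, `energy`, `is_peak`;
#'   attribute `peak_frequencies_hz` carries the peak set.
#' @export
mean_periodicity_profile <- function(aps) {
  stopifnot(inherits(aps, "periodicity_surface"))
  e <- aps$energy
  if (length(dim(e)) == 3L) {
    abort("Average the surface across bands first (see `average_surface()`).")
  }
  profile <- rowMeans(e)
  is_peak <- find_profile_peaks(profile, rel_threshold = 0.05)
  out <- tibble(
    frequency_hz = aps$frequencies_hz,
    energy = profile,
    is_peak = is_peak
  )
  class(out) <- c("mpp", class(out))
  attr(out, "peak_frequencies_hz") <- aps$frequencies_hz[is_peak]
  out
}

# Strict local maxima above min + rel_threshold * range. Plateaus are
# attributed to their lowest-frequency sample; endpoints are not peaks.
find_profile_peaks <- function(profile, rel_threshold = 0.05) {
  n <- length(profile)
  if (n < 3L) {
    return(rep(FALSE, n))
  }
  rng <- max(profile) - min(profile)
  thr <- min(profile) + rel_threshold * rng
  idx <- 2:(n - 1)
  peak <- rep(FALSE, n)
  peak[idx] <- profile[idx] > profile[idx - 1] & profile[idx] >= profile[idx + 1]
  if (rng == 0) {
    return(rep(FALSE, n))
  }
  peak & profile > thr
}

#' Peak frequencies of a mean periodicity profile
#' @param mpp An `mpp` from [mean_periodicity_profile()].
#' @return Numeric vector of peak frequencies in Hz.
#' @export
peak_frequencies <- function(mpp) {
  attr(mpp, "peak_frequencies_hz") %||% mpp$frequency_hz[mpp$is_peak]
}

#' Temporal salience from reson-bank output
#'
#' The model's estimate of moment-to-moment attentional pull. For the
#' `"peak_masked"` variant the reson output is masked to the peak-periodicity
#' filters of the mean periodicity profile and the rectified amplitudes are
#' averaged point-wise across the selected (band, filter) pairs. The
#' `"full_reson"` variant averages over all filters instead, asking whether
#' the prominent metric periodicities matter at all.
#'
#' @param reson_out A `reson_output`.
#' @param mpp The stimulus's [mean_periodicity_profile()] (required for
#'   `"peak_masked"`).
#' @param variant `"peak_masked"` or `"full_reson"`.
#' @param amplitude How "resonator amplitude" is measured per filter:
#'   `"analytic"` (default) takes the instantaneous amplitude of the analytic
#'   signal, which tracks how strongly an oscillator is ringing without the
#'   double-frequency ripple that full-wave rectification introduces;
#'   `"rectified"` uses the rectified absolute output.
#' @return A `salience_series` tibble (`time_s`, `salience`) with attributes
#'   `variant` and `rate_hz`.
#' @export
temporal_salience <- function(reson_out, mpp = NULL,
                              variant = c("peak_masked", "full_reson"),
                              amplitude = c("analytic", "rectified")) {
  stopifnot(inherits(reson_out, "reson_output"))
  variant <- match.arg(variant)
  amplitude <- match.arg(amplitude)
  nf <- length(reson_out$frequencies_hz)
  if (variant == "peak_masked") {
    if (is.null(mpp)) abort("`peak_masked` salience needs an `mpp`.")
    keep <- which(mpp$is_peak)
    if (length(keep) == 0L) {
      abort("Peak-masked salience is undefined: the MPP peak set is empty.")
    }
  } else {
    keep <- seq_len(nf)
  }
  d <- dim(reson_out$values)
  acc <- numeric(d[3])
  for (b in seq_len(d[1])) {
    for (k in keep) {
      y <- reson_out$values[b, k, ]
      acc <- acc + if (amplitude == "analytic") analytic_amplitude(y) else abs(y)
    }
  }
  values <- acc / (d[1] * length(keep))
  new_salience_series(values, reson_out$rate_hz, variant)
}

new_salience_series <- function(values, rate_hz, variant, pattern = NULL) {
  out <- tibble(
    time_s = (seq_along(values) - 1) / rate_hz,
    salience = as.numeric(values)
  )
  class(out) <- c("salience_series", class(out))
  attr(out, "rate_hz") <- rate_hz
  attr(out, "variant") <- variant
  attr(out, "pattern") <- pattern
  out
}

#' Run the full oscillator model on a pattern or audio
#'
#' Convenience wrapper composing the whole chain: cochlear band envelopes,
#' per-band onset detection, 40-to-5 band reduction, the 99-filter reson
#' bank, windowed-RMS periodicity surfaces, the band-averaged surface, the
#' mean periodicity profile with peak picking, and the salience series. The
#' stimulus is tiled for `loops` iterations so the oscillators reach steady
#' state; the returned one-loop salience series is cut from the final loop.
#'
#' @param x A `rhythm_pattern` (rendered internally) or an [audio_signal()]
#'   containing exactly one loop.
#' @param loops Number of loop iterations fed to the model.
#' @param sample_rate Audio rate used when `x` is a pattern.
#' @param bank A [reson_bank()].
#' @param window_s,hop_s Periodicity-surface RMS window parameters.
#' @param amplitude Resonator amplitude measure (see [temporal_salience()]).
#' @param seed Seed for rendering when `x` is a pattern.
#' @return An `oscillator_model` list: `onsets5`, `reson`, `aps`, `mpp`,
#'   `salience` (one loop, peak-masked), `salience_full`, `loop_samples`,
#'   `loop_duration_s`.
#' @examples
#' \donttest{
#' m <- oscillator_model(make_pattern("sparse1-like"), loops = 6)
#' peak_frequencies(m$mpp)
#' }
#' @export
oscillator_model <- function(x, loops = 10L, sample_rate = 44100,
                             bank = reson_bank(), window_s = 2, hop_s = 0.01,
                             amplitude = c("analytic", "rectified"),
                             seed = 1L) {
  amplitude <- match.arg(amplitude)
  if (inherits(x, "rhythm_pattern")) {
    audio <- render_loop(x, sample_rate = sample_rate, seed = seed)
    loop_duration_s <- x$loop_duration_s
  } else if (inherits(x, "audio_signal")) {
    audio <- x
    loop_duration_s <- audio$duration_s
  } else {
    abort("`x` must be a rhythm_pattern or an audio_signal.")
  }
  tiled <- audio_signal(rep(audio$samples, loops), audio$sample_rate)
  env40 <- cochlear_bands(tiled)
  onsets40 <- detect_onsets(env40)
  onsets5 <- reduce_bands(onsets40, group_size = 8L)
  reson <- reson_bank_apply(onsets5, bank)
  aps <- average_surface(periodicity_surface(reson, window_s, hop_s))
  mpp <- mean_periodicity_profile(aps)
  sal_tiled <- temporal_salience(reson, mpp, "peak_masked", amplitude)
  sal_full_tiled <- temporal_salience(reson,
    variant = "full_reson", amplitude = amplitude
  )
  rate <- reson$rate_hz
  loop_samples <- round(loop_duration_s * rate)
  last_loop <- function(s) {
    v <- s$salience
    i1 <- length(v) - loop_samples + 1L
    if (i1 < 1L) abort("Fewer model frames than one loop.")
    new_salience_series(v[i1:length(v)], rate, attr(s, "variant"))
  }
  structure(
    list(
      onsets5 = onsets5,
      reson = reson,
      aps = aps,
      mpp = mpp,
      salience = last_loop(sal_tiled),
      salience_full = last_loop(sal_full_tiled),
      loop_samples = loop_samples,
      loop_duration_s = loop_duration_s,
      rate_hz = rate
    ),
    class = "oscillator_model"
  )
}

#' @export
print.oscillator_model <- function(x, ...) {
  pk <- peak_frequencies(x$mpp)
  cat(sprintf(
    "<oscillator_model: loop %.3f s, %d peak periodicities (%s Hz)>\n",
    x$loop_duration_s, length(pk),
    paste(sprintf("%.2f", pk), collapse = ", ")
  ))
  invisible(x)
}
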