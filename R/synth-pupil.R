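#' Synthesize a raw eye-tracker pupil log
#'
#' Generates a 500 Hz pupil-size log with the statistical structure the
#' entrainment analysis assumes: the tiled one-loop salience prediction
#' convolved with the pupillary response function, expressed in arbitrary
#' eye-tracker units around a baseline, plus slow sinusoidal drift, broadband
#' noise, and blink artifacts (100-300 ms missing runs flanked by spike
#' artifacts, with saccade flags at the run edges). Loop and deviant onsets
#' are carried as event markers. With `noise_sd`, `blink_rate_hz` and
#' `drift_amplitude` all zero the log is exactly the tiled convolved
#' prediction resampled to 500 Hz (affinely rescaled into pupil units).
#'
#' @param salience A one-loop `salience_series` (100 Hz).
#' @param prf A [prf_kernel()] at the salience rate.
#' @param n_loops Number of loop iterations to simulate.
#' @param noise_sd White-noise SD in pupil units.
#' @param blink_rate_hz Mean blink rate (Poisson events per second).
#' @param drift_amplitude Amplitude of the slow (~0.01 Hz) drift component,
#'   pupil units.
#' @param baseline Mean pupil size in arbitrary units.
#' @param signal_gain Pupil units per unit of (peak-normalized) prediction.
#' @param deviant_times_s Optional deviant onset times (s from log start),
#'   written into the `event` column.
#' @param out_rate_hz Log sampling rate (default 500 Hz).
#' @param seed Integer seed; the log is bit-reproducible from it.
#' @return A `pupil_log` tibble: `time_ms`, `pupil` (NA within blinks),
#'   `blink`, `saccade` (0/1 flags), `event` (`""`, `"loop"`, `"deviant"`).
#'   Attributes: `sample_rate_hz`, `seed`, `fraction_missing`,
#'   `loop_duration_s`.
#' @export
synth_pupil <- function(salience, prf, n_loops = 170L, noise_sd = 4,
                        blink_rate_hz = 0.1, drift_amplitude = 15,
                        baseline = 1000, signal_gain = 30,
                        deviant_times_s = NULL, out_rate_hz = 500,
                        seed = 1L) {
  stopifnot(inherits(salience, "salience_series"), inherits(prf, "prf_kernel"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_loops < 1L) abort("`n_loops` must be >= 1.")
  rate <- attr(salience, "rate_hz")
  loop_samples <- nrow(salience)
  x <- rep(salience$salience, n_loops)
  k <- prf$h
  pred <- convolve_full(x, k)[seq_along(x)]
  if (max(abs(pred)) > 0) pred <- pred / max(abs(pred))
  # 100 Hz -> 500 Hz by linear interpolation
  n_out <- length(pred) * out_rate_hz / rate
  t_model <- (seq_along(pred) - 1) / rate
  t_out <- (seq_len(n_out) - 1) / out_rate_hz
  pupil <- baseline + signal_gain *
    approx(t_model, pred, xout = t_out, rule = 2)$y
  n <- length(pupil)
  blink <- integer(n)
  saccade <- integer(n)
  with_seed(seed, {
    if (drift_amplitude > 0) {
      drift_f <- 0.01
      pupil <- pupil + drift_amplitude *
        sin(2 * pi * drift_f * t_out + runif(1, 0, 2 * pi))
    }
    if (noise_sd > 0) pupil <- pupil + rnorm(n, sd = noise_sd)
    if (blink_rate_hz > 0) {
      n_blinks <- rpois(1, blink_rate_hz * n / out_rate_hz)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n, n_blinks))
        for (s in starts) {
          len <- round(runif(1, 0.1, 0.3) * out_rate_hz)
          run <- s:min(s + len - 1L, n)
          # spike artifacts flanking the missing run (eyelid sweep)
          pre <- max(run[1] - 1L, 1L)
          post <- min(run[length(run)] + 1L, n)
          pupil[pre] <- pupil[pre] + 60
          pupil[post] <- pupil[post] - 60
          pupil[run] <- NA_real_
          blink[run] <- 1L
          saccade[c(pre, post)] <- 1L
        }
      }
    }
  })
  event <- character(n)
  loop_idx <- round(seq(0, by = loop_samples / rate, length.out = n_loops) *
    out_rate_hz) + 1L
  event[loop_idx[loop_idx <= n]] <- "loop"
  if (!is.null(deviant_times_s)) {
    dev_idx <- round(deviant_times_s * out_rate_hz) + 1L
    event[dev_idx[dev_idx >= 1L & dev_idx <= n]] <- "deviant"
  }
  out <- tibble(
    time_ms = t_out * 1000,
    pupil = pupil,
    blink = blink,
    saccade = saccade,
    event = event
  )
  class(out) <- c("pupil_log", class(out))
  attr(out, "sample_rate_hz") <- out_rate_hz
  attr(out, "seed") <- as.integer(seed)
  attr(out, "fraction_missing") <- mean(is.na(pupil))
  attr(out, "loop_duration_s") <- loop_samples / rate
  out
}
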