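#' Pupillary response function (Erlang gamma kernel)
#'
#' The impulse response of pupil size to a discrete attentional event,
#' modelled as an Erlang gamma function
#' \deqn{h(t) = t^{n} e^{-n t / t_{max}}}
#' where `n` is the number of sequential neural signalling steps between
#' attentional pulse and pupillary response and `t_max` the latency of the
#' response peak. The defaults are the non-motor parameterization
#' (`n = 10.1`, `t_max = 512` ms) appropriate when responses are not
#' systematically tied to button presses. The kernel is peak-normalized
#' (`max h = 1`) since its output units are arbitrary, and truncated where it
#' has decayed below `trunc_frac` of its peak (about 1.4 s at defaults, just
#' past the empirically reported ~1300 ms return-to-baseline delay, which is
#' recorded as metadata in `return_to_baseline_ms`). Truncating on the decay
#' fraction rather than at a fixed delay keeps the rule valid for any
#' `(n, t_max)`.
#'
#' @param n Shape exponent (default 10.1).
#' @param t_max_ms Peak latency in ms (default 512).
#' @param rate_hz Sampling rate of the kernel grid (default 100 Hz).
#' @param trunc_frac Truncate once `h` falls below this fraction of the peak
#'   after the peak (default 0.001).
#' @return A `prf_kernel` tibble (`time_ms`, `h`) with attributes `n`,
#'   `t_max_ms`, `rate_hz`, `return_to_baseline_ms`.
#' @examples
#' k <- prf_kernel()
#' k$time_ms[which.max(k$h)] # peaks at t_max
#' @export
prf_kernel <- function(n = 10.1, t_max_ms = 512, rate_hz = 100,
                       trunc_frac = 0.001) {
  if (n <= 0 || t_max_ms <= 0) abort("`n` and `t_max_ms` must be positive.")
  if (trunc_frac <= 0 || trunc_frac >= 1) {
    abort("`trunc_frac` must be in (0, 1).")
  }
  step_ms <- 1000 / rate_hz
  # generous horizon; trimmed below once h has decayed past trunc_frac
  t <- seq(0, 20 * t_max_ms, by = step_ms)
  h <- prf_eval(t, n, t_max_ms)
  h <- h / max(h)
  peak_i <- which_max_first(h)
  below <- which(h < trunc_frac & seq_along(h) > peak_i)
  if (length(below) == 0L) abort("Truncation horizon too short for `trunc_frac`.")
  keep <- seq_len(below[1])
  out <- tibble(time_ms = t[keep], h = h[keep])
  class(out) <- c("prf_kernel", class(out))
  attr(out, "n") <- n
  attr(out, "t_max_ms") <- t_max_ms
  attr(out, "rate_hz") <- rate_hz
  attr(out, "return_to_baseline_ms") <- 1300
  out
}

# Unnormalized Erlang gamma h(t) = t^n exp(-n t / t_max), t in ms.
# Evaluated in log space: t^10.1 overflows double precision for t in ms.
prf_eval <- function(t_ms, n, t_max_ms) {
  h <- numeric(length(t_ms))
  pos <- t_ms > 0
  h[pos] <- exp(n * log(t_ms[pos]) - n * t_ms[pos] / t_max_ms)
  h
}

#' Predict the continuous pupil signal from a salience series
#'
#' Forward model of the pupil under continuous listening: the one-loop
#' salience series is tiled for `n_loops` iterations, convolved with the
#' pupillary response function, the first kernel length of output (the onset
#' transient) is discarded, and the result is mean-centered.
#'
#' @param salience A one-loop `salience_series`.
#' @param prf A [prf_kernel()] at the same rate.
#' @param n_loops Number of loop iterations (>= 3 so the transient discard
#'   leaves signal).
#' @return A `predicted_pupil` tibble (`time_s`, `prediction`) with
#'   attributes `rate_hz`, `loop_samples`, `n_loops`, `variant`.
#' @export
predict_pupil <- function(salience, prf, n_loops = 10L) {
  stopifnot(inherits(salience, "salience_series"), inherits(prf, "prf_kernel"))
  rate <- attr(salience, "rate_hz")
  if (rate != attr(prf, "rate_hz")) {
    abort("Salience and PRF kernel rates differ.")
  }
  if (n_loops < 3L) abort("`n_loops` must be at least 3.")
  x <- rep(salience$salience, n_loops)
  k <- prf$h
  if (length(k) >= length(x)) {
    abort("PRF kernel is longer than the tiled salience signal.")
  }
  y <- convolve_full(x, k)[seq_along(x)]
  y <- y[-seq_len(length(k))]
  y <- y - mean(y)
  out <- tibble(time_s = (seq_along(y) - 1) / rate, prediction = y)
  class(out) <- c("predicted_pupil", class(out))
  attr(out, "rate_hz") <- rate
  attr(out, "loop_samples") <- nrow(salience)
  attr(out, "n_loops") <- n_loops
  attr(out, "variant") <- attr(salience, "variant")
  out
}

# Linear (full) convolution via FFT.
convolve_full <- function(x, k) {
  convolve(x, rev(k), type = "open")
}

#' Power spectral density of a predicted pupil signal
#'
#' Welch PSD of the forward-model prediction, on a grid resolving the loop
#' harmonics. For rhythmic stimuli essentially all mass lies below ~3 Hz,
#' reflecting the low-pass character of the pupillary response function.
#'
#' @param pred A `predicted_pupil` (at least ~8 loops long).
#' @param window_s,overlap Welch parameters (defaults 4.4 s, 0.75).
#' @return A tibble (`frequency_hz`, `psd`).
#' @export
prediction_spectrum <- function(pred, window_s = 4.4, overlap = 0.75) {
  stopifnot(inherits(pred, "predicted_pupil"))
  welch_psd(pred$prediction, rate_hz = attr(pred, "rate_hz"),
    window_s = window_s, overlap = overlap
  )
}
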