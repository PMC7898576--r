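#' A single reson filter
#'
#' A reson filter is a two-pole damped linear oscillator: an IIR resonator
#' that rings maximally when driven at its tuned frequency. The difference
#' equation is
#' \deqn{y[t] = g x[t] + 2 r \cos(\omega_0) y[t-1] - r^2 y[t-2]}
#' with \eqn{\omega_0 = 2\pi f / \mathrm{rate}} and constant-Q damping
#' \eqn{r = \exp(-\pi f / (Q \cdot \mathrm{rate}))}. The input gain `g` is
#' normalized so a steady sinusoid at the tuned frequency passes with unit
#' amplitude.
#'
#' @param x Numeric input series at `rate_hz`.
#' @param f_hz Tuned (resonant) frequency; must be below `rate_hz / 2`.
#' @param q Quality factor (default 10); larger means narrower tuning and
#'   longer ringing.
#' @param rate_hz Sampling rate of `x` (model rate, default 100 Hz).
#' @return Numeric vector, the filter output (same length as `x`).
#' @export
reson_filter <- function(x, f_hz, q = 10, rate_hz = 100) {
  co <- reson_coefficients(f_hz, q, rate_hz)
  as.numeric(stats::filter(co$g * x, c(co$a1, co$a2), method = "recursive"))
}

# Coefficients (a1, a2) and unit-resonance gain g for one reson filter.
reson_coefficients <- function(f_hz, q = 10, rate_hz = 100) {
  if (f_hz >= rate_hz / 2) {
    abort("`f_hz` must be below the Nyquist frequency of the model rate.")
  }
  if (f_hz <= 0 || q <= 0) abort("`f_hz` and `q` must be positive.")
  w0 <- 2 * pi * f_hz / rate_hz
  r <- exp(-pi * f_hz / (q * rate_hz))
  a1 <- 2 * r * cos(w0)
  a2 <- -r^2
  # |A(e^{i w0})| of the denominator 1 - a1 z^-1 - a2 z^-2
  z <- exp(-1i * w0)
  g <- Mod(1 - a1 * z - a2 * z^2)
  list(a1 = a1, a2 = a2, g = g, r = r)
}

#' A bank of reson filters
#'
#' 99 constant-Q reson filters with center frequencies logarithmically spaced
#' between 0.25 and 10 Hz — the periodicity range relevant for musical meter.
#'
#' @param n_filters Number of oscillators (default 99).
#' @param freq_range Lowest and highest tuned frequencies, Hz.
#' @param q Shared quality factor.
#' @param rate_hz Model rate the bank runs at.
#' @return A `reson_bank`: list with `frequencies_hz`, `q`, `rate_hz`.
#' @export
reson_bank <- function(n_filters = 99L, freq_range = c(0.25, 10), q = 10,
                       rate_hz = 100) {
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
    length.out = n_filters
  ))
  structure(
    list(frequencies_hz = freqs, q = q, rate_hz = rate_hz),
    class = "reson_bank"
  )
}

#' @export
print.reson_bank <- function(x, ...) {
  cat(sprintf(
    "<reson_bank: %d filters, %.2f-%.1f Hz (log-spaced), Q = %g, %g Hz rate>\n",
    length(x$frequencies_hz), min(x$frequencies_hz), max(x$frequencies_hz),
    x$q, x$rate_hz
  ))
  invisible(x)
}

#' Drive a reson bank with multi-band onset signals
#'
#' Feeds each of the onset bands through every filter of the bank. The
#' oscillators driven most strongly by periodicities present in the input
#' ring with the largest amplitude.
#'
#' @param onsets A `band_matrix` of onset signals at the bank's rate
#'   (typically the 5 reduced bands).
#' @param bank A [reson_bank()].
#' @return A `reson_output`: list with `values`, an array of dimension
#'   `n_bands x n_filters x n_frames`, plus `frequencies_hz`,
#'   `band_centers_hz` and `rate_hz`.
#' @export
reson_bank_apply <- function(onsets, bank = reson_bank()) {
  stopifnot(inherits(onsets, "band_matrix"), inherits(bank, "reson_bank"))
  if (onsets$rate_hz != bank$rate_hz) {
    abort("Onset matrix and reson bank rates differ.")
  }
  nb <- nrow(onsets$values)
  nf <- length(bank$frequencies_hz)
  nt <- ncol(onsets$values)
  out <- array(0, dim = c(nb, nf, nt))
  for (b in seq_len(nb)) {
    xb <- onsets$values[b, ]
    for (k in seq_len(nf)) {
      out[b, k, ] <- reson_filter(xb, bank$frequencies_hz[k],
        q = bank$q, rate_hz = bank$rate_hz
      )
    }
  }
  structure(
    list(
      values = out,
      frequencies_hz = bank$frequencies_hz,
      band_centers_hz = onsets$band_centers_hz,
      rate_hz = bank$rate_hz
    ),
    class = "reson_output"
  )
}

#' @export
print.reson_output <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<reson_output: %d bands x %d filters x %d frames at %g Hz>\n",
    d[1], d[2], d[3], x$rate_hz
  ))
  invisible(x)
}
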