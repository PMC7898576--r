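# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic generators in the
# package route their randomness through this so runs are reproducible from
# a single recorded seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Periodic Hann taper of length n (matches the common Welch convention).
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

# Moving RMS over a centered window of `width` samples.
moving_rms <- function(x, width) {
  stopifnot(width >= 1, width <= length(x))
  kernel <- rep(1 / width, width)
  ms <- stats::filter(x^2, kernel, sides = 2)
  # stats::filter leaves NAs at the edges; extend with the nearest value
  ms <- fill_edge_na(as.numeric(ms))
  sqrt(pmax(ms, 0))
}

fill_edge_na <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) {
    return(x)
  }
  if (ok[1] > 1L) x[seq_len(ok[1] - 1L)] <- x[ok[1]]
  last <- ok[length(ok)]
  if (last < length(x)) x[(last + 1L):length(x)] <- x[last]
  x
}

# Decimate `x` from `from_hz` to `to_hz` (integer factor) with a zero-phase
# anti-alias low-pass. Used wherever two signals must share a sample grid.
#' Resample a signal to a lower rate with anti-alias filtering
#'
#' Applies a zero-phase Butterworth low-pass at 80\% of the target Nyquist
#' frequency, then keeps every \code{from_hz / to_hz}-th sample. The ratio of
#' the two rates must be a whole number (e.g. 500 Hz eye-tracker samples down
#' to the 100 Hz model rate).
#'
#' @param x Numeric vector of samples.
#' @param from_hz,to_hz Source and target sampling rates in Hz.
#' @return Numeric vector at \code{to_hz}.
#' @export
resample_signal <- function(x, from_hz, to_hz) {
  if (from_hz == to_hz) {
    return(x)
  }
  factor <- from_hz / to_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    abort("`from_hz` must be an integer multiple of `to_hz`.")
  }
  factor <- as.integer(round(factor))
  bf <- signal::butter(4, 0.8 / factor, type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1L, length(y), by = factor)]
}

# Instantaneous amplitude of a real signal: modulus of the analytic signal
# (FFT-based Hilbert transform).
analytic_amplitude <- function(x) {
  n <- length(x)
  if (n < 2L) {
    return(abs(x))
  }
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# argmax that resolves ties to the first (earliest) index
which_max_first <- function(x) which(x == max(x))[1L]

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
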