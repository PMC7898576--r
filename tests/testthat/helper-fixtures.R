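# Shared fixtures, built once per test run and memoised. Audio-stage tests
# render at 20 kHz (an integer multiple of the 100 Hz model rate whose
# Nyquist clears the top cochlear band edge) to keep the suite quick; the
# model itself is rate-agnostic.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

fx_rate <- 20000

fx_model <- function(preset = "complex1-like", loops = 6) {
  memo(paste0("model_", preset, "_", loops), {
    oscillator_model(make_pattern(preset),
      loops = loops, sample_rate = fx_rate, seed = 42
    )
  })
}

fx_prf <- function(rate_hz = 100) {
  memo(paste0("prf_", rate_hz), prf_kernel(rate_hz = rate_hz))
}

# A simple synthetic one-loop salience series (impulse-like events), for
# tests that need a salience input without running the audio chain.
fx_salience <- function(loop_samples = 224, events = c(1, 75, 150),
                        rate_hz = 100) {
  v <- numeric(loop_samples)
  v[events] <- 1
  pupilbeat:::new_salience_series(v, rate_hz, "peak_masked")
}

# Direct single reson recursion, independent of the package's filter path.
brute_reson <- function(x, f_hz, q = 10, rate_hz = 100) {
  r <- exp(-pi * f_hz / (q * rate_hz))
  w0 <- 2 * pi * f_hz / rate_hz
  a1 <- 2 * r * cos(w0)
  a2 <- -r^2
  z <- exp(-1i * w0)
  g <- Mod(1 - a1 * z - a2 * z^2)
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    y1 <- if (t > 1) y[t - 1] else 0
    y2 <- if (t > 2) y[t - 2] else 0
    y[t] <- g * x[t] + a1 * y1 + a2 * y2
  }
  y
}
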