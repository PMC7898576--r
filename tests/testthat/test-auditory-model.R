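# Cochlear bands, onset detection, band reduction, reson filters, periodicity
# surfaces, the mean periodicity profile, and the salience variants.

test_that("cochlear bands localize a pure tone and handle edge inputs", {
  sr <- fx_rate
  t <- seq(0, 2 - 1 / sr, by = 1 / sr)
  tone <- audio_signal(0.5 * sin(2 * pi * 1000 * t), sr)
  bm <- cochlear_bands(tone)
  expect_equal(nrow(bm$values), 40L)
  expect_true(all(bm$values >= 0))
  # brute-force energy per band: the band whose center is nearest 1 kHz wins
  energy <- rowMeans(bm$values^2)
  expect_equal(which.max(energy), which.min(abs(bm$band_centers_hz - 1000)))
  expect_true(all(abs(range(bm$band_centers_hz) - c(141, 8877)) < 1e-6))

  silence <- audio_signal(numeric(sr), sr)
  expect_equal(max(cochlear_bands(silence)$values), 0)

  set.seed(2)
  noise <- audio_signal(stats::rnorm(sr) * 0.1, sr)
  expect_true(all(rowMeans(cochlear_bands(noise)$values^2) > 0))

  expect_error(cochlear_bands(audio_signal(numeric(0), sr)), "empty")
})

test_that("onset detection is the half-wave rectified first difference", {
  mk <- function(v) {
    pupilbeat:::band_matrix(matrix(v, nrow = 1), 1000, 100, "envelope")
  }
  # monotonically decreasing envelope -> all zeros
  expect_equal(max(detect_onsets(mk(seq(5, 1, length.out = 50)))$values), 0)
  # unit step at k -> single 1 at k
  step <- c(rep(0, 10), rep(1, 10))
  d <- detect_onsets(mk(step))$values[1, ]
  expect_equal(d, c(rep(0, 10), 1, rep(0, 9)))
  # ramp of slope s per sample -> constant s (after the zeroed first frame)
  ramp <- 0.25 * (0:19)
  d2 <- detect_onsets(mk(ramp))$values[1, ]
  expect_equal(d2[-1], rep(0.25, 19))
  expect_equal(d2[1], 0)
})

test_that("band reduction averages groups of adjacent bands", {
  set.seed(1)
  m <- matrix(runif(40 * 30), nrow = 40)
  bm <- pupilbeat:::band_matrix(m, exp(seq(log(141), log(8877), length.out = 40)),
    100, "onsets"
  )
  red <- reduce_bands(bm)
  expect_equal(dim(red$values), c(5L, 30L))
  # independent group-mean oracle
  oracle <- t(vapply(1:5, function(g) {
    colMeans(m[((g - 1) * 8 + 1):(g * 8), ])
  }, numeric(30)))
  expect_equal(red$values, oracle)
  # all ones -> all ones; single-band energy scaled by 1/8
  ones <- pupilbeat:::band_matrix(matrix(1, 40, 10), bm$band_centers_hz, 100, "x")
  expect_equal(reduce_bands(ones)$values, matrix(1, 5, 10))
  e1 <- matrix(0, 40, 10); e1[1, ] <- 1
  r1 <- reduce_bands(pupilbeat:::band_matrix(e1, bm$band_centers_hz, 100, "x"))
  expect_equal(r1$values[1, ], rep(1 / 8, 10))
  expect_equal(max(r1$values[-1, ]), 0)
  expect_error(reduce_bands(bm, group_size = 7), "divisible")
})

test_that("a reson filter passes its tuned sinusoid at unit amplitude", {
  rate <- 100
  for (f in c(0.5, 2, 8)) {
    t <- seq(0, 120 - 1 / rate, by = 1 / rate)
    y <- reson_filter(sin(2 * pi * f * t), f, q = 10, rate_hz = rate)
    steady <- y[(length(y) / 2):length(y)]
    expect_equal(max(abs(steady)), 1, tolerance = 0.02)
  }
  expect_equal(max(abs(reson_filter(numeric(100), 2))), 0)
  expect_error(reson_filter(rnorm(10), 50, rate_hz = 100), "Nyquist")
})

test_that("reson impulse response rings at the tuned frequency", {
  x <- c(1, numeric(999))
  y <- reson_filter(x, 2, q = 10, rate_hz = 100)
  # zero-crossing interval ~ half a period = 1/(2f) = 0.25 s = 25 samples
  crossings <- which(diff(sign(y[1:600])) != 0)
  intervals <- diff(crossings)
  expect_equal(median(intervals), 25, tolerance = 0.05)
  # matches the direct recursion oracle
  expect_equal(y, brute_reson(x, 2), tolerance = 1e-10)
})

test_that("the reson bank is linear and maximally driven near the stimulus rate", {
  x <- numeric(2000)
  x[seq(1, 2000, by = 50)] <- 1 # 2 Hz impulse train at 100 Hz
  bm <- pupilbeat:::band_matrix(matrix(x, nrow = 1), 1000, 100, "onsets")
  bank <- reson_bank()
  expect_length(bank$frequencies_hz, 99L)
  expect_true(all(diff(bank$frequencies_hz) > 0))
  ro <- reson_bank_apply(bm, bank)
  expect_equal(dim(ro$values), c(1L, 99L, 2000L))
  # silence -> zeros; linearity
  zero <- reson_bank_apply(
    pupilbeat:::band_matrix(matrix(0, 1, 100), 1000, 100, "onsets"), bank
  )
  expect_equal(max(abs(zero$values)), 0)
  bm2 <- pupilbeat:::band_matrix(matrix(2 * x, nrow = 1), 1000, 100, "onsets")
  ro2 <- reson_bank_apply(bm2, bank)
  expect_equal(ro2$values, 2 * ro$values, tolerance = 1e-12)
  # brute force RMS over all 99 filters: below the first harmonic the
  # energy maximum sits on the filter nearest 2 Hz
  rms <- vapply(seq_len(99), function(k) {
    sqrt(mean(brute_reson(x, bank$frequencies_hz[k])^2))
  }, numeric(1))
  sub <- which(bank$frequencies_hz < 3)
  expect_equal(
    sub[which.max(rms[sub])],
    which.min(abs(bank$frequencies_hz - 2))
  )
})

test_that("periodicity surfaces match a windowed-RMS oracle and average correctly", {
  set.seed(7)
  vals <- array(rnorm(2 * 4 * 400), dim = c(2, 4, 400))
  ro <- structure(
    list(values = vals, frequencies_hz = c(1, 2, 4, 8),
         band_centers_hz = c(500, 2000), rate_hz = 100),
    class = "reson_output"
  )
  ps <- periodicity_surface(ro, window_s = 1, hop_s = 0.1)
  L <- 100; hop <- 10
  starts <- seq(1, 400 - L + 1, by = hop)
  oracle <- sqrt(mean(vals[2, 3, starts[5]:(starts[5] + L - 1)]^2))
  expect_equal(ps$energy[2, 3, 5], oracle)
  # constant reson output c -> surface constant c
  cvals <- array(0.7, dim = c(1, 2, 300))
  roc <- structure(
    list(values = cvals, frequencies_hz = c(1, 2), band_centers_hz = 500,
         rate_hz = 100),
    class = "reson_output"
  )
  psc <- periodicity_surface(roc, window_s = 2, hop_s = 0.01)
  expect_equal(range(psc$energy), c(0.7, 0.7))
  # identical bands -> average equals each band
  same <- array(rep(vals[1, , ], each = 2), dim = c(2, 4, 400))
  ros <- ro; ros$values <- same
  avg <- average_surface(periodicity_surface(ros, 1, 0.1))
  one <- periodicity_surface(ro, 1, 0.1)$energy[1, , ]
  expect_equal(avg$energy, one)
  expect_error(periodicity_surface(ro, window_s = 0.05, hop_s = 0.1), "hop")
})

test_that("MPP peak picking follows the 5%-of-range rule", {
  mk_aps <- function(profile) {
    structure(
      list(energy = matrix(profile, ncol = 1),
           frequencies_hz = seq_along(profile), times_s = 0,
           window_s = 2, hop_s = 0.01, rate_hz = 100),
      class = "periodicity_surface"
    )
  }
  # flat profile -> no peaks
  expect_length(peak_frequencies(mean_periodicity_profile(mk_aps(rep(1, 20)))), 0L)
  # all-zero surface -> empty peak set, not an error
  expect_length(peak_frequencies(mean_periodicity_profile(mk_aps(rep(0, 20)))), 0L)
  # single spike -> exactly one peak
  spike <- rep(0, 20); spike[10] <- 1
  expect_equal(peak_frequencies(mean_periodicity_profile(mk_aps(spike))), 10)
  # a local max below the 5% threshold is not a peak
  low <- c(0, 0.04, 0, rep(c(0, 1), 5), rep(0, 7))
  mpp <- mean_periodicity_profile(mk_aps(low))
  expect_false(2 %in% peak_frequencies(mpp))
  # MPP peaks of a real stimulus stay within the bank range
  pk <- peak_frequencies(fx_model()$mpp)
  expect_true(all(pk >= 0.25 & pk <= 10))
})

test_that("2 Hz impulse train puts an MPP peak on the filter nearest 2 Hz", {
  x <- numeric(3000)
  x[seq(1, 3000, by = 50)] <- 1
  bm <- pupilbeat:::band_matrix(matrix(x, nrow = 1), 1000, 100, "onsets")
  bank <- reson_bank()
  mpp <- mean_periodicity_profile(
    average_surface(periodicity_surface(reson_bank_apply(bm, bank)))
  )
  pk <- peak_frequencies(mpp)
  nearest2 <- bank$frequencies_hz[which.min(abs(bank$frequencies_hz - 2))]
  expect_true(nearest2 %in% pk)
  expect_equal(pk[which.min(abs(pk - 2))], nearest2)
})

test_that("tempo covariance: time-stretching shifts MPP peaks by 1/s", {
  train <- function(period) {
    x <- numeric(4000)
    x[seq(1, 4000, by = period)] <- 1
    pupilbeat:::band_matrix(matrix(x, nrow = 1), 1000, 100, "onsets")
  }
  bank <- reson_bank()
  peak_near <- function(bm, f) {
    pk <- peak_frequencies(mean_periodicity_profile(
      average_surface(periodicity_surface(reson_bank_apply(bm, bank)))
    ))
    pk[which.min(abs(pk - f))]
  }
  f1 <- peak_near(train(50), 2) # 2 Hz train
  f2 <- peak_near(train(100), 1) # stretched by s = 2 -> 1 Hz
  expect_equal(f2, f1 / 2, tolerance = 0.05) # nearest-filter resolution
})

test_that("salience variants equal their brute-force definitions", {
  m <- fx_model()
  ro <- m$reson
  mpp <- m$mpp
  keep <- which(mpp$is_peak)
  oracle <- colMeans(matrix(
    abs(ro$values[, keep, , drop = FALSE]),
    ncol = dim(ro$values)[3]
  ))
  sal <- temporal_salience(ro, mpp, "peak_masked", amplitude = "rectified")
  expect_equal(sal$salience, oracle)
  expect_true(all(sal$salience >= 0))
  # analytic amplitude dominates the rectified output and shares its scale
  sal_a <- temporal_salience(ro, mpp, "peak_masked", amplitude = "analytic")
  expect_true(all(sal_a$salience >= 0))
  expect_gt(cor(sal_a$salience, sal$salience), 0.8)
  # full_reson on zero input -> zero series
  zero_ro <- ro
  zero_ro$values[] <- 0
  expect_equal(max(temporal_salience(zero_ro, variant = "full_reson")$salience), 0)
  # peak_masked demands a nonempty peak set
  empty_mpp <- mpp
  empty_mpp$is_peak <- FALSE
  expect_error(temporal_salience(ro, empty_mpp, "peak_masked"), "empty")
  # one-loop salience has loop length +/- 1 sample
  expect_equal(nrow(m$salience), m$loop_samples)
})

test_that("scaling audio scales salience without moving the peak set", {
  p <- make_pattern("sparse1-like")
  a <- render_loop(p, sample_rate = fx_rate, seed = 2)
  m1 <- oscillator_model(a, loops = 4)
  a2 <- audio_signal(0.5 * a$samples, a$sample_rate)
  m2 <- oscillator_model(a2, loops = 4)
  expect_equal(peak_frequencies(m2$mpp), peak_frequencies(m1$mpp))
  expect_equal(m2$salience$salience, 0.5 * m1$salience$salience,
    tolerance = 1e-6
  )
})

test_that("amplitude envelope has the RMS closed form and tracks AM rate", {
  sr <- fx_rate
  t <- seq(0, 3 - 1 / sr, by = 1 / sr)
  tone <- audio_signal(0.8 * sin(2 * pi * 220 * t), sr)
  env <- amplitude_envelope(tone)
  steady <- env$salience[50:250]
  expect_equal(mean(steady), 0.8 / sqrt(2), tolerance = 0.01)
  # silence -> zero envelope
  expect_equal(max(amplitude_envelope(audio_signal(numeric(sr), sr))$salience), 0)
  # 2 Hz amplitude-modulated noise -> envelope spectrum peaks at 2 Hz
  set.seed(8)
  am <- audio_signal((1 + sin(2 * pi * 2 * t)) / 2 * rnorm(length(t), sd = 0.2), sr)
  enva <- amplitude_envelope(am)
  v <- enva$salience - mean(enva$salience)
  spec <- Mod(fft(v))^2
  freqs <- (seq_along(v) - 1) * 100 / length(v)
  band <- freqs > 0.5 & freqs < 50
  expect_equal(freqs[band][which.max(spec[band])], 2, tolerance = 0.2)
  expect_error(
    amplitude_envelope(audio_signal(numeric(100), sr), rms_window_ms = 50),
    "longer"
  )
})

test_that("peak-masked and amplitude-envelope salience correlate on metrically plain presets", {
  # The causal resonator path rings a few tens of ms after each onset while
  # the envelope is extracted zero-phase, so the correlation is taken at the
  # best alignment within +/- 50 ms. The heavily offbeat preset is excluded:
  # peak-periodicity masking encodes meter, not instantaneous energy, and
  # deliberately decouples from the envelope there (it stays positively
  # correlated, checked separately below).
  env_cor <- function(nm) {
    m <- fx_model(nm)
    a <- render_loop(make_pattern(nm), sample_rate = fx_rate, seed = 42)
    env <- amplitude_envelope(audio_signal(rep(a$samples, 6), a$sample_rate))
    n <- nrow(m$salience)
    env_loop <- env$salience[(length(env$salience) - n + 1):length(env$salience)]
    max(ccf(m$salience$salience, env_loop, lag.max = 5, plot = FALSE)$acf)
  }
  rs <- vapply(names(pattern_presets()), env_cor, numeric(1))
  expect_true(all(rs > 0.3))
  # straight-accented presets correlate strongly; the offbeat and
  # double-time-accented ones trade envelope correspondence for metrical
  # structure, which is the model's point
  expect_gte(sum(rs > 0.7), 3L)
})
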