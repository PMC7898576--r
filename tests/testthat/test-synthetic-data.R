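# Rhythm patterns, loop rendering, deviant scheduling and insertion, and the
# synthetic pupil generator.

test_that("pattern geometry follows tempo and grid size", {
  p <- make_pattern("complex1-like", tempo_bpm = 107, n_positions = 16)
  expect_equal(round(1000 * p$grid_interval_s), 140)
  expect_equal(round(p$loop_duration_s, 1), 2.2)
  # general formula on a different tempo/grid
  p2 <- make_pattern(
    tracks = tibble::tibble(timbre = "snap", position = c(1L, 5L), velocity = 1),
    tempo_bpm = 120, n_positions = 8
  )
  expect_equal(p2$grid_interval_s, 60 / (120 * 8 / 4))
})

test_that("degenerate pattern specs are rejected", {
  expect_error(make_pattern(tracks = tibble::tibble(
    timbre = character(0), position = integer(0), velocity = numeric(0)
  )), "no onsets")
  expect_error(make_pattern("complex1-like", tempo_bpm = 0), "positive")
  expect_error(make_pattern(tracks = tibble::tibble(
    timbre = "snap", position = 1L, velocity = 1.5
  )), "Velocities")
  expect_error(make_pattern("no-such-preset"), "Unknown preset")
})

test_that("all presets are valid and mutually distinct", {
  presets <- pattern_presets()
  expect_gte(length(presets), 5L)
  grids <- purrr::map_chr(names(presets), function(nm) {
    p <- make_pattern(nm)
    paste(sort(paste(p$tracks$timbre, p$tracks$position)), collapse = ";")
  })
  expect_equal(anyDuplicated(grids), 0L)
})

test_that("rendered loops concentrate energy after onsets and scale with velocity", {
  one <- make_pattern(tracks = tibble::tibble(
    timbre = "snap", position = 5L, velocity = 0.4
  ))
  a <- render_loop(one, sample_rate = fx_rate, seed = 7)
  sr <- a$sample_rate
  onset <- round((5 - 1) * one$grid_interval_s * sr)
  pre <- a$samples[1:(onset - 10)]
  post <- a$samples[(onset + 1):(onset + round(0.05 * sr))]
  expect_equal(max(abs(pre)), 0)
  expect_gt(sqrt(mean(post^2)), 0)
  # doubling every velocity doubles the waveform (fixed master gain)
  two <- make_pattern(tracks = tibble::tibble(
    timbre = "snap", position = 5L, velocity = 0.8
  ))
  b <- render_loop(two, sample_rate = fx_rate, seed = 7)
  expect_gt(sqrt(mean(b$samples^2)), sqrt(mean(a$samples^2)))
  expect_equal(b$samples, 2 * a$samples, tolerance = 1e-12)
})

test_that("a 2 Hz isochronous click loop has an envelope autocorrelation peak at 500 ms", {
  # 2 s loop, clicks every 0.5 s: 4 positions, 120 BPM, 4 beats
  p <- make_pattern(
    tracks = tibble::tibble(timbre = "snap", position = 1:4, velocity = 1),
    n_positions = 4, tempo_bpm = 120, beats_per_loop = 4
  )
  expect_equal(p$grid_interval_s, 0.5)
  a <- render_loop(p, sample_rate = fx_rate, seed = 3)
  env <- amplitude_envelope(a)
  # brute-force autocorrelation of the demeaned envelope at positive lags
  v <- env$salience - mean(env$salience)
  lags <- 10:90 # 100 ms .. 900 ms at 100 Hz
  ac <- vapply(lags, function(k) {
    sum(v[1:(length(v) - k)] * v[(k + 1):length(v)])
  }, numeric(1))
  expect_equal(lags[which.max(ac)], 50, tolerance = 0.02)
})

test_that("loop rendering is circular: k tiled loops equal k concatenated renders", {
  # 120 BPM makes the loop an exact number of samples, so tiling is
  # sample-exact rather than subject to per-loop rounding
  p <- make_pattern(
    tracks = pattern_presets()[["syncopated1-like"]],
    tempo_bpm = 120
  )
  one <- render_loop(p, sample_rate = fx_rate, seed = 11)
  tiled <- render_loop(pupilbeat:::tile_pattern(p, 3),
    sample_rate = fx_rate, seed = 11
  )
  expect_equal(tiled$samples, rep(one$samples, 3), tolerance = 1e-9)
})

test_that("rendering is deterministic given pattern and seed", {
  p <- make_pattern("dense1-like")
  expect_identical(
    render_loop(p, sample_rate = fx_rate, seed = 5)$samples,
    render_loop(p, sample_rate = fx_rate, seed = 5)$samples
  )
  expect_error(render_loop(p, sample_rate = 4000), "8000")
})

test_that("schedules respect the deviant grammar", {
  sch <- schedule_run(20, 0.8, c(2, 6, 9, 14), seed = 1)
  k <- sch$kind
  # never two consecutive deviants
  expect_equal(sum(k[-1] == "deviant" & k[-length(k)] == "deviant"), 0L)
  # exact quota per position
  expect_equal(as.integer(table(sch$probe_position)), rep(20L, 4))
  # without-replacement blocks of 4
  pos <- sch$probe_position[!is.na(sch$probe_position)]
  blocks <- matrix(pos, nrow = 4)
  expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 4L)))
  # reproducible
  expect_identical(sch, schedule_run(20, 0.8, c(2, 6, 9, 14), seed = 1))
})

test_that("p_deviant = 1 gives strict standard/deviant alternation", {
  sch <- schedule_run(5, 1, c(1, 2, 3, 4), seed = 2)
  k <- head(sch$kind, -1) # drop the trailing closing standard
  expect_equal(unique(k[seq(1, length(k), by = 2)]), "standard")
  expect_equal(unique(k[seq(2, length(k), by = 2)]), "deviant")
})

test_that("the deviant-after-standard rate converges to p_deviant", {
  sch <- schedule_run(600, 0.8, c(1, 2, 3, 4), seed = 9, max_loops = 2e4)
  n_std <- sum(head(sch$kind, -1) == "standard")
  rate <- deviant_after_standard_rate(sch)
  ci <- qbinom(c(0.005, 0.995), n_std, 0.8) / n_std
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("schedule validation and degenerate paths work", {
  expect_error(schedule_run(20, 0.8, c(1, 1, 2, 3)), "distinct")
  expect_error(schedule_run(20, 1.2, c(1, 2, 3, 4)), "0, 1")
  expect_warning(
    sch0 <- schedule_run(2, 0, c(1, 2, 3, 4), seed = 1, max_loops = 50),
    "quota"
  )
  expect_false(attr(sch0, "quota_met"))
  expect_equal(unique(sch0$kind), "standard")
})

test_that("insert_deviant scales exactly the probed window", {
  p <- make_pattern("complex1-like")
  a <- render_loop(p, sample_rate = fx_rate, seed = 1)
  probe_t <- (9 - 1) * p$grid_interval_s
  out <- insert_deviant(a, probe_t, duration_ms = 200, delta_db = 6.0206)
  sr <- a$sample_rate
  i0 <- round(probe_t * sr) + 1
  idx <- i0:(i0 + round(0.2 * sr) - 1)
  expect_equal(length(idx), round(0.2 * sr)) # 200 ms of samples
  expect_identical(out$samples[-idx], a$samples[-idx]) # bit-identical outside
  nz <- idx[a$samples[idx] != 0]
  expect_equal(out$samples[nz] / a$samples[nz], rep(2, length(nz)),
    tolerance = 1e-4
  )
  # identity at 0 dB, error when the window wraps
  expect_identical(insert_deviant(a, probe_t, 200, 0)$samples, a$samples)
  expect_error(insert_deviant(a, a$duration_s - 0.1, 200, 3), "wrap")
})

test_that("synth_pupil with all noise sources off is the convolved prediction", {
  sal <- fx_salience()
  prf <- fx_prf()
  log <- synth_pupil(sal, prf,
    n_loops = 8, noise_sd = 0, blink_rate_hz = 0,
    drift_amplitude = 0, seed = 1
  )
  expect_equal(nrow(log), 8 * 224 * 5)
  expect_equal(attr(log, "fraction_missing"), 0)
  # reconstruct the tiled convolved prediction independently
  x <- rep(sal$salience, 8)
  k <- prf$h
  pred <- numeric(length(x))
  for (i in seq_along(k)) {
    pred <- pred + c(rep(0, i - 1), k[i] * x)[seq_along(x)]
  }
  pred <- pred / max(abs(pred))
  ref <- approx((seq_along(pred) - 1) / 100, pred,
    xout = (seq_len(nrow(log)) - 1) / 500, rule = 2
  )$y
  expect_equal(log$pupil, 1000 + 30 * ref, tolerance = 1e-6)
})

test_that("synth_pupil blink artifacts and determinism behave", {
  sal <- fx_salience()
  log <- synth_pupil(sal, fx_prf(), n_loops = 20, blink_rate_hz = 0.3, seed = 4)
  expect_gt(attr(log, "fraction_missing"), 0)
  expect_true(all(is.na(log$pupil[log$blink == 1])))
  log2 <- synth_pupil(sal, fx_prf(), n_loops = 20, blink_rate_hz = 0.3, seed = 4)
  expect_identical(log$pupil, log2$pupil)
  expect_error(synth_pupil(sal, fx_prf(), noise_sd = -1), ">= 0")
  # loop markers present at the loop period
  loops <- which(log$event == "loop")
  expect_equal(length(loops), 20L)
  expect_equal(unique(diff(loops)), 224 * 5)
})
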