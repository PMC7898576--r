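#' Rhythm patterns on a metrical grid
#'
#' A rhythm pattern places percussive onsets of several timbres on a discrete
#' grid of equally spaced positions within one loop. With the defaults
#' (16 positions, 107 BPM, 4 beats per loop) the grid interval is 140 ms and a
#' loop lasts 2.24 s, matching the short multi-timbre percussion loops the
#' pipeline is designed around.
#'
#' Five built-in presets span sparse to dense onset profiles with varying
#' syncopation; all are deterministic. A custom pattern is given as `tracks`,
#' a data frame with columns `timbre` (one of `"snap"`, `"shaker"`, `"conga"`),
#' `position` (1-based grid index) and `velocity` (in (0, 1]).
#'
#' @param preset Name of a built-in pattern (see [pattern_presets()]), ignored
#'   when `tracks` is supplied.
#' @param tracks Optional data frame of onsets (see Details).
#' @param n_positions Grid length per loop.
#' @param tempo_bpm Tempo in beats per minute.
#' @param beats_per_loop Number of beats spanned by one loop.
#' @return A `rhythm_pattern`: list with `tracks` (tibble), `n_positions`,
#'   `tempo_bpm`, `beats_per_loop`, `grid_interval_s`, `loop_duration_s`.
#' @examples
#' p <- make_pattern("complex1-like")
#' p$grid_interval_s # 0.1402 s = 140 ms grid
#' p$loop_duration_s # 2.243 s per loop
#' @export
make_pattern <- function(preset = "complex1-like", tracks = NULL,
                         n_positions = 16L, tempo_bpm = 107,
                         beats_per_loop = 4L) {
  if (tempo_bpm <= 0) abort("`tempo_bpm` must be positive.")
  if (n_positions < 1) abort("`n_positions` must be a positive integer.")
  if (is.null(tracks)) {
    presets <- pattern_presets()
    if (!preset %in% names(presets)) {
      abort(sprintf(
        "Unknown preset '%s'. Available: %s.",
        preset, paste(names(presets), collapse = ", ")
      ))
    }
    tracks <- presets[[preset]]
  } else {
    preset <- "custom"
  }
  tracks <- as_tibble(tracks)
  required <- c("timbre", "position", "velocity")
  if (!all(required %in% names(tracks))) {
    abort("`tracks` needs columns timbre, position, velocity.")
  }
  if (nrow(tracks) == 0L) {
    abort("Pattern has no onsets: at least one onset is required.")
  }
  if (any(tracks$position < 1 | tracks$position > n_positions)) {
    abort("Track positions must lie in 1..n_positions.")
  }
  if (any(tracks$velocity <= 0 | tracks$velocity > 1)) {
    abort("Velocities must lie in (0, 1].")
  }
  grid_interval_s <- 60 / (tempo_bpm * n_positions / beats_per_loop)
  structure(
    list(
      name = preset,
      tracks = arrange(tracks, .data$position, .data$timbre),
      n_positions = as.integer(n_positions),
      tempo_bpm = tempo_bpm,
      beats_per_loop = as.integer(beats_per_loop),
      grid_interval_s = grid_interval_s,
      loop_duration_s = n_positions * grid_interval_s
    ),
    class = "rhythm_pattern"
  )
}

#' Built-in rhythm pattern presets
#'
#' Generic 16-position, three-timbre patterns spanning sparse to dense onset
#' profiles with differing amounts of syncopation. Onsets on grid positions
#' 1, 5, 9, 13 fall on the beat (4 beats per 16-position loop); even
#' positions are offbeat eighths/sixteenths. Each preset carries a dynamic
#' accent cycle — onset velocities wax and wane at one characteristic
#' metrical periodicity (half-note, whole-bar, beat, ...) — so the presets
#' emphasize different prominent periodicities, the way a varied battery of
#' drum loops does, rather than all sharing one flat metrical profile.
#'
#' @return Named list of track tibbles usable with [make_pattern()].
#' @export
pattern_presets <- function() {
  tr <- function(timbre, position, velocity) {
    tibble(timbre = timbre, position = as.integer(position), velocity = velocity)
  }
  # velocities accented at grid harmonic k (k cycles per 16-position loop):
  # 107 BPM -> k = 1 is the 0.45 Hz bar cycle, k = 4 the 1.78 Hz beat
  accent <- function(position, k, lo = 0.15, hi = 1, phase = 0) {
    lo + (hi - lo) * (0.5 + 0.5 * cos(2 * pi * k * (position - 1) / 16 + phase))
  }
  preset <- function(k, conga_pos, snap_pos, shaker_pos, phase = 0) {
    bind_rows(
      tr("conga", conga_pos, accent(conga_pos, k, phase = phase)),
      tr("snap", snap_pos, accent(snap_pos, k, phase = phase)),
      tr("shaker", shaker_pos, accent(shaker_pos, k, phase = phase))
    )
  }
  list(
    # beat-accented (1.78 Hz), moderately dense
    "complex1-like" = preset(4, c(1, 5, 9, 13), c(7, 15), 1:16),
    # double-time accents (2.68 Hz), dense offbeat shaker
    "complex2-like" = preset(6, c(1, 7, 9, 15), c(5, 13), 1:16),
    # dotted accents (1.34 Hz) over a full sixteenth carpet
    "dense1-like" = preset(3, c(1, 5, 9, 13), c(3, 7, 11, 15), 1:16),
    # half-note accents (0.89 Hz), sparse
    "sparse1-like" = preset(2, c(1, 9), c(5, 13), seq(1, 15, by = 2)),
    # bar-cycle accents (0.45 Hz) on offbeat positions
    "syncopated1-like" = preset(
      1, c(2, 4, 10, 12), c(6, 14, 16), seq(2, 16, by = 2),
      phase = pi / 2
    )
  )
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  cat(sprintf(
    "<rhythm_pattern '%s': %d positions, %g BPM, grid %.1f ms, loop %.3f s, %d onsets>\n",
    x$name, x$n_positions, x$tempo_bpm, 1000 * x$grid_interval_s,
    x$loop_duration_s, nrow(x$tracks)
  ))
  invisible(x)
}

# Onset times (s) within the loop for every track row.
pattern_onset_times <- function(pattern) {
  (pattern$tracks$position - 1) * pattern$grid_interval_s
}

# Tile a pattern k times onto a k-fold grid (used by rendering invr. tests).
tile_pattern <- function(pattern, k) {
  tracks <- purrr::map(seq_len(k) - 1L, function(i) {
    mutate(pattern$tracks, position = .data$position + i * pattern$n_positions)
  })
  make_pattern(
    tracks = bind_rows(tracks),
    n_positions = pattern$n_positions * k,
    tempo_bpm = pattern$tempo_bpm,
    beats_per_loop = pattern$beats_per_loop * k
  )
}
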