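# File formats: RIFF/WAV audio, tab-separated pupil logs, CSV schedules and
# tables, YAML run configs. The WAV reader/writer is a minimal RIFF
# implementation (PCM 16-bit and IEEE float32, mono or the first channel).

#' Write an audio signal as a WAV file
#'
#' @param audio An [audio_signal()].
#' @param path Output path.
#' @param format `"float32"` (exact for rendered audio) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(audio, "audio_signal"))
  format <- match.arg(format)
  samples <- audio$samples
  sr <- as.integer(audio$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bits <- 16L
    fmt_code <- 1L
    pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    data_bytes <- length(pcm) * 2L
  } else {
    bits <- 32L
    fmt_code <- 3L
    data_bytes <- length(samples) * 4L
  }
  block_align <- bits %/% 8L
  fact <- format == "float32"
  riff_size <- 4L + (8L + 16L) + (if (fact) 8L + 4L else 0L) + 8L + data_bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(riff_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  if (fact) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(length(samples), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE float32; multi-channel files yield the first
#' channel.
#'
#' @param path WAV file path.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") abort("Not a RIFF file.")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") abort("Not a WAVE file.")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little")
      )
      readBin(con, raw(), n = size - 8L)
    } else if (id == "data") {
      if (is.null(fmt)) abort("Malformed WAV: data before fmt chunk.")
      if (fmt$code == 1L) {
        raw_s <- readBin(con, integer(), n = size %/% 2L, size = 2,
          endian = "little", signed = TRUE
        )
        samples <- raw_s / 32767
      } else if (fmt$code == 3L) {
        samples <- readBin(con, numeric(), n = size %/% 4L, size = 4,
          endian = "little"
        )
      } else {
        abort(sprintf("Unsupported WAV format code %d.", fmt$code))
      }
      if (fmt$channels > 1L) {
        samples <- samples[seq(1L, length(samples), by = fmt$channels)]
      }
    } else {
      readBin(con, raw(), n = size)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort("Malformed WAV: no data chunk found.")
  audio_signal(samples, fmt$rate)
}

# Header line carrying provenance; every text output starts with one.
provenance_header <- function(config_hash = NA_character_, seed = NA_integer_) {
  sprintf("# pupilbeat config=%s seed=%s", config_hash, seed)
}

#' Write / read a raw pupil log as tab-separated text
#'
#' Columns `time_ms`, `pupil`, `blink`, `saccade`, `event`; a leading `#`
#' comment line records the config hash and seed. [read_pupil_log()]
#' validates that time is strictly increasing.
#'
#' @param log A `pupil_log` tibble.
#' @param path File path.
#' @param config_hash,seed Provenance recorded in the header comment.
#' @return `path` (write) or a `pupil_log` tibble (read).
#' @export
write_pupil_log <- function(log, path, config_hash = NA_character_,
                            seed = attr(log, "seed") %||% NA_integer_) {
  writeLines(provenance_header(config_hash, seed), path)
  readr::write_tsv(as_tibble(log), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @param sample_rate_hz Rate recorded on the returned log.
#' @rdname write_pupil_log
#' @export
read_pupil_log <- function(path, sample_rate_hz = 500) {
  out <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      time_ms = "d", pupil = "d", blink = "i", saccade = "i", event = "c"
    )
  )
  if (any(diff(out$time_ms) <= 0)) {
    abort("Malformed pupil log: time must be strictly increasing.")
  }
  out$event[is.na(out$event)] <- ""
  class(out) <- c("pupil_log", class(out))
  attr(out, "sample_rate_hz") <- sample_rate_hz
  out
}

#' Write / read a deviant schedule as CSV
#'
#' @param schedule A [schedule_run()] tibble.
#' @param path File path.
#' @param config_hash Provenance recorded in the header comment.
#' @return `path` (write) or the schedule tibble (read).
#' @export
write_schedule <- function(schedule, path, config_hash = NA_character_) {
  writeLines(provenance_header(config_hash, attr(schedule, "seed")), path)
  readr::write_csv(as_tibble(schedule), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      loop_index = "i", kind = "c", probe_position = "i"
    )
  )
  attr(out, "probe_positions") <-
    sort(unique(out$probe_position[!is.na(out$probe_position)]))
  out
}

#' Default run configuration
#'
#' A fully serializable list of every tunable the pipeline uses: pattern,
#' tempo, probe positions, ZEST, PRF, preprocessing and coherence
#' parameters, seeds. Written and read as YAML.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    pattern = list(preset = "complex1-like", n_positions = 16L,
      tempo_bpm = 107, beats_per_loop = 4L),
    audio = list(sample_rate = 44100),
    probe_positions = c(2L, 6L, 9L, 14L),
    schedule = list(n_observations_per_position = 20L, p_deviant = 0.8),
    zest = list(prior_mean_db = 10, prior_sd_db = 6, grid_min = -10,
      grid_max = 30, grid_step = 0.1, sigma_db = 2, gamma = 0.02,
      lambda = 0.02, response_window_ms = 1000),
    observer = list(true_threshold_db = 6, slope_db = 2, lapse_rate = 0.02,
      false_alarm_rate = 0.02),
    prf = list(n = 10.1, t_max_ms = 512),
    deviant = list(duration_ms = 200),
    model = list(loops = 10L, window_s = 2, hop_s = 0.01),
    pupil = list(n_loops = 60L, noise_sd = 4, blink_rate_hz = 0.1,
      drift_amplitude = 15),
    preprocess = list(jump_threshold = 20, pad_samples = 25L,
      max_fraction = 0.30, highpass_hz = 0.05),
    coherence = list(window_s = 4.4, overlap = 0.75, fmax_hz = 3),
    seed = 1L
  )
}

#' Write / read a run configuration as YAML
#' @param config Configuration list (see [default_config()]).
#' @param path File path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
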