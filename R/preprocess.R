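#' Mark artifacts in a raw pupil log
#'
#' Sets to missing every sample flagged as blink or saccade, plus any sample
#' whose pupil value exceeds the preceding sample by more than
#' `jump_threshold` arbitrary units, then pads every missing run by
#' `pad_samples` on each side to remove edge artifacts (25 samples = 50 ms at
#' 500 Hz).
#'
#' @param raw A `pupil_log` tibble (see [synth_pupil()] /
#'   [read_pupil_log()]).
#' @param jump_threshold Sample-to-sample increase, in the log's arbitrary
#'   units, above which a sample is treated as artifactual (default 20).
#' @param pad_samples Samples removed on each side of every missing run
#'   (default 25).
#' @return The log with `pupil` set `NA` at artifacts and a logical
#'   `artifact` column; attribute `fraction_missing` updated.
#' @export
mark_artifacts <- function(raw, jump_threshold = 20, pad_samples = 25L) {
  stopifnot(is.data.frame(raw), all(c("pupil", "blink", "saccade") %in% names(raw)))
  p <- raw$pupil
  bad <- is.na(p) | raw$blink > 0 | raw$saccade > 0
  jump <- c(FALSE, diff(p) > jump_threshold)
  jump[is.na(jump)] <- FALSE
  bad <- bad | jump
  bad <- pad_runs(bad, pad_samples)
  out <- raw
  out$pupil[bad] <- NA_real_
  out$artifact <- bad
  attr(out, "sample_rate_hz") <- attr(raw, "sample_rate_hz")
  attr(out, "fraction_missing") <- mean(bad)
  out
}

# Expand every TRUE run of `bad` by `pad` samples on both sides.
pad_runs <- function(bad, pad) {
  if (!any(bad) || pad < 1L) {
    return(bad)
  }
  idx <- which(bad)
  padded <- unique(as.vector(outer(idx, -pad:pad, `+`)))
  padded <- padded[padded >= 1L & padded <= length(bad)]
  out <- logical(length(bad))
  out[padded] <- TRUE
  out
}

#' Interpolate missing pupil data and screen by interpolation budget
#'
#' Imputes missing samples by linear interpolation between the flanking valid
#' samples; leading/trailing missing runs are filled by nearest-valid-value
#' extension. Traces requiring `max_fraction` (default 30\%) or more
#' interpolation are rejected rather than cleaned.
#'
#' @param masked A log from [mark_artifacts()].
#' @param max_fraction Rejection threshold on the missing fraction.
#' @return On acceptance, the log with `pupil` gap-free, a logical
#'   `interpolated` column, and attributes `fraction_interpolated`,
#'   `accepted = TRUE`, `stage = "interpolated"`. On rejection, the input
#'   unchanged with `accepted = FALSE` (check with [trace_accepted()]).
#' @export
interpolate_and_screen <- function(masked, max_fraction = 0.30) {
  stopifnot(is.data.frame(masked), "pupil" %in% names(masked))
  miss <- is.na(masked$pupil)
  frac <- mean(miss)
  out <- masked
  attr(out, "fraction_interpolated") <- frac
  if (frac >= max_fraction) {
    attr(out, "accepted") <- FALSE
    warn(sprintf(
      "Trace rejected: %.1f%% of samples need interpolation (budget %.0f%%).",
      100 * frac, 100 * max_fraction
    ))
    return(out)
  }
  if (any(miss)) {
    if (all(miss)) abort("No valid samples to interpolate from.")
    ok <- which(!miss)
    out$pupil <- approx(
      x = ok, y = masked$pupil[ok],
      xout = seq_along(masked$pupil), rule = 2
    )$y
  }
  out$interpolated <- miss
  attr(out, "accepted") <- TRUE
  attr(out, "stage") <- "interpolated"
  out
}

#' Did a trace survive screening?
#' @param trace Output of [interpolate_and_screen()].
#' @return Logical.
#' @export
trace_accepted <- function(trace) isTRUE(attr(trace, "accepted"))

#' High-pass filter and z-score a cleaned pupil trace
#'
#' Removes slow drift with a 3rd-order Butterworth high-pass at 0.05 Hz
#' applied forward-backward (zero phase, so event-locked latencies are
#' preserved), then normalizes:
#' `z = (x - mean(x)) / sd(x)`.
#'
#' @param trace A gap-free trace from [interpolate_and_screen()].
#' @param cutoff_hz High-pass cutoff (default 0.05 Hz).
#' @param order Butterworth order (default 3).
#' @return The trace with `pupil` z-scored (mean 0, SD 1); attribute
#'   `stage = "zscored"`.
#' @export
highpass_and_zscore <- function(trace, cutoff_hz = 0.05, order = 3L) {
  stopifnot(is.data.frame(trace), "pupil" %in% names(trace))
  if (anyNA(trace$pupil)) abort("Trace still contains missing samples; interpolate first.")
  rate <- attr(trace, "sample_rate_hz") %||% 500
  x <- trace$pupil
  if (sd(x) == 0) abort("Trace has zero variance; cannot z-score.")
  if (length(x) / rate < 60) {
    warn("Trace is shorter than 60 s; the 0.05 Hz high-pass is poorly resolved.")
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "high")
  y <- as.numeric(signal::filtfilt(bf, x))
  y <- (y - mean(y)) / sd(y)
  out <- trace
  out$pupil <- y
  attr(out, "sample_rate_hz") <- rate
  attr(out, "stage") <- "zscored"
  out
}

#' Epoch the pupil dilation response around deviant onsets
#'
#' Time-locks the cleaned trace to each event, subtracts the mean of the
#' 200 ms pre-onset baseline, and keeps onset through `window_ms` (default
#' 3000 ms). Per-epoch features follow: mean and max evoked amplitude,
#' latency from onset to the epoch maximum, velocity as the two-point slope
#' from the onset sample to the maximum (0 when the maximum sits at onset),
#' and the baseline mean itself.
#'
#' @param trace A cleaned (typically z-scored) trace.
#' @param events Data frame with `time_ms` (event onsets) and optionally
#'   `trial_kind` (e.g. hit / miss / no_deviant) and `trial_id`.
#' @param baseline_ms Baseline window before onset (default 200 ms).
#' @param window_ms Epoch length after onset (default 3000 ms).
#' @return A `pdr_epochs` list: `epochs` (long tibble: `trial_id`,
#'   `trial_kind`, `time_ms`, `pupil`) and `features` (one row per trial:
#'   `trial_id`, `trial_kind`, `baseline_mean`, `mean_evoked`, `max_evoked`,
#'   `latency_to_max_ms`, `velocity`).
#' @export
epoch_pdr <- function(trace, events, baseline_ms = 200, window_ms = 3000) {
  stopifnot(is.data.frame(trace), is.data.frame(events),
            "time_ms" %in% names(events))
  rate <- attr(trace, "sample_rate_hz") %||% 500
  x <- trace$pupil
  n <- length(x)
  bl_n <- round(baseline_ms / 1000 * rate)
  ep_n <- round(window_ms / 1000 * rate)
  if (!"trial_kind" %in% names(events)) events$trial_kind <- "deviant"
  if (!"trial_id" %in% names(events)) events$trial_id <- seq_len(nrow(events))
  res <- purrr::pmap(events[, c("trial_id", "trial_kind", "time_ms")],
    function(trial_id, trial_kind, time_ms) {
      i0 <- round(time_ms / 1000 * rate) + 1L
      if (i0 - bl_n < 1L || i0 + ep_n - 1L > n) {
        abort(sprintf("Event at %.0f ms is too close to the trace edge.", time_ms))
      }
      baseline <- mean(x[(i0 - bl_n):(i0 - 1L)])
      ep <- x[i0:(i0 + ep_n - 1L)] - baseline
      i_max <- which_max_first(ep)
      latency_ms <- (i_max - 1L) / rate * 1000
      velocity <- if (i_max == 1L) 0 else (ep[i_max] - ep[1L]) / latency_ms
      list(
        epoch = tibble(
          trial_id = trial_id, trial_kind = trial_kind,
          time_ms = (seq_len(ep_n) - 1L) / rate * 1000, pupil = ep
        ),
        features = tibble(
          trial_id = trial_id, trial_kind = trial_kind,
          baseline_mean = baseline,
          mean_evoked = mean(ep), max_evoked = max(ep),
          latency_to_max_ms = latency_ms, velocity = velocity
        )
      )
    }
  )
  structure(
    list(
      epochs = list_rbind(purrr::map(res, "epoch")),
      features = list_rbind(purrr::map(res, "features")),
      baseline_ms = baseline_ms, window_ms = window_ms
    ),
    class = "pdr_epochs"
  )
}

#' @export
print.pdr_epochs <- function(x, ...) {
  cat(sprintf(
    "<pdr_epochs: %d trials (%s), %g ms window>\n",
    nrow(x$features),
    paste(names(table(x$features$trial_kind)), collapse = "/"),
    x$window_ms
  ))
  invisible(x)
}

#' Scaled-MAD outlier filter
#'
#' Removes values lying outside `median(x) +/- k * scaledMAD`, where
#' `scaledMAD = 1.4826 * median(|x - median(x)|)` (the scaling makes the MAD
#' a consistent SD estimate under normality). Used for reaction times and
#' baseline pupil sizes. When the MAD is zero but the values are not all
#' identical, only exact-median values are kept, with a warning.
#'
#' @param x Numeric vector (length >= 3).
#' @param k Multiplier (default 3).
#' @return List with `values` (kept values), `removed` (indices removed),
#'   `bounds` (the interval used).
#' @export
mad_outlier_filter <- function(x, k = 3) {
  if (length(x) < 3L) abort("Need at least 3 values.")
  med <- median(x)
  smad <- mad(x) # constant 1.4826 by default
  if (smad == 0 && any(x != med)) {
    warn("Scaled MAD is zero with non-identical values; keeping exact-median values only.")
  }
  lo <- med - k * smad
  hi <- med + k * smad
  keep <- x >= lo & x <= hi
  list(values = x[keep], removed = which(!keep), bounds = c(lo, hi))
}
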