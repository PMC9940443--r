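#' Extract ST segments after each R-peak
#'
#' Cuts one fixed-length window per detected beat, starting a fixed offset
#' after the R-peak: at the 350 Hz design rate the defaults (57.14 ms offset,
#' 120 ms length) give windows starting 20 samples after the R-peak and
#' spanning 42 samples — the conventional ST interval. Peaks whose window
#' would run past the end of the record yield no segment (the number skipped
#' is reported via a message).
#'
#' @param raw An `ecg_signal` at stage `"raw"`.
#' @param peaks An `r_peaks` tibble (or any data frame with a 0-based
#'   `index` column) on the same signal.
#' @param offset_ms Window start relative to the R-peak, in milliseconds.
#' @param length_ms Window duration in milliseconds.
#' @return A tibble of class `st_segments`, one row per retained segment:
#'   `r_index`, `start_index` (0-based), `n` (samples in the window), and a
#'   list-column `samples`.
#' @export
extract_st_segments <- function(raw, peaks, offset_ms = 57.14,
                                length_ms = 120) {
  assert_stage(raw, "raw", "extract_st_segments")
  if (!is.numeric(offset_ms) || offset_ms <= 0 ||
      !is.numeric(length_ms) || length_ms <= 0) {
    stop("`offset_ms` and `length_ms` must be positive durations.",
         call. = FALSE)
  }
  fs <- ecg_fs(raw)
  off <- as.integer(floor(offset_ms * fs / 1000 + 0.5))
  len <- as.integer(floor(length_ms * fs / 1000 + 0.5))
  idx0 <- as.integer(peaks$index)

  start0 <- idx0 + off
  keep <- (start0 + len) <= length(raw)  # 0-based start + len must fit
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    message(sprintf("%d peak(s) too close to the signal end: skipped.",
                    n_skip))
  }
  x <- as.numeric(raw)
  rows <- tibble::tibble(
    r_index = idx0[keep],
    start_index = start0[keep],
    n = rep(len, sum(keep)),
    samples = lapply(start0[keep], function(s0) x[(s0 + 1):(s0 + len)])
  )
  structure(rows, fs = fs, offset_samples = off,
            class = c("st_segments", class(rows)))
}

#' ST-segment slope
#'
#' For a window of N samples with first amplitude Y and last amplitude X the
#' slope is `tan(theta) = (X - Y) / N`, in amplitude units per sample. The
#' denominator is the sample count N (not N - 1), so a perfectly linear ramp
#' of per-sample increment k reports `k (N - 1) / N`. Adding a constant
#' offset to the whole window leaves the slope unchanged.
#'
#' @param samples Numeric amplitude vector, length >= 2.
#' @return The slope, a single number.
#' @examples
#' compute_st_slope(seq(0, 0.42, length.out = 43)[-1]) # rises 0.42 over 42
#' @export
compute_st_slope <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L || !all(is.finite(samples))) {
    stop("ST slope needs at least 2 finite samples.", call. = FALSE)
  }
  (samples[length(samples)] - samples[1]) / length(samples)
}

#' Per-beat and summary ST slopes
#'
#' Applies [compute_st_slope()] to each extracted segment and summarizes
#' across beats (mean by default; the aggregation over a recording session is
#' a reporting choice, so the median is available).
#'
#' @param segments An `st_segments` tibble from [extract_st_segments()].
#' @param summary `"mean"` (default) or `"median"`.
#' @return A list with `per_beat` (tibble: `r_index`, `tan_theta`) and
#'   `summary` (single number; `NA` when no segments were retained).
#' @export
st_slopes <- function(segments, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  per_beat <- tibble::tibble(
    r_index = segments$r_index,
    tan_theta = vapply(segments$samples, compute_st_slope, numeric(1))
  )
  s <- if (nrow(per_beat) == 0L) {
    NA_real_
  } else if (summary == "mean") {
    mean(per_beat$tan_theta)
  } else {
    stats::median(per_beat$tan_theta)
  }
  list(per_beat = per_beat, summary = s)
}

#' Map a continuous ST slope to the ordinal `slope` attribute
#'
#' The heart-disease table codes the peak-exercise ST slope as 1 =
#' upsloping, 2 = flat, 3 = downsloping. On amplitude-normalized signals a
#' symmetric dead band of +/- `threshold` (amplitude units per sample,
#' default 0.002) around zero is labelled flat.
#'
#' @param tan_theta Slope value(s) in amplitude units per sample.
#' @param threshold Half-width of the flat band.
#' @return Integer vector in `{1, 2, 3}`.
#' @export
slope_to_category <- function(tan_theta, threshold = 0.002) {
  ifelse(tan_theta >= threshold, 1L,
         ifelse(tan_theta <= -threshold, 3L, 2L))
}

#' Maximum heart rate from a pulse-reading burst
#'
#' The `thalach` attribute is operationalized as the maximum of a burst of
#' exactly 20 consecutive pulse-rate readings (bpm). Readings outside the
#' physiological range are clamped with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param pulse_readings Numeric vector of exactly 20 bpm readings.
#' @param range Allowed physiological range, default 30-250 bpm.
#' @param strict Reject (error) rather than clamp out-of-range readings.
#' @return The maximum reading, bpm.
#' @export
compute_thalach <- function(pulse_readings, range = c(30, 250),
                            strict = FALSE) {
  pulse_readings <- as.numeric(pulse_readings)
  if (length(pulse_readings) != 20L) {
    stop(sprintf("thalach needs exactly 20 pulse readings (got %d).",
                 length(pulse_readings)), call. = FALSE)
  }
  if (anyNA(pulse_readings)) {
    stop("Pulse readings must not be missing.", call. = FALSE)
  }
  out_of_range <- pulse_readings < range[1] | pulse_readings > range[2]
  if (any(out_of_range)) {
    if (strict) {
      stop(sprintf("%d pulse reading(s) outside [%g, %g] bpm.",
                   sum(out_of_range), range[1], range[2]), call. = FALSE)
    }
    warning(sprintf("%d pulse reading(s) outside [%g, %g] bpm: clamped.",
                    sum(out_of_range), range[1], range[2]), call. = FALSE)
    pulse_readings <- pmin(pmax(pulse_readings, range[1]), range[2])
  }
  max(pulse_readings)
}
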