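#' Single-channel ECG signal
#'
#' Lightweight container for an evenly sampled single-lead ECG trace: a
#' numeric amplitude vector (arbitrary units — mV or raw ADC counts) plus its
#' sampling rate and a provenance tag recording which stage of the QRS
#' detection chain produced it.
#'
#' Stages advance only along the chain
#' `raw -> lowpass -> bandpass -> derivative -> squared -> integrated`;
#' each filter checks that its input carries the stage it expects.
#'
#' @param samples Numeric vector of amplitudes; must be finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param stage Provenance tag, one of `"raw"`, `"lowpass"`, `"bandpass"`,
#'   `"derivative"`, `"squared"`, `"integrated"`.
#' @return An `ecg_signal` object (numeric vector with `fs` and `stage`
#'   attributes).
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 350)), fs = 350)
#' sig
#' @export
ecg_signal <- function(samples, fs, stage = "raw") {
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one value.", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf).", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  stage <- match.arg(stage, ecg_stages())
  structure(samples, fs = as.numeric(fs), stage = stage,
            class = c("ecg_signal", "numeric"))
}

ecg_stages <- function() {
  c("raw", "lowpass", "bandpass", "derivative", "squared", "integrated")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s), stage = %s\n",
              length(x), ecg_fs(x), length(x) / ecg_fs(x), ecg_stage(x)))
  invisible(x)
}

#' Sampling rate and stage accessors
#' @param x An `ecg_signal`.
#' @return `ecg_fs()` the sampling rate in Hz; `ecg_stage()` the stage tag.
#' @export
ecg_fs <- function(x) attr(x, "fs")

#' @rdname ecg_fs
#' @export
ecg_stage <- function(x) attr(x, "stage")

# Rebuild an ecg_signal with new samples/stage, keeping fs.
restamp <- function(x, samples, stage) {
  ecg_signal(samples, fs = ecg_fs(x), stage = stage)
}

assert_stage <- function(x, expected, op) {
  if (!inherits(x, "ecg_signal")) {
    stop(sprintf("`%s()` expects an `ecg_signal`; see `ecg_signal()`.", op),
         call. = FALSE)
  }
  if (!identical(ecg_stage(x), expected)) {
    stop(sprintf("`%s()` expects a signal at stage '%s' (got '%s').",
                 op, expected, ecg_stage(x)), call. = FALSE)
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.ecg_signal <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x) - 1L,
    time_s = (seq_along(x) - 1L) / ecg_fs(x),
    amplitude = as.numeric(x)
  )
}

#' Read a signal file into an `ecg_signal`
#'
#' Accepts either plain text with one amplitude per line, or a CSV with
#' `(sample_index, amplitude)` columns (header detected by sniffing the first
#' line for non-numeric tokens).
#'
#' @param path Path to the signal file.
#' @param fs Sampling rate in Hz.
#' @return An `ecg_signal` at stage `"raw"`.
#' @export
read_signal <- function(path, fs) {
  if (!file.exists(path)) stop("Signal file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("Signal file is empty: ", path, call. = FALSE)
  has_comma <- grepl(",", lines[[1]], fixed = TRUE)
  if (has_comma) {
    first_tokens <- strsplit(lines[[1]], ",")[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(first_tokens))))
    body <- if (header) lines[-1] else lines
    parts <- strsplit(body, ",")
    amp <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) < 2L) {
        stop(sprintf("Line %d: expected (sample_index, amplitude).",
                     i + as.integer(header)), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(p[[2]]))
      if (is.na(v)) {
        stop(sprintf("Line %d: non-numeric amplitude '%s'.",
                     i + as.integer(header), p[[2]]), call. = FALSE)
      }
      v
    }, numeric(1))
  } else {
    amp <- suppressWarnings(as.numeric(lines))
    if (anyNA(amp)) {
      bad <- which(is.na(amp))[[1]]
      stop(sprintf("Line %d: non-numeric value '%s'.", bad, lines[[bad]]),
           call. = FALSE)
    }
  }
  ecg_signal(amp, fs = fs, stage = "raw")
}

#' Write R-peak detections to CSV
#'
#' @param peaks Tibble from [detect_r_peaks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_r_peaks <- function(peaks, path) {
  readr::write_csv(peaks[c("index", "time_s")], path)
  invisible(path)
}
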