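#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' Runs the full filter chain ([pan_tompkins_stages()]) on a raw signal,
#' thresholds the integrated envelope adaptively, and maps each accepted
#' candidate back to the raw-signal local maximum after compensating the
#' cumulative group delay of the linear stages.
#'
#' Thresholding follows the two-level signal/noise scheme: a signal-level
#' estimate S (initialised as the maximum of the integrated envelope over the
#' first 2 s) and a noise-level estimate N (its mean over the same span) give
#' the decision threshold `T = N + 0.25 (S - N)`; S and N are updated with
#' the usual 1/8 running rule as peaks are accepted or rejected. Candidate
#' peaks are local maxima of the envelope above T separated by at least the
#' refractory interval (200 ms by default); when two candidates fall inside
#' one refractory span the larger survives.
#'
#' The refinement window in the raw signal spans
#' `[c - D - 60 ms, c]` for an envelope candidate at sample `c`, where
#' `D = 5 + 16 + 2 + (W - 1) / 2` samples is the group delay of the
#' low-pass, high-pass, derivative and integration stages.
#'
#' Sample indices in the result are 0-based (time in seconds is `index/fs`),
#' matching the file formats written by [write_r_peaks()].
#'
#' @param raw An `ecg_signal` at stage `"raw"`, at least 2 s long.
#' @param coeffs Coefficient set for the linear stages
#'   (`"canonical"`/`"paper"`).
#' @param window_ms Integration window in milliseconds.
#' @param refractory_ms Minimum inter-peak interval in milliseconds.
#' @param quiet Suppress the off-design-rate message.
#' @return A tibble of class `r_peaks` with columns `index` (0-based raw
#'   sample index, strictly increasing), `time_s`, and `amplitude` (raw
#'   amplitude at the peak); attributes `fs` and `refractory_ms`. Zero rows
#'   when nothing crosses the threshold.
#' @examples
#' fx <- simulate_ecg(fs = 350, duration = 10, hr_bpm = 60, seed = 1)
#' detect_r_peaks(fx$signal, quiet = TRUE)
#' @export
detect_r_peaks <- function(raw, coeffs = c("canonical", "paper"),
                           window_ms = 150, refractory_ms = 200,
                           quiet = FALSE) {
  assert_stage(raw, "raw", "detect_r_peaks")
  coeffs <- match.arg(coeffs)
  fs <- ecg_fs(raw)
  init_n <- as.integer(round(2 * fs))
  if (length(raw) < init_n) {
    stop(sprintf(
      "Signal too short for threshold initialization: need >= 2 s (%d samples), got %d.",
      init_n, length(raw)), call. = FALSE)
  }
  stages <- pan_tompkins_stages(raw, coeffs = coeffs, window_ms = window_ms,
                                quiet = quiet)
  z <- as.numeric(stages$integrated)
  n <- length(z)
  refr <- as.integer(round(refractory_ms / 1000 * fs))

  # local maxima of the envelope
  cand <- which(diff(sign(diff(z))) < 0) + 1L
  S <- max(z[seq_len(init_n)])
  N <- mean(z[seq_len(init_n)])

  kept <- integer(0)
  kept_val <- numeric(0)
  for (i in cand) {
    thr <- N + 0.25 * (S - N)
    if (z[i] <= thr) {
      N <- 0.875 * N + 0.125 * z[i]
      next
    }
    if (length(kept) > 0L && (i - kept[length(kept)]) < refr) {
      if (z[i] > kept_val[length(kept)]) {
        kept[length(kept)] <- i
        kept_val[length(kept)] <- z[i]
      }
      next
    }
    kept <- c(kept, i)
    kept_val <- c(kept_val, z[i])
    S <- 0.875 * S + 0.125 * z[i]
  }

  W <- integration_window_samples(window_ms, fs)
  delay <- as.integer(round(5 + 16 + 2 + (W - 1) / 2))
  back <- as.integer(round(0.060 * fs))
  x <- as.numeric(raw)

  refined <- vapply(kept, function(i) {
    lo <- max(1L, i - delay - back)
    hi <- min(n, i)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))

  # refractory pass on the refined indices: larger raw amplitude survives
  if (length(refined) > 1L) {
    out <- refined[1]
    for (i in refined[-1]) {
      last <- out[length(out)]
      if (i - last >= refr) {
        out <- c(out, i)
      } else if (x[i] > x[last]) {
        out[length(out)] <- i
      }
    }
    refined <- out
  }

  res <- tibble::tibble(
    index = as.integer(refined - 1L),
    time_s = (refined - 1L) / fs,
    amplitude = x[refined]
  )
  structure(res, fs = fs, refractory_ms = refractory_ms,
            class = c("r_peaks", class(res)))
}
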