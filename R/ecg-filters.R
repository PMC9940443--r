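#' Pan-Tompkins filter chain
#'
#' The classic QRS-detection preprocessing chain: a recursive integer-
#' coefficient low-pass filter (cutoff ~11 Hz, DC gain 36), a recursive
#' high-pass filter (cutoff ~5 Hz, zero DC gain), a five-point derivative,
#' element-wise squaring, and a 150 ms causal moving-window integration.
#' All linear stages are causal with zero initial state: history terms that
#' fall before the start of the record are taken as 0, so the first few
#' dozen output samples are a start-up transient.
#'
#' The filters were designed for 200 Hz ECG; they are applied at the native
#' sampling rate of the input (a message is emitted when `fs != 200` Hz so
#' the shifted corner frequencies are not silent). Two coefficient sets are
#' available: `"canonical"` (the standard Pan-Tompkins difference equations,
#' the default) and `"paper"` (a sign-variant transcription that circulates
#' in the applied literature), selected by the `coeffs` argument of
#' [highpass_filter()] and [derivative_filter()].
#'
#' @name pan_tompkins_chain
NULL

# Apply a rational difference equation sum(a_k y(n-k)) = sum(b_k x(n-k))
# with zero initial conditions. a[1] must be 1.
apply_difference_eq <- function(x, b, a) {
  as.numeric(signal::filter(signal::Arma(b = b, a = a), as.numeric(x)))
}

warn_if_offrate <- function(fs) {
  if (!isTRUE(all.equal(fs, 200))) {
    message(sprintf(
      "Pan-Tompkins coefficients were designed at 200 Hz; applying at %g Hz shifts the passband.",
      fs))
  }
}

#' Low-pass stage of the Pan-Tompkins chain
#'
#' Applies `y(n) = 2y(n-1) - y(n-2) + x(n) - 2x(n-6) + x(n-12)`
#' (transfer function `(1 - z^-6)^2 / (1 - z^-1)^2`; DC gain 36, group delay
#' 5 samples) with zero initial conditions.
#'
#' @param signal An `ecg_signal` at stage `"raw"`.
#' @param quiet Suppress the off-design-rate message.
#' @return An `ecg_signal` at stage `"lowpass"`.
#' @examples
#' s <- ecg_signal(rep(1, 200), fs = 200)
#' tail(as.numeric(lowpass_filter(s)), 1) # converges to the DC gain, 36
#' @export
lowpass_filter <- function(signal, quiet = FALSE) {
  assert_stage(signal, "raw", "lowpass_filter")
  if (!quiet) warn_if_offrate(ecg_fs(signal))
  b <- numeric(13); b[1] <- 1; b[7] <- -2; b[13] <- 1
  a <- c(1, -2, 1)
  restamp(signal, apply_difference_eq(signal, b, a), "lowpass")
}

#' High-pass stage of the Pan-Tompkins chain
#'
#' With `coeffs = "canonical"` applies
#' `y(n) = y(n-1) - x(n)/32 + x(n-16) - x(n-17) + x(n-32)/32`
#' (an all-pass-minus-low-pass construction; zero DC gain, group delay 16
#' samples). `coeffs = "paper"` substitutes the sign-variant
#' `y(n) = y(n-1) - x(n)/32 - x(n-16) - x(n-17) + x(n-32)/32`.
#'
#' @param signal An `ecg_signal` at stage `"lowpass"`.
#' @param coeffs `"canonical"` (default) or `"paper"`.
#' @return An `ecg_signal` at stage `"bandpass"`.
#' @export
highpass_filter <- function(signal, coeffs = c("canonical", "paper")) {
  assert_stage(signal, "lowpass", "highpass_filter")
  coeffs <- match.arg(coeffs)
  b <- numeric(33)
  b[1] <- -1 / 32
  b[17] <- if (coeffs == "canonical") 1 else -1
  b[18] <- -1
  b[33] <- 1 / 32
  a <- c(1, -1)
  restamp(signal, apply_difference_eq(signal, b, a), "bandpass")
}

#' Five-point derivative stage
#'
#' With `coeffs = "canonical"` applies
#' `y(n) = (1/8) * (2x(n) + x(n-1) - x(n-3) - 2x(n-4))`, an FIR
#' differentiator with group delay 2 samples; `coeffs = "paper"` substitutes
#' the sign-variant `(1/8) * (2x(n) - x(n-1) - x(n-3) + 2x(n-4))`.
#'
#' @param signal An `ecg_signal` at stage `"bandpass"`.
#' @param coeffs `"canonical"` (default) or `"paper"`.
#' @return An `ecg_signal` at stage `"derivative"`.
#' @export
derivative_filter <- function(signal, coeffs = c("canonical", "paper")) {
  assert_stage(signal, "bandpass", "derivative_filter")
  coeffs <- match.arg(coeffs)
  b <- if (coeffs == "canonical") {
    c(2, 1, 0, -1, -2) / 8
  } else {
    c(2, -1, 0, -1, 2) / 8
  }
  restamp(signal, apply_difference_eq(signal, b, 1), "derivative")
}

#' Squaring stage
#'
#' Element-wise squaring; magnifies the dominant R deflections and makes the
#' series non-negative ahead of integration.
#'
#' @param signal An `ecg_signal` at stage `"derivative"`.
#' @return An `ecg_signal` at stage `"squared"`.
#' @export
square_signal <- function(signal) {
  assert_stage(signal, "derivative", "square_signal")
  restamp(signal, as.numeric(signal)^2, "squared")
}

#' Moving-window integration stage
#'
#' Causal moving average over a `window_ms` window:
#' `y(n) = (1/W) * sum_{k=0..W-1} x(n-k)` with zero-padded history, where
#' `W = floor(window_ms * fs / 1000 + 0.5)` (half-up rounding; at the 350 Hz
#' design rate the default 150 ms window is 53 samples). Consolidates the
#' squared QRS energy into a single lobe per beat.
#'
#' @param signal An `ecg_signal` at stage `"squared"`.
#' @param window_ms Window duration in milliseconds (> 0).
#' @return An `ecg_signal` at stage `"integrated"`.
#' @export
moving_window_integrate <- function(signal, window_ms = 150) {
  assert_stage(signal, "squared", "moving_window_integrate")
  if (!is.numeric(window_ms) || length(window_ms) != 1L || window_ms <= 0) {
    stop("`window_ms` must be a single positive duration.", call. = FALSE)
  }
  W <- integration_window_samples(window_ms, ecg_fs(signal))
  n <- length(signal)
  if (W > n) {
    stop(sprintf("Integration window (%d samples) exceeds signal length (%d).",
                 W, n), call. = FALSE)
  }
  cs <- cumsum(as.numeric(signal))
  lagged <- c(rep(0, W), cs[seq_len(n - W)])
  restamp(signal, (cs - lagged) / W, "integrated")
}

#' @rdname moving_window_integrate
#' @param fs Sampling rate in Hz.
#' @return `integration_window_samples()`: the window length W in samples.
#' @export
integration_window_samples <- function(window_ms, fs) {
  as.integer(floor(window_ms * fs / 1000 + 0.5))
}

#' Run the full filter chain
#'
#' Convenience wrapper running lowpass -> highpass -> derivative -> square ->
#' integrate and returning every intermediate stage.
#'
#' @param signal An `ecg_signal` at stage `"raw"`.
#' @param coeffs Coefficient set for the high-pass and derivative stages.
#' @param window_ms Integration window in milliseconds.
#' @param quiet Suppress the off-design-rate message.
#' @return Named list of `ecg_signal`s:
#'   `raw`, `lowpass`, `bandpass`, `derivative`, `squared`, `integrated`.
#' @export
pan_tompkins_stages <- function(signal, coeffs = c("canonical", "paper"),
                                window_ms = 150, quiet = FALSE) {
  coeffs <- match.arg(coeffs)
  lp <- lowpass_filter(signal, quiet = quiet)
  bp <- highpass_filter(lp, coeffs = coeffs)
  dv <- derivative_filter(bp, coeffs = coeffs)
  sq <- square_signal(dv)
  mw <- moving_window_integrate(sq, window_ms = window_ms)
  list(raw = signal, lowpass = lp, bandpass = bp,
       derivative = dv, squared = sq, integrated = mw)
}
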