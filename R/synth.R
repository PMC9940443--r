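#' Simulate a parametric PQRST ECG with known ground truth
#'
#' Builds each beat as a sum of five Gaussian bumps (P, Q, R, S, T) at fixed
#' fractional offsets of the RR interval, overlays a linear ramp of slope
#' `st_slope` (amplitude units per sample) across the 57-177 ms post-R
#' window — the window later read back by [extract_st_segments()] — and adds
#' white Gaussian noise. Amplitudes are normalized to a unit R bump. The
#' generator is a pure function of its parameters: the same tuple (seed
#' included) reproduces the identical fixture bit for bit.
#'
#' This is a test-bench waveform, not a physiological model: bump placement
#' keeps the T wave (+0.32 RR, sd 0.04 RR) clear of the ST window at resting
#' heart rates, so the injected slope can be recovered in closed form.
#'
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration Record length in seconds (>= 2).
#' @param hr_bpm Heart rate, 30-220 bpm.
#' @param st_slope Injected ST ramp slope, amplitude units per sample.
#' @param noise_sd White-noise standard deviation (amplitude units).
#' @param seed Seed for the noise draw.
#' @return An `ecg_fixture` list: `signal` (an `ecg_signal`),
#'   `true_r_indices` (0-based sample indices), `true_st_slope` (per beat),
#'   `params`.
#' @examples
#' fx <- simulate_ecg(fs = 350, duration = 10, hr_bpm = 60, seed = 42)
#' length(fx$true_r_indices) # 10 beats
#' @export
simulate_ecg <- function(fs = 350, duration = 10, hr_bpm = 60,
                         st_slope = 0, noise_sd = 0, seed = 1) {
  if (fs < 100) stop("`fs` must be >= 100 Hz.", call. = FALSE)
  if (duration < 2) stop("`duration` must be >= 2 s.", call. = FALSE)
  if (hr_bpm < 30 || hr_bpm > 220) {
    stop("`hr_bpm` must lie in [30, 220].", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)

  n <- as.integer(round(duration * fs))
  rr <- fs * 60 / hr_bpm  # samples per beat (possibly fractional)

  # bump table: offsets and widths as fractions of RR, unit R amplitude
  bumps <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    offset = c(-0.20, -0.025, 0, 0.03, 0.32),
    width = c(0.02, 0.008, 0.010, 0.008, 0.04),
    amp = c(0.15, -0.12, 1.00, -0.20, 0.30))

  centers <- seq(rr / 2, n - 1, by = rr)
  i <- seq_len(n) - 1  # 0-based sample grid
  x <- numeric(n)
  for (c0 in centers) {
    for (b in seq_len(nrow(bumps))) {
      mu <- c0 + bumps$offset[b] * rr
      sd_b <- bumps$width[b] * rr
      lo <- max(0, floor(mu - 6 * sd_b)); hi <- min(n - 1, ceiling(mu + 6 * sd_b))
      if (lo > hi) next
      sel <- (lo:hi) + 1
      x[sel] <- x[sel] + bumps$amp[b] * exp(-((i[sel] - mu)^2) / (2 * sd_b^2))
    }
  }

  st_off <- as.integer(floor(0.05714 * fs + 0.5))  # 20 samples at 350 Hz
  st_len <- as.integer(floor(0.120 * fs + 0.5))    # 42 samples at 350 Hz
  for (c0 in round(centers)) {
    s0 <- c0 + st_off
    idx <- s0 + seq_len(st_len) - 1  # 0-based
    keep <- idx < n
    x[idx[keep] + 1] <- x[idx[keep] + 1] + st_slope * (seq_len(st_len)[keep] - 1)
  }

  set.seed(seed)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)

  structure(list(
    signal = ecg_signal(x, fs = fs, stage = "raw"),
    true_r_indices = as.integer(round(centers)),
    true_st_slope = rep(st_slope, length(centers)),
    params = list(fs = fs, duration = duration, hr_bpm = hr_bpm,
                  st_slope = st_slope, noise_sd = noise_sd, seed = seed)),
    class = "ecg_fixture")
}

cohort_continuous_spec <- function() {
  tibble::tibble(
    column = c("age", "trestbps", "chol", "thalach", "oldpeak"),
    mean = c(54, 131, 250, 150, 1.05),
    sd = c(8, 15, 45, 18, 1.0),
    direction = c(1, 1, 1, -1, 1))  # thalach falls with risk
}

#' Simulate a patient cohort with the heart-disease schema
#'
#' Draws zone labels from `class_proportions`, then the 12 modelling
#' attributes from class-conditional distributions: continuous attributes
#' are normal with class means `effect_size` pooled SDs apart (higher-risk
#' classes shifted up, except `thalach` which falls with risk), clamped to
#' the documented attribute ranges; categorical attributes are class-tilted
#' multinomials over their domains. A `num` severity consistent with the
#' zone is attached (green 0, yellow 1, red drawn from 2-4). Exactly
#' `round(missing_rate * 12 n)` feature cells are masked, completely at
#' random by default or, with `mechanism = "mar"`, with probability
#' increasing in the (observed) age rank.
#'
#' @param n Number of records.
#' @param class_proportions Named or unnamed proportions over the zones, in
#'   scheme order (three: green, yellow, red; two: green, red); must sum
#'   to 1. Defaults to the 413/258/249 three-zone composition.
#' @param effect_size Separation of adjacent class means, in pooled SDs.
#' @param missing_rate Fraction of feature cells masked, in `[0, 0.5)`.
#' @param scheme `"three"` or `"two"`.
#' @param mechanism `"mcar"` (default) or `"mar"`.
#' @param seed Seed; the generator is a pure function of its arguments.
#' @return A tibble with the 12 attributes plus `num`; generating
#'   parameters are attached as the `params` attribute.
#' @export
simulate_cohort <- function(n = 920,
                            class_proportions = c(413, 258, 249) / 920,
                            effect_size = 1, missing_rate = 0,
                            scheme = c("three", "two"),
                            mechanism = c("mcar", "mar"), seed = 1) {
  scheme <- match.arg(scheme)
  mechanism <- match.arg(mechanism)
  k_expected <- if (scheme == "three") 3L else 2L
  if (length(class_proportions) != k_expected) {
    stop(sprintf("`class_proportions` must have %d entries for scheme '%s'.",
                 k_expected, scheme), call. = FALSE)
  }
  if (any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("`class_proportions` must be positive and sum to 1.",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop("`missing_rate` must lie in [0, 0.5).", call. = FALSE)
  }
  set.seed(seed)
  K <- k_expected
  cls <- sample.int(K, n, replace = TRUE, prob = class_proportions) - 1L

  spec <- cohort_continuous_spec()
  out <- list()
  for (r in seq_len(nrow(spec))) {
    shift <- spec$direction[r] * (cls - (K - 1) / 2) * effect_size * spec$sd[r]
    v <- stats::rnorm(n, spec$mean[r] + shift, spec$sd[r])
    rng <- uci_ranges()[[spec$column[r]]]
    out[[spec$column[r]]] <- pmin(pmax(v, rng[1]), rng[2])
  }

  cat_domains <- uci_domains()[c("sex", "cp", "fbs", "restecg", "exang",
                                 "slope")]
  k_centered <- if (K > 1) 2 * cls / (K - 1) - 1 else rep(0, n)
  for (nm in names(cat_domains)) {
    dom <- cat_domains[[nm]]
    m <- length(dom)
    j_centered <- if (m > 1) {
      (seq_len(m) - 1 - (m - 1) / 2) / ((m - 1) / 2)
    } else {
      0
    }
    out[[nm]] <- vapply(seq_len(n), function(ii) {
      w <- exp(effect_size * j_centered * k_centered[ii])
      sample(dom, 1, prob = w / sum(w))
    }, numeric(1))
  }

  num <- integer(n)
  if (scheme == "three") {
    num[cls == 1L] <- 1L
    nr <- sum(cls == 2L)
    num[cls == 2L] <- sample(2:4, nr, replace = TRUE)
  } else {
    nr <- sum(cls == 1L)
    num[cls == 1L] <- sample(1:4, nr, replace = TRUE)
  }
  out$num <- num

  tbl <- tibble::as_tibble(out)[c(uci_used_columns(), "num")]

  feat_cols <- uci_used_columns()
  n_cells <- n * length(feat_cols)
  n_mask <- round(missing_rate * n_cells)
  if (n_mask > 0L) {
    w <- if (mechanism == "mar") {
      rep(rank(tbl$age) / n, times = length(feat_cols))
    } else {
      rep(1, n_cells)
    }
    cells <- sample.int(n_cells, n_mask, prob = w)
    for (cell in cells) {
      row <- ((cell - 1L) %% n) + 1L
      col <- feat_cols[((cell - 1L) %/% n) + 1L]
      tbl[[col]][row] <- NA_real_
    }
    # guard: never leave a column with nothing observed
    for (col in feat_cols) {
      if (all(is.na(tbl[[col]]))) tbl[[col]][1] <- cohort_column_fallback(col)
    }
  }

  attr(tbl, "params") <- list(
    n = n, class_proportions = class_proportions, effect_size = effect_size,
    missing_rate = missing_rate, scheme = scheme, mechanism = mechanism,
    seed = seed)
  tbl
}

cohort_column_fallback <- function(col) {
  if (col %in% names(uci_ranges())) {
    mean(uci_ranges()[[col]])
  } else {
    uci_domains()[[col]][1]
  }
}
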