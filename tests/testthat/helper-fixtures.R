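# Shared fixtures and independent reference implementations.
#
# The naive_* functions re-derive each difference equation by direct sample
# recursion (plain loops, no signal-processing library), so they can serve
# as independent oracles for the package's filter implementations.

naive_lowpass <- function(x) {
  n <- length(x)
  y <- numeric(n)
  at <- function(v, i) if (i >= 1 && i <= n) v[i] else 0
  for (i in seq_len(n)) {
    y[i] <- 2 * at(y, i - 1) - at(y, i - 2) +
      at(x, i) - 2 * at(x, i - 6) + at(x, i - 12)
  }
  y
}

naive_highpass <- function(x) {
  n <- length(x)
  y <- numeric(n)
  at <- function(v, i) if (i >= 1 && i <= n) v[i] else 0
  for (i in seq_len(n)) {
    y[i] <- at(y, i - 1) - at(x, i) / 32 + at(x, i - 16) -
      at(x, i - 17) + at(x, i - 32) / 32
  }
  y
}

naive_derivative <- function(x) {
  n <- length(x)
  y <- numeric(n)
  at <- function(v, i) if (i >= 1 && i <= n) v[i] else 0
  for (i in seq_len(n)) {
    y[i] <- (2 * at(x, i) + at(x, i - 1) - at(x, i - 3) -
               2 * at(x, i - 4)) / 8
  }
  y
}

# Impulse response of a naive filter, truncated where |h| stays < tol.
impulse_response <- function(filter_fun, length_out, tol = 1e-12) {
  h <- filter_fun(c(1, numeric(length_out - 1)))
  last <- max(which(abs(h) >= tol), 1L)
  h[seq_len(last)]
}

# Direct-convolution oracle: y(n) = sum_k h(k+1) x(n-k), zero-padded.
brute_conv <- function(h, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    k <- seq_len(min(i, length(h)))
    y[i] <- sum(h[k] * x[i - k + 1])
  }
  y
}

run_chain_quiet <- function(x, fs, stage_fun) {
  s <- ecg_signal(x, fs = fs)
  suppressMessages(stage_fun(s))
}

# Expand a confusion matrix (rows = truth, cols = predicted) into parallel
# truth/prediction label vectors.
labels_from_matrix <- function(cm) {
  truth <- character(0)
  pred <- character(0)
  for (i in rownames(cm)) {
    for (j in colnames(cm)) {
      truth <- c(truth, rep(i, cm[i, j]))
      pred <- c(pred, rep(j, cm[i, j]))
    }
  }
  list(truth = truth, pred = pred)
}

# Printed field-evaluation confusion matrices (rows = true labels).
table5_two_level <- function() {
  matrix(c(23, 1, 3, 13), nrow = 2, byrow = TRUE,
         dimnames = list(c("green", "red"), c("green", "red")))
}

table5_three_level <- function() {
  # row/column order green, red, yellow as printed
  matrix(c(13, 0, 5, 0, 14, 0, 0, 0, 8), nrow = 3, byrow = TRUE,
         dimnames = list(c("green", "red", "yellow"),
                         c("green", "red", "yellow")))
}

# Well-separated synthetic cohort, preprocessed leakage-free.
make_prepped_cohort <- function(n = 400, scheme = "three", effect_size = 3,
                                seed = 1, missing_rate = 0) {
  props <- if (scheme == "three") c(413, 258, 249) / 920 else
    c(413, 507) / 920
  coh <- simulate_cohort(n = n, class_proportions = props,
                         effect_size = effect_size,
                         missing_rate = missing_rate,
                         scheme = scheme, seed = seed)
  suppressWarnings(preprocess_recipe(coh, scheme = scheme, seed = seed,
                                     split_first = TRUE))
}
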