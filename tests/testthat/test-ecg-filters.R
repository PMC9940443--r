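test_that("low-pass steady state matches the DC gain derived from its impulse response", {
  # independent oracle: sum of the brute-force impulse response
  h <- impulse_response(naive_lowpass, 400)
  expect_equal(sum(h), 36, tolerance = 1e-12)

  for (c0 in c(1, 0.25, -3)) {
    out <- run_chain_quiet(rep(c0, 200), 350, lowpass_filter)
    expect_equal(tail(as.numeric(out), 1), 36 * c0, tolerance = 1e-9)
    expect_identical(ecg_stage(out), "lowpass")
  }

  zero <- run_chain_quiet(numeric(50), 350, lowpass_filter)
  expect_true(all(as.numeric(zero) == 0))
})

test_that("band-pass (high-pass after low-pass) has zero DC gain and is linear", {
  const <- run_chain_quiet(rep(1, 400), 350, function(s) {
    highpass_filter(lowpass_filter(s, quiet = TRUE))
  })
  expect_equal(tail(as.numeric(const), 1), 0, tolerance = 1e-9 * 36)

  set.seed(41)
  x1 <- rnorm(300)
  x2 <- rnorm(300)
  bp <- function(x) as.numeric(run_chain_quiet(x, 350, function(s) {
    highpass_filter(lowpass_filter(s, quiet = TRUE))
  }))
  expect_equal(bp(2.5 * x1 - 1.5 * x2), 2.5 * bp(x1) - 1.5 * bp(x2),
               tolerance = 1e-10)
})

test_that("derivative stage: zero for constants, 10/8 for a unit ramp", {
  sig <- ecg_signal(rep(2, 300), fs = 350, stage = "bandpass")
  out <- derivative_filter(sig)
  expect_equal(tail(as.numeric(out), 1), 0, tolerance = 1e-12)

  ramp <- ecg_signal(0:299, fs = 350, stage = "bandpass")
  expect_equal(tail(as.numeric(derivative_filter(ramp)), 1), 1.25,
               tolerance = 1e-12)

  expect_true(all(as.numeric(
    derivative_filter(ecg_signal(numeric(20), 350, "bandpass"))) == 0))
})

test_that("each linear stage equals its brute-force convolution oracle", {
  set.seed(97)
  x <- rnorm(500)
  cases <- list(
    list(naive = naive_lowpass, stage = "raw",
         fun = function(s) lowpass_filter(s, quiet = TRUE)),
    list(naive = naive_highpass, stage = "lowpass",
         fun = highpass_filter),
    list(naive = naive_derivative, stage = "bandpass",
         fun = derivative_filter))
  for (cs in cases) {
    h <- impulse_response(cs$naive, 2000)
    expected <- brute_conv(h, x)
    got <- as.numeric(cs$fun(ecg_signal(x, 350, cs$stage)))
    expect_lt(max(abs(got - expected)), 1e-8)
  }
})

test_that("the printed-variant coefficients give a different, self-consistent filter", {
  set.seed(13)
  x <- rnorm(200)
  canon <- as.numeric(highpass_filter(ecg_signal(x, 350, "lowpass")))
  paperv <- as.numeric(highpass_filter(ecg_signal(x, 350, "lowpass"),
                                       coeffs = "paper"))
  expect_gt(max(abs(canon - paperv)), 1e-3)

  dv_paper <- derivative_filter(ecg_signal(rep(1, 100), 350, "bandpass"),
                                coeffs = "paper")
  # printed derivative taps sum to 2/8, not 0: constant input keeps a bias
  expect_equal(tail(as.numeric(dv_paper), 1), 2 / 8, tolerance = 1e-12)
})

test_that("squaring is non-negative and sign-invariant", {
  s <- ecg_signal(c(-2, 3, 0, -1), 350, "derivative")
  expect_equal(as.numeric(square_signal(s)), c(4, 9, 0, 1))
  s_neg <- ecg_signal(-c(-2, 3, 0, -1), 350, "derivative")
  expect_equal(as.numeric(square_signal(s)), as.numeric(square_signal(s_neg)))
})

test_that("integration window length uses half-up rounding and averages correctly", {
  expect_identical(integration_window_samples(150, 350), 53L)
  expect_identical(integration_window_samples(150, 200), 30L)

  const <- moving_window_integrate(ecg_signal(rep(1, 300), 350, "squared"))
  expect_equal(tail(as.numeric(const), 1), 1, tolerance = 1e-12)

  imp <- moving_window_integrate(
    ecg_signal(c(1, numeric(199)), 350, "squared"))
  W <- integration_window_samples(150, 350)
  expect_equal(as.numeric(imp)[seq_len(W)], rep(1 / W, W))
  expect_equal(as.numeric(imp)[W + 1], 0)

  expect_error(
    moving_window_integrate(ecg_signal(rep(1, 10), 350, "squared")),
    "exceeds")
})

test_that("stage contract is enforced along the chain", {
  raw <- ecg_signal(rnorm(50), 350)
  expect_error(highpass_filter(raw), "stage 'lowpass'")
  expect_error(derivative_filter(raw), "stage 'bandpass'")
  expect_error(square_signal(raw), "stage 'derivative'")
  expect_error(ecg_signal(numeric(0), 350), "at least one")
  expect_error(ecg_signal(c(1, NA), 350), "finite")
  expect_error(ecg_signal(1:10, -1), "positive")
})
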