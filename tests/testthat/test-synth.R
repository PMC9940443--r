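test_that("the ECG generator honors its rate arithmetic and determinism", {
  fx <- simulate_ecg(fs = 350, duration = 10, hr_bpm = 60, seed = 1)
  expect_length(fx$true_r_indices, 10L)
  expect_equal(unique(diff(fx$true_r_indices)), 350L)
  expect_length(fx$signal, 3500L)

  fx2 <- simulate_ecg(fs = 350, duration = 10, hr_bpm = 60, seed = 1)
  expect_identical(as.numeric(fx$signal), as.numeric(fx2$signal))

  noisy1 <- simulate_ecg(fs = 350, duration = 5, hr_bpm = 80,
                         noise_sd = 0.1, seed = 4)
  noisy2 <- simulate_ecg(fs = 350, duration = 5, hr_bpm = 80,
                         noise_sd = 0.1, seed = 4)
  expect_identical(as.numeric(noisy1$signal), as.numeric(noisy2$signal))
})

test_that("sampling the template at the ST window endpoints reproduces the slope", {
  s <- 0.006
  fx <- simulate_ecg(fs = 350, duration = 10, hr_bpm = 60, st_slope = s,
                     seed = 2)
  x <- as.numeric(fx$signal)
  slopes <- vapply(fx$true_r_indices, function(r0) {
    w <- x[(r0 + 20 + 1):(r0 + 20 + 42)] # 0-based window, 1-based vector
    compute_st_slope(w)
  }, numeric(1))
  expect_lt(max(abs(slopes - s) / s), 0.10)
})

test_that("generator parameter validation matches its documented domain", {
  expect_error(simulate_ecg(fs = 50), ">= 100")
  expect_error(simulate_ecg(duration = 1), ">= 2")
  expect_error(simulate_ecg(hr_bpm = 20), "30, 220")
  expect_error(simulate_cohort(class_proportions = c(0.5, 0.5, 0.2)),
               "sum to 1")
  expect_error(simulate_cohort(missing_rate = 0.6), "0.5")
})

test_that("cohort class counts track the requested proportions", {
  tbl <- simulate_cohort(n = 1000,
                         class_proportions = c(0.45, 0.28, 0.27),
                         seed = 5)
  zones <- map_num_to_zone(tbl$num, "three")
  counts <- table(zones)
  expect_lt(max(abs(counts / 1000 - c(0.45, 0.28, 0.27))), 0.03 +
              3 * sqrt(0.45 * 0.55 / 1000))
})

test_that("cohort missingness is exact in count and zero when disabled", {
  full <- simulate_cohort(n = 200, missing_rate = 0, seed = 6)
  expect_false(anyNA(full))

  miss <- simulate_cohort(n = 200, missing_rate = 0.1, seed = 6)
  n_cells <- 200 * length(uci_used_columns())
  expect_identical(sum(is.na(miss[uci_used_columns()])),
                   as.integer(round(0.1 * n_cells)))
  expect_false(anyNA(miss$num))
})

test_that("cohort attributes stay inside the documented schema domains", {
  tbl <- simulate_cohort(n = 300, effect_size = 3, seed = 7)
  for (nm in names(uci_ranges())) {
    r <- uci_ranges()[[nm]]
    expect_true(all(tbl[[nm]] >= r[1] & tbl[[nm]] <= r[2]), label = nm)
  }
  for (nm in c("sex", "cp", "fbs", "restecg", "exang", "slope")) {
    expect_true(all(tbl[[nm]] %in% uci_domains()[[nm]]), label = nm)
  }
  expect_true(all(tbl$num %in% 0:4))
})

test_that("a zero-effect cohort carries no class signal", {
  prep <- make_prepped_cohort(n = 300, effect_size = 0, seed = 8)
  fit <- fit_base_learner("random_forest",
                          cardiorisk:::features_matrix(prep$train),
                          prep$train$zone, seed = 8)
  acc <- mean(predict(fit, cardiorisk:::features_matrix(prep$test)) ==
                prep$test$zone)
  expect_lt(acc, 0.55) # chance is ~1/3 for three balanced-ish zones
})
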