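test_that("disease severity maps onto the declared zone schemes", {
  expect_identical(as.character(map_num_to_zone(c(0, 1, 3), "three")),
                   c("green", "yellow", "red"))
  expect_identical(as.character(map_num_to_zone(2, "two")), "red")
  expect_identical(as.character(map_num_to_zone(0:4, "two")),
                   c("green", rep("red", 4)))
  expect_error(map_num_to_zone(5, "three"), "0, \\.\\.\\., 4")
  expect_error(map_num_to_zone(NA, "three"))
})

test_that("chained-equation imputation recovers a linearly determined column", {
  set.seed(7)
  tbl <- tibble::tibble(A = runif(200, 1, 10))
  tbl$B <- 2 * tbl$A
  truth <- tbl$B
  masked <- sample(200, 20)
  tbl$B[masked] <- NA
  imp <- mice_impute(tbl)
  expect_false(anyNA(imp))
  rel_err <- abs(imp$B[masked] - truth[masked]) / truth[masked]
  expect_lt(max(rel_err), 0.05)
  # observed values untouched
  expect_identical(imp$B[-masked], truth[-masked])
  expect_identical(imp$A, tbl$A)
})

test_that("imputation respects categorical domains and degenerate inputs", {
  complete <- tibble::tibble(a = 1:10 + 0.5, b = 10:1 + 0)
  expect_identical(mice_impute(complete), complete)

  set.seed(8)
  coh <- simulate_cohort(n = 150, missing_rate = 0.15, seed = 3)
  imp <- mice_impute(coh[uci_used_columns()])
  expect_false(anyNA(imp))
  expect_true(all(imp$restecg %in% 0:2))
  expect_true(all(imp$cp %in% 1:4))

  allna <- tibble::tibble(a = rnorm(5), b = rep(NA_real_, 5))
  expect_error(mice_impute(allna), "entirely missing")
})

test_that("robust scaling gives median 0 and IQR 1 exactly, and resists outliers", {
  tbl <- tibble::tibble(chol = as.numeric(1:100))
  scaled <- robust_scale(tbl, "chol")
  expect_equal(stats::median(scaled$chol), 0)
  q <- stats::quantile(scaled$chol, c(0.25, 0.75), names = FALSE)
  expect_equal(q[2] - q[1], 1)

  # heavy-tailed column: robust scaling shrinks the outlier magnitude
  set.seed(9)
  v <- c(rnorm(200, 250, 30), 2000, 2500)
  rb <- (v - stats::median(v)) /
    (stats::quantile(v, 0.75) - stats::quantile(v, 0.25))
  zs <- (v - mean(v)) / stats::sd(v)
  # outliers inflate the SD, compressing everything, so the robust scale
  # keeps the bulk tighter while mean/sd scaling understates the outliers
  expect_lt(max(abs(zs)), max(abs(rb)))

  expect_warning(robust_scale(tibble::tibble(x = rep(5, 10)), "x"),
                 "zero IQR")
})

test_that("scaler state reproduces and inverts the training transform", {
  set.seed(10)
  tbl <- tibble::tibble(age = rnorm(50, 54, 9), chol = rnorm(50, 250, 50))
  scaled <- robust_scale(tbl)
  state <- attr(scaled, "scaler")
  fresh <- tibble::tibble(age = c(40, 60), chol = c(200, 300))
  again <- apply_scaler(fresh, state)
  expect_equal(again$age, (fresh$age - state$center[state$column == "age"]) /
                 state$scale[state$column == "age"])
  expect_equal(invert_scaler(again, state), fresh)
})

test_that("categorical encoding is the fixed 0..K-1 dictionary and round-trips", {
  tbl <- tibble::tibble(cp = c(1, 4, 2), sex = c(0, 1, 1),
                        slope = c(3, 1, 2))
  enc <- encode_categoricals(tbl)
  expect_identical(enc$cp, c(0L, 3L, 1L))
  expect_identical(enc$sex, c(0L, 1L, 1L))
  expect_identical(enc$slope, c(2L, 0L, 1L))
  dec <- decode_categoricals(enc, attr(enc, "encoder"))
  expect_equal(as.list(dec), as.list(tbl), ignore_attr = TRUE)
  expect_error(encode_categoricals(tibble::tibble(cp = 7)), "unseen")
})

test_that("oversampling balances to the majority count and keeps originals", {
  tbl <- tibble::tibble(x = seq_len(400),
                        zone = factor(rep(c("green", "red"), c(300, 100))))
  ov <- oversample(tbl, seed = 11)
  expect_identical(unname(table(ov$zone)["green"]), 300L)
  expect_identical(unname(table(ov$zone)["red"]), 300L)
  expect_true(all(tbl$x %in% ov$x))
  # majority multiset untouched
  expect_identical(sort(ov$x[ov$zone == "green"]), 1:300)

  three <- tibble::tibble(zone = factor(rep(c("g", "y", "r"),
                                            c(413, 258, 249))))
  ov3 <- oversample(three, seed = 12)
  expect_true(all(table(ov3$zone) == 413L))

  balanced <- tibble::tibble(zone = factor(rep(c("a", "b"), 50)))
  expect_identical(nrow(oversample(balanced, seed = 1)), 100L)
  expect_error(oversample(tibble::tibble(zone = rep("a", 5))), "two classes")
})

test_that("the 70/30 split partitions exactly, reproducibly, and stratifies", {
  tbl <- tibble::tibble(id = 1:100,
                        zone = factor(rep(c("g", "y", "r"), c(50, 30, 20))))
  sp <- split_70_30(tbl, seed = 13)
  expect_identical(nrow(sp$train), 70L)
  expect_identical(nrow(sp$test), 30L)
  expect_length(intersect(sp$train$id, sp$test$id), 0)

  sp2 <- split_70_30(tbl, seed = 13)
  expect_identical(sp$train$id, sp2$train$id)

  st <- split_70_30(tbl, seed = 14, stratified = TRUE)
  for (cl in c("g", "y", "r")) {
    n_cl <- sum(tbl$zone == cl)
    expect_lte(abs(sum(st$train$zone == cl) - 0.7 * n_cl), 1)
  }
})

test_that("the full recipe is deterministic and warns about pre-split oversampling", {
  coh <- simulate_cohort(n = 200, missing_rate = 0.1, seed = 15)
  expect_warning(p1 <- preprocess_recipe(coh, seed = 15), "leakage")
  expect_warning(p2 <- preprocess_recipe(coh, seed = 15), "leakage")
  expect_equal(as.data.frame(p1$train), as.data.frame(p2$train))
  expect_identical(p1$steps,
                   c("zone", "impute", "scale", "encode", "oversample",
                     "split"))
  pf <- suppressWarnings(preprocess_recipe(coh, seed = 15,
                                           split_first = TRUE))
  expect_identical(pf$steps,
                   c("zone", "impute", "scale", "encode", "split",
                     "oversample"))
  expect_false(anyNA(pf$train))
})
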