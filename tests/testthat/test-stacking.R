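# Shared well-separated cohort for the ensemble tests (module-level cache
# keeps the suite fast; every consumer treats it as read-only).
prep3 <- make_prepped_cohort(n = 360, scheme = "three", seed = 31)
prep2 <- make_prepped_cohort(n = 360, scheme = "two", seed = 32)

test_that("grid search returns the best point and an honest trace", {
  # empty grid: defaults, no search
  t0 <- tune_base_learner("decision_tree", prep3$train, grid = list(),
                          seed = 1)
  expect_false(any(t0$trace$searched))
  expect_identical(nrow(t0$trace), 1L)

  # one grid point: identical to a direct fit with those settings
  t1 <- tune_base_learner("knn", prep3$train, grid = list(k = 5), seed = 2)
  direct <- fit_base_learner("knn",
                             cardiorisk:::features_matrix(prep3$train),
                             prep3$train$zone, params = list(k = 5),
                             seed = 2)
  xt <- cardiorisk:::features_matrix(prep3$test)
  expect_identical(predict(t1$fit, xt), predict(direct, xt))
  expect_identical(t1$best_params$k, 5)

  # multi-point search keeps one score per point
  t2 <- tune_base_learner("svm", prep3$train, seed = 3)
  expect_identical(nrow(t2$trace),
                   nrow(expand.grid(default_grid("svm"))))
  expect_true(all(t2$trace$cv_macro_f1 >= 0 & t2$trace$cv_macro_f1 <= 1))
})

test_that("every learner family separates a near-separable cohort (macro-F1 >= 0.95)", {
  # wide 6-SD class separation: effectively linearly separable classes
  prep_sep <- make_prepped_cohort(n = 360, scheme = "three",
                                  effect_size = 6, seed = 31)
  xt <- cardiorisk:::features_matrix(prep_sep$test)
  lev <- levels(prep_sep$train$zone)
  for (nm in base_learner_names()) {
    fit <- fit_base_learner(nm, cardiorisk:::features_matrix(prep_sep$train),
                            prep_sep$train$zone, seed = 7)
    f1 <- cardiorisk:::macro_f1(predict(fit, xt), prep_sep$test$zone, lev)
    expect_gte(f1, 0.95)
  }
})

test_that("stack probabilities are proper and predictions match the argmax", {
  model <- build_stacking(prep3$train, stacking_spec(scheme = "three"),
                          seed = 5)
  p <- predict(model, prep3$test, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  zones <- predict(model, prep3$test, type = "zone")
  expect_identical(as.integer(zones), unname(max.col(p, ties.method = "first")))
  tb <- predict(model, prep3$test)
  expect_identical(names(tb), c("zone", model$levels))
})

test_that("a single-learner stack agrees with that learner's own labels", {
  spec1 <- stacking_spec(base_learners = "random_forest", scheme = "three")
  stack1 <- build_stacking(prep3$train, spec1, seed = 6)
  solo <- fit_base_learner("random_forest",
                           cardiorisk:::features_matrix(prep3$train),
                           prep3$train$zone, seed = 6)
  xt <- cardiorisk:::features_matrix(prep3$test)
  agreement <- mean(predict(stack1, prep3$test, type = "zone") ==
                      predict(solo, xt))
  expect_gte(agreement, 0.95)
})

test_that("the default stacks do not fall below their best base learner", {
  xt2 <- cardiorisk:::features_matrix(prep2$test)
  lev2 <- levels(prep2$train$zone)
  base_f1 <- vapply(c("knn", "xgb", "mlp"), function(nm) {
    fit <- fit_base_learner(nm, cardiorisk:::features_matrix(prep2$train),
                            prep2$train$zone, seed = 8)
    cardiorisk:::macro_f1(predict(fit, xt2), prep2$test$zone, lev2)
  }, numeric(1))
  stack <- build_stacking(prep2$train, stacking_spec(scheme = "two"),
                          seed = 8)
  stack_f1 <- cardiorisk:::macro_f1(
    predict(stack, prep2$test, type = "zone"), prep2$test$zone, lev2)
  expect_gte(stack_f1, max(base_f1) - 0.02)
})

test_that("stacking guards its fold and class preconditions", {
  tiny <- prep3$train[c(1:4, 150:153, 300:303), ]
  expect_error(build_stacking(tiny, stacking_spec(scheme = "three",
                                                  n_folds = 10)),
               "minority-class")
  expect_error(stacking_spec(base_learners = c("knn", "nope")), "Unknown")
  expect_error(stacking_spec(base_learners = c("knn", "knn", "xgb")),
               "distinct")
})

test_that("the combination search enumerates all 16 subsets, ranked and reproducible", {
  cand <- c("svm", "knn", "xgb", "mlp", "naive_bayes")
  rank1 <- enumerate_stack_combinations(prep3$train, prep3$test, cand,
                                        seed = 9)
  expect_identical(nrow(rank1), 16L)
  expect_identical(sort(unique(rank1$size)), c(3L, 4L, 5L))
  expect_false(is.unsorted(rev(rank1$macro_f1)))

  rank2 <- enumerate_stack_combinations(prep3$train, prep3$test, cand,
                                        seed = 9)
  expect_identical(rank1$combination, rank2$combination)
  expect_equal(rank1$macro_f1, rank2$macro_f1)

  expect_error(enumerate_stack_combinations(prep3$train, prep3$test,
                                            cand[1:4]),
               "Exactly 5")
})

test_that("confusion-matrix bookkeeping is exact", {
  truth <- factor(c("a", "a", "b", "b", "c"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "b", "b", "b", "c"), levels = c("a", "b", "c"))
  rep <- evaluate_classifier(pred, truth)
  expect_identical(sum(rep$confusion), 5L)
  expect_equal(unname(rowSums(rep$confusion)), c(2, 2, 1))
  expect_equal(unname(colSums(rep$confusion)), c(1, 3, 1))
  expect_equal(rep$accuracy, 4 / 5)

  perfect <- evaluate_classifier(truth, truth)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$accuracy, 1)

  expect_error(evaluate_classifier(c("a", "z"), c("a", "a"),
                                   levels = c("a", "b")), "outside")
  expect_warning(
    evaluate_classifier(factor(c("a", "a"), levels = c("a", "b")),
                        factor(c("a", "b"), levels = c("a", "b"))),
    "Zero-denominator")
})

test_that("rank-statistic AUC behaves as the Mann-Whitney functional", {
  # perfectly separating probabilities
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  colnames(probs) <- c("g", "r")
  auc <- roc_auc_report(probs, c("g", "g", "r", "r"))
  expect_equal(auc$auc, c(1, 1))

  # score reversal maps a -> 1 - a
  set.seed(33)
  p1 <- runif(200)
  probs2 <- cbind(g = p1, r = 1 - p1)
  y <- sample(c("g", "r"), 200, replace = TRUE)
  a <- roc_auc_report(probs2, y)$auc[1]
  probs_rev <- cbind(g = 1 - p1, r = p1)
  expect_equal(roc_auc_report(probs_rev, y)$auc[1], 1 - a)

  # label-independent probabilities concentrate near 1/2
  set.seed(34)
  pnull <- runif(10000)
  probsn <- cbind(g = pnull, r = 1 - pnull)
  yn <- sample(c("g", "r"), 10000, replace = TRUE)
  expect_lt(abs(roc_auc_report(probsn, yn)$auc[1] - 0.5), 0.02)

  # class absent from truth -> undefined
  expect_true(is.na(roc_auc_report(probs, c("g", "g", "g", "g"))$auc[2]))
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(35)
  score <- runif(150)
  y <- factor(ifelse(score + rnorm(150, 0, 0.3) > 0.5, "pos", "neg"),
              levels = c("neg", "pos"))
  probs <- cbind(neg = 1 - score, pos = score)
  mine <- roc_auc_report(probs, y)$auc[2]
  ref <- as.numeric(pROC::auc(pROC::roc(y, score, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("tune -> stack -> evaluate is deterministic under a fixed seed", {
  run_once <- function() {
    model <- build_stacking(prep2$train, stacking_spec(scheme = "two"),
                            seed = 12)
    pred <- predict(model, prep2$test, type = "zone")
    glance(evaluate_classifier(pred, prep2$test$zone,
                               levels = model$levels))
  }
  expect_equal(as.data.frame(run_once()), as.data.frame(run_once()))
})
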