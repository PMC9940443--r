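#' Stacking-ensemble specification
#'
#' Describes a stacked generalization model: the ordered set of base
#' learners whose out-of-fold class probabilities become meta-features, the
#' zone scheme, and the fold count used to produce those meta-features. The
#' defaults are the winning combinations of the exhaustive search:
#' KNN + XGB + MLP for two-zone and SVM + KNN + XGB for three-zone
#' classification, under a logistic-regression meta-classifier.
#'
#' @param base_learners Character vector of learner names
#'   (subset of [base_learner_names()]).
#' @param scheme `"three"` or `"two"`.
#' @param n_folds Folds for out-of-fold meta-feature generation.
#' @return A `stacking_spec` list.
#' @export
stacking_spec <- function(base_learners = NULL,
                          scheme = c("three", "two"), n_folds = 5) {
  scheme <- match.arg(scheme)
  if (is.null(base_learners)) {
    base_learners <- if (scheme == "two") {
      c("knn", "xgb", "mlp")
    } else {
      c("svm", "knn", "xgb")
    }
  }
  unknown <- setdiff(base_learners, base_learner_names())
  if (length(unknown) > 0L) {
    stop("Unknown base learner(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(base_learners)) {
    stop("Base learners must be distinct.", call. = FALSE)
  }
  structure(list(base_learners = base_learners, scheme = scheme,
                 n_folds = n_folds, meta_learner = "logistic_regression"),
            class = "stacking_spec")
}

meta_feature_names <- function(learners, lev) {
  unlist(lapply(learners, function(l) paste(l, lev, sep = "_")))
}

fit_meta_logistic <- function(meta_x, y) {
  df <- data.frame(.y = y, meta_x, check.names = TRUE)
  nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500,
                 decay = 1e-4)
}

predict_meta_logistic <- function(meta, meta_x, lev) {
  df <- data.frame(meta_x, check.names = TRUE)
  p <- stats::predict(meta, newdata = df, type = "probs")
  if (is.null(dim(p))) {  # two classes: multinom returns P(second level)
    p <- cbind(1 - p, p)
    colnames(p) <- lev
  }
  normalize_proba(as.matrix(p), lev)
}

# Out-of-fold class probabilities for one learner over a fold assignment.
oof_probabilities <- function(name, x, y, folds, params = list(), seed = 1) {
  lev <- levels(y)
  out <- matrix(NA_real_, nrow = nrow(x), ncol = length(lev),
                dimnames = list(NULL, lev))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_base_learner(name, x[tr, , drop = FALSE], y[tr],
                            params = params, seed = seed + f)
    out[!tr, ] <- predict_proba(fit, x[!tr, , drop = FALSE])
  }
  out
}

#' Build a stacking ensemble
#'
#' Trains the stack in the standard leakage-free way: each base learner's
#' meta-features are its out-of-fold class probabilities under `n_folds`
#' stratified cross-validation on the training table; the logistic-
#' regression meta-classifier is fit on those; finally every base learner is
#' refit on the full training table for use at prediction time.
#'
#' @param train Labeled training table (numeric features + label column).
#' @param spec A [stacking_spec()].
#' @param label Label column name.
#' @param params Optional named list of per-learner hyperparameter lists
#'   (e.g. from [tune_base_learner()] best params); defaults otherwise.
#' @param seed Seed for folds and stochastic learners.
#' @return A `stacking_model` with `predict()`, `tidy()` and `glance()`
#'   methods.
#' @export
build_stacking <- function(train, spec = stacking_spec(), label = "zone",
                           params = list(), seed = 1) {
  stopifnot(inherits(spec, "stacking_spec"))
  y <- droplevels(as.factor(train[[label]]))
  if (nlevels(y) < 2L) stop("Need at least two classes.", call. = FALSE)
  if (min(table(y)) < spec$n_folds) {
    stop(sprintf(
      "n_folds (%d) exceeds the minority-class size (%d).",
      spec$n_folds, min(table(y))), call. = FALSE)
  }
  x <- features_matrix(train, label)
  lev <- levels(y)
  folds <- make_folds(y, spec$n_folds, seed = seed)

  oof <- lapply(spec$base_learners, function(nm) {
    oof_probabilities(nm, x, y, folds,
                      params = params[[nm]] %||% list(), seed = seed)
  })
  meta_x <- do.call(cbind, oof)
  colnames(meta_x) <- meta_feature_names(spec$base_learners, lev)
  meta <- fit_meta_logistic(meta_x, y)

  base_fits <- lapply(spec$base_learners, function(nm) {
    fit_base_learner(nm, x, y, params = params[[nm]] %||% list(),
                     seed = seed)
  })
  names(base_fits) <- spec$base_learners

  structure(list(spec = spec, base_fits = base_fits, meta = meta,
                 levels = lev, label = label,
                 feature_names = colnames(x), seed = seed),
            class = "stacking_model")
}

stack_base_matrix <- function(object, newx) {
  probs <- lapply(object$base_fits, function(f) predict_proba(f, newx))
  meta_x <- do.call(cbind, probs)
  colnames(meta_x) <- meta_feature_names(object$spec$base_learners,
                                         object$levels)
  meta_x
}

#' Predict risk zones from a stacking model
#'
#' @param object A `stacking_model`.
#' @param newdata Data frame with the training feature columns (a label
#'   column, if present, is ignored).
#' @param type `"tibble"` (zone + per-class probabilities, the default),
#'   `"prob"` (probability matrix) or `"zone"` (factor).
#' @param ... Unused.
#' @return See `type`. Zone is the probability argmax; on exact ties the
#'   lowest class index wins.
#' @export
predict.stacking_model <- function(object, newdata,
                                   type = c("tibble", "prob", "zone"),
                                   ...) {
  type <- match.arg(type)
  newx <- if (is.matrix(newdata)) {
    newdata
  } else {
    cols <- setdiff(names(newdata), object$label)
    features_matrix(newdata[cols], label = NULL)
  }
  newx <- newx[, object$feature_names, drop = FALSE]
  p <- predict_meta_logistic(object$meta, stack_base_matrix(object, newx),
                             object$levels)
  zone <- factor(object$levels[max.col(p, ties.method = "first")],
                 levels = object$levels)
  switch(type,
    prob = p,
    zone = zone,
    tibble = dplyr::bind_cols(
      tibble::tibble(zone = zone),
      tibble::as_tibble(as.data.frame(p, check.names = FALSE))))
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf(
    "<stacking_model> %s-zone | base: %s | meta: logistic regression (%d-fold OOF)\n",
    x$spec$scheme, paste(x$spec$base_learners, collapse = ", "),
    x$spec$n_folds))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stacking_model <- function(x, ...) {
  tibble::tibble(
    learner = x$spec$base_learners,
    params = vapply(x$base_fits, function(f) {
      paste(sprintf("%s=%s", names(f$params), unlist(f$params)),
            collapse = ", ")
    }, character(1)))
}

#' @exportS3Method generics::glance
glance.stacking_model <- function(x, ...) {
  tibble::tibble(scheme = x$spec$scheme,
                 n_base = length(x$spec$base_learners),
                 base = paste(x$spec$base_learners, collapse = ","),
                 n_folds = x$spec$n_folds,
                 n_classes = length(x$levels))
}

#' Exhaustive search over base-learner combinations
#'
#' Evaluates every stacking ensemble built from 3, 4 or 5 of exactly five
#' candidate learners — `choose(5,3) + choose(5,4) + choose(5,5) = 16`
#' subsets. Each learner's out-of-fold training probabilities and full-fit
#' test probabilities are computed once and shared across subsets, so only
#' the meta-classifier is refit per combination.
#'
#' @param train,test Labeled tables (numeric features + label column).
#' @param candidates Exactly five learner names.
#' @param label Label column name.
#' @param n_folds Folds for the out-of-fold meta-features.
#' @param seed Seed for folds and stochastic learners.
#' @return Tibble ranked by decreasing macro-F1 on `test`: `combination`,
#'   `size`, `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
enumerate_stack_combinations <- function(train, test, candidates,
                                         label = "zone", n_folds = 5,
                                         seed = 1) {
  if (length(candidates) != 5L) {
    stop("Exactly 5 candidate learners are required (got ",
         length(candidates), ").", call. = FALSE)
  }
  unknown <- setdiff(candidates, base_learner_names())
  if (length(unknown) > 0L) {
    stop("Unknown base learner(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y <- droplevels(as.factor(train[[label]]))
  y_test <- factor(as.character(test[[label]]), levels = levels(y))
  x <- features_matrix(train, label)
  x_test <- features_matrix(test, label)[, colnames(x), drop = FALSE]
  lev <- levels(y)
  folds <- make_folds(y, n_folds, seed = seed)

  oof <- lapply(candidates, function(nm) {
    oof_probabilities(nm, x, y, folds, seed = seed)
  })
  test_probs <- lapply(candidates, function(nm) {
    fit <- fit_base_learner(nm, x, y, seed = seed)
    predict_proba(fit, x_test)
  })
  names(oof) <- names(test_probs) <- candidates

  subsets <- unlist(lapply(3:5, function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map_dfr(subsets, function(ss) {
    meta_x <- do.call(cbind, oof[ss])
    colnames(meta_x) <- meta_feature_names(ss, lev)
    meta <- fit_meta_logistic(meta_x, y)
    test_x <- do.call(cbind, test_probs[ss])
    colnames(test_x) <- meta_feature_names(ss, lev)
    p <- predict_meta_logistic(meta, test_x, lev)
    pred <- factor(lev[max.col(p, ties.method = "first")], levels = lev)
    rep <- evaluate_classifier(pred, y_test, levels = lev)
    tibble::tibble(combination = paste(ss, collapse = "+"),
                   size = length(ss),
                   accuracy = rep$accuracy,
                   macro_precision = rep$macro_precision,
                   macro_recall = rep$macro_recall,
                   macro_f1 = rep$macro_f1)
  })
  dplyr::arrange(rows, dplyr::desc(.data$macro_f1))
}
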