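#' Base-learner families
#'
#' The ten classifier families available as stacking base learners:
#' k-nearest neighbours, naive Bayes, random forest, support-vector machine
#' (RBF), gradient boosting, a linear model trained by stochastic gradient
#' descent, extreme gradient boosting, a single-hidden-layer perceptron,
#' a decision tree, and AdaBoost (SAMME over shallow trees).
#'
#' @return Character vector of learner names.
#' @export
base_learner_names <- function() {
  c("knn", "naive_bayes", "random_forest", "svm", "gradient_boosting",
    "sgd", "xgb", "mlp", "decision_tree", "adaboost")
}

#' Default hyperparameter grids
#'
#' Modest declared grids searched by [tune_base_learner()]. Grids are kept
#' small on purpose; every searched value is recorded in the tuning trace so
#' a run is fully reproducible from its manifest.
#'
#' @param name A learner name from [base_learner_names()].
#' @return A named list of parameter value vectors (possibly empty).
#' @export
default_grid <- function(name) {
  switch(match.arg(name, base_learner_names()),
    knn = list(k = c(3, 5, 9)),
    naive_bayes = list(laplace = c(0, 1)),
    random_forest = list(ntree = 300, mtry = c(2, 3)),
    svm = list(cost = c(1, 10), gamma = c(0.05, 0.2)),
    gradient_boosting = list(nrounds = 100, max_depth = c(2, 3)),
    sgd = list(lr = 0.1, epochs = 50, lambda = c(1e-4, 1e-2)),
    xgb = list(nrounds = 50, max_depth = c(3, 6)),
    mlp = list(size = c(5, 10), decay = 0.01),
    decision_tree = list(cp = c(0.01, 0.001)),
    adaboost = list(n_rounds = 50, maxdepth = 2)
  )
}

default_params <- function(name) {
  lapply(default_grid(name), `[[`, 1)
}

features_matrix <- function(data, label = "zone") {
  cols <- setdiff(names(data), label)
  x <- as.matrix(as.data.frame(lapply(data[cols], as.numeric)))
  storage.mode(x) <- "double"
  x
}

# columns in `lev` order, rows renormalized to sum to 1
normalize_proba <- function(p, lev) {
  p <- p[, lev, drop = FALSE]
  p <- pmax(p, 0)
  sweep(p, 1, pmax(rowSums(p), .Machine$double.eps), "/")
}

fit_xgb_family <- function(x, y, nrounds, max_depth, eta, seed) {
  k <- nlevels(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  params <- list(objective = "multi:softprob", num_class = k,
                 max_depth = max_depth, eta = eta, nthread = 1,
                 seed = seed %% .Machine$integer.max)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

predict_xgb_family <- function(model, newx, lev) {
  p <- stats::predict(model, xgboost::xgb.DMatrix(newx))
  p <- matrix(p, ncol = length(lev), byrow = FALSE)
  # xgboost >= 3 returns an n x K matrix already; older returns a vector
  if (nrow(p) != nrow(newx)) {
    p <- matrix(as.numeric(p), nrow = nrow(newx), byrow = TRUE)
  }
  colnames(p) <- lev
  normalize_proba(p, lev)
}

fit_sgd_logistic <- function(x, y, lr, epochs, lambda, seed) {
  set.seed(seed)
  k <- nlevels(y)
  p <- ncol(x)
  W <- matrix(0, nrow = p + 1L, ncol = k)
  xb <- cbind(1, x)
  yi <- as.integer(y)
  n <- nrow(x)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t_step <- t_step + 1L
      eta_t <- lr / (1 + lr * lambda * t_step)
      z <- drop(xb[i, ] %*% W)
      z <- z - max(z)
      pr <- exp(z) / sum(exp(z))
      grad_out <- pr
      grad_out[yi[i]] <- grad_out[yi[i]] - 1
      W <- W - eta_t * outer(xb[i, ], grad_out)
      W[-1, ] <- W[-1, ] - eta_t * lambda * W[-1, ]  # L2 on non-intercept rows
    }
  }
  W
}

predict_sgd_logistic <- function(W, newx, lev) {
  z <- cbind(1, newx) %*% W
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p <- p / rowSums(p)
  colnames(p) <- lev
  p
}

fit_adaboost_samme <- function(x, y, n_rounds, maxdepth, seed) {
  set.seed(seed)
  k <- nlevels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 5,
                          xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k || err <= 0) {
      if (err <= 0) {  # perfect stump: keep with a capped weight and stop
        stumps[[length(stumps) + 1L]] <- fit
        alphas <- c(alphas, log((1 - 1e-10) / 1e-10) + log(k - 1))
      }
      break
    }
    alpha <- log((1 - err) / err) + log(k - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {
    stop("AdaBoost could not fit any weak learner.", call. = FALSE)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost_samme <- function(model, newx, lev) {
  votes <- matrix(0, nrow = nrow(newx), ncol = length(lev),
                  dimnames = list(NULL, lev))
  df <- as.data.frame(newx)
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(newx)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(newx)), as.integer(pred))] + model$alphas[[m]]
  }
  normalize_proba(votes + 1e-12, lev)
}

#' Fit one base learner
#'
#' Uniform fitting interface over the ten learner families. Parameters not
#' supplied fall back to the first value of the declared default grid.
#'
#' @param name Learner name from [base_learner_names()].
#' @param x Numeric feature matrix.
#' @param y Factor of class labels.
#' @param params Named list of hyperparameters.
#' @param seed Seed for the stochastic learners.
#' @return A `base_fit` object usable with [predict_proba()].
#' @export
fit_base_learner <- function(name, x, y, params = list(), seed = 1) {
  name <- match.arg(name, base_learner_names())
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("Need at least two classes.", call. = FALSE)
  pars <- utils::modifyList(default_params(name), params)
  set.seed(seed)
  lev <- levels(y)
  model <- switch(name,
    knn = caret::knn3(x, y, k = pars$k),
    naive_bayes = e1071::naiveBayes(x, y, laplace = pars$laplace),
    random_forest = randomForest::randomForest(
      x, y, ntree = pars$ntree, mtry = min(pars$mtry, ncol(x))),
    svm = e1071::svm(x, y, probability = TRUE, kernel = "radial",
                     cost = pars$cost, gamma = pars$gamma),
    gradient_boosting = fit_xgb_family(
      x, y, nrounds = pars$nrounds, max_depth = pars$max_depth,
      eta = 0.1, seed = seed),
    sgd = fit_sgd_logistic(x, y, lr = pars$lr, epochs = pars$epochs,
                           lambda = pars$lambda, seed = seed),
    xgb = fit_xgb_family(x, y, nrounds = pars$nrounds,
                         max_depth = pars$max_depth, eta = 0.3, seed = seed),
    mlp = nnet::nnet(x, nnet::class.ind(y), softmax = TRUE,
                     size = pars$size, decay = pars$decay, maxit = 200,
                     trace = FALSE, MaxNWts = 10000),
    decision_tree = rpart::rpart(
      .y ~ ., data = data.frame(.y = y, x, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(cp = pars$cp, xval = 0)),
    adaboost = fit_adaboost_samme(x, y, n_rounds = pars$n_rounds,
                                  maxdepth = pars$maxdepth, seed = seed)
  )
  structure(list(name = name, model = model, levels = lev, params = pars,
                 seed = seed, feature_names = colnames(x)),
            class = "base_fit")
}

#' Class-probability predictions from a base learner
#'
#' @param fit A `base_fit` from [fit_base_learner()].
#' @param newx Numeric feature matrix with the training columns.
#' @return An `n x K` matrix of class probabilities (columns in training
#'   level order; rows sum to 1).
#' @export
predict_proba <- function(fit, newx) {
  stopifnot(inherits(fit, "base_fit"))
  lev <- fit$levels
  p <- switch(fit$name,
    knn = stats::predict(fit$model, newx, type = "prob"),
    naive_bayes = stats::predict(fit$model, newx, type = "raw"),
    random_forest = stats::predict(fit$model, newx, type = "prob"),
    svm = {
      pr <- stats::predict(fit$model, newx, probability = TRUE)
      attr(pr, "probabilities")
    },
    gradient_boosting = predict_xgb_family(fit$model, newx, lev),
    sgd = predict_sgd_logistic(fit$model, newx, lev),
    xgb = predict_xgb_family(fit$model, newx, lev),
    mlp = {
      pm <- stats::predict(fit$model, newx)
      colnames(pm) <- colnames(fit$model$fitted.values)
      pm
    },
    decision_tree = stats::predict(fit$model, as.data.frame(newx),
                                   type = "prob"),
    adaboost = predict_adaboost_samme(fit$model, newx, lev)
  )
  p <- as.matrix(p)
  if (is.null(colnames(p)) || !all(lev %in% colnames(p))) {
    colnames(p) <- lev
  }
  normalize_proba(p, lev)
}

#' @export
predict.base_fit <- function(object, newx, ...) {
  p <- predict_proba(object, newx)
  # argmax tie-break: lowest class index wins
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

# Stratified fold assignment (1..k) for cross-validation.
make_folds <- function(y, k, seed = 1) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(droplevels(as.factor(y)))) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Grid-search tuning of a base learner
#'
#' Exhaustive search over the declared grid, scored by macro-F1 under
#' stratified k-fold cross-validation on the training table; the best point
#' (first on ties) is refit on the full training data. An empty grid skips
#' the search and fits the declared defaults, which the trace records.
#'
#' @param name Learner name from [base_learner_names()].
#' @param train Labeled training table (numeric features + label column).
#' @param label Label column name.
#' @param grid Named list of parameter value vectors; defaults to
#'   [default_grid()]. Pass `list()` to skip the search.
#' @param n_folds Cross-validation folds.
#' @param seed Seed for folds and stochastic learners.
#' @return A `tuned_learner`: the refit `base_fit` plus a `trace` tibble of
#'   every searched point and its CV macro-F1.
#' @export
tune_base_learner <- function(name, train, label = "zone",
                              grid = default_grid(name), n_folds = 3,
                              seed = 1) {
  name <- match.arg(name, base_learner_names())
  y <- droplevels(as.factor(train[[label]]))
  x <- features_matrix(train, label)
  if (length(grid) == 0L) {
    fit <- fit_base_learner(name, x, y, seed = seed)
    trace <- tibble::tibble(params = list(fit$params), cv_macro_f1 = NA_real_,
                            searched = FALSE)
    return(structure(list(name = name, fit = fit, trace = trace,
                          best_params = fit$params),
                     class = "tuned_learner"))
  }
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  folds <- make_folds(y, n_folds, seed = seed)
  scores <- vapply(seq_len(nrow(points)), function(i) {
    pars <- as.list(points[i, , drop = FALSE])
    f1 <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_base_learner(name, x[tr, , drop = FALSE], y[tr],
                              params = pars, seed = seed + f)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      macro_f1(pred, y[!tr], levels = levels(y))
    }, numeric(1))
    mean(f1)
  }, numeric(1))
  best <- which.max(scores)
  best_params <- as.list(points[best, , drop = FALSE])
  fit <- fit_base_learner(name, x, y, params = best_params, seed = seed)
  trace <- tibble::tibble(
    params = lapply(seq_len(nrow(points)), function(i) as.list(points[i, ])),
    cv_macro_f1 = scores, searched = TRUE)
  structure(list(name = name, fit = fit, trace = trace,
                 best_params = best_params),
            class = "tuned_learner")
}

#' @exportS3Method generics::tidy
tidy.tuned_learner <- function(x, ...) {
  dplyr::mutate(x$trace,
                params = vapply(.data$params, function(p) {
                  paste(sprintf("%s=%s", names(p), unlist(p)),
                        collapse = ", ")
                }, character(1)))
}

#' @exportS3Method generics::glance
glance.tuned_learner <- function(x, ...) {
  tibble::tibble(
    learner = x$name,
    n_searched = nrow(x$trace),
    best_cv_macro_f1 = if (all(is.na(x$trace$cv_macro_f1))) NA_real_ else
      max(x$trace$cv_macro_f1, na.rm = TRUE),
    best_params = paste(sprintf("%s=%s", names(x$best_params),
                                unlist(x$best_params)), collapse = ", "))
}
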