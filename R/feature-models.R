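#' Correlation-screened feature selection
#'
#' Pearson correlation of every candidate column with the target; columns
#' with `|r| >= threshold` are retained. Shared by the oldpeak regressor and
#' the restecg classifier.
#'
#' @param data Data frame with the target and candidate columns (numeric or
#'   numerically coded categoricals).
#' @param target Name of the target column.
#' @param threshold Absolute-correlation cutoff in `[0, 1]`.
#' @return Tibble with `feature`, `correlation`, `selected`.
#' @export
correlation_screen <- function(data, target, threshold = 0.2) {
  stopifnot(target %in% names(data))
  candidates <- setdiff(names(data), target)
  y <- as.numeric(data[[target]])
  cors <- vapply(candidates, function(cl) {
    x <- as.numeric(data[[cl]])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  tibble::tibble(
    feature = candidates,
    correlation = unname(cors),
    selected = abs(unname(cors)) >= threshold
  )
}

#' Oldpeak regression from correlated attributes
#'
#' Fits a support-vector regression (radial kernel) predicting the `oldpeak`
#' attribute (exercise-induced ST depression, 0-6.2) from the table columns
#' whose absolute Pearson correlation with oldpeak meets the threshold.
#' Predictions are clipped to the attribute's observed domain `[0, 6.2]`.
#'
#' @param data Data frame containing `oldpeak` and candidate predictors.
#' @param correlation_threshold Absolute-correlation cutoff for selection.
#' @param clip Two-element range predictions are clipped to.
#' @return An object of class `oldpeak_model` with `tidy()`/`glance()`
#'   methods and a `predict()` method taking new data frames.
#' @export
fit_oldpeak_regressor <- function(data, correlation_threshold = 0.2,
                                  clip = c(0, 6.2)) {
  if (!"oldpeak" %in% names(data)) {
    stop("`data` must contain an `oldpeak` column.", call. = FALSE)
  }
  screen <- correlation_screen(data, "oldpeak", correlation_threshold)
  sel <- screen$feature[screen$selected]
  if (length(sel) == 0L) {
    stop(paste0(
      "No feature reaches |r| >= ", correlation_threshold,
      " with oldpeak. Computed correlations: ",
      paste(sprintf("%s=%.3f", screen$feature, screen$correlation),
            collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(lapply(data[sel], as.numeric)))
  fit <- e1071::svm(x, as.numeric(data$oldpeak), type = "eps-regression",
                    kernel = "radial")
  structure(
    list(fit = fit, features = sel, screen = screen, clip = clip,
         threshold = correlation_threshold, n = nrow(data)),
    class = "oldpeak_model")
}

#' @export
predict.oldpeak_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("Missing selected predictor(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(lapply(newdata[object$features], as.numeric)))
  p <- as.numeric(stats::predict(object$fit, x))
  pmin(pmax(p, object$clip[1]), object$clip[2])
}

#' Resting-ECG classification from correlated attributes
#'
#' Fits a support-vector classifier predicting the ordinal `restecg`
#' attribute (0 = normal, 1 = ST-T wave abnormality, 2 = probable/definite
#' left-ventricular hypertrophy) after the same correlation screening as the
#' oldpeak model. Predictions are always within `{0, 1, 2}`.
#'
#' @inheritParams fit_oldpeak_regressor
#' @param data Data frame containing `restecg` (values in `{0, 1, 2}`) and
#'   candidate predictors.
#' @return An object of class `restecg_model`.
#' @export
fit_restecg_classifier <- function(data, correlation_threshold = 0.2) {
  if (!"restecg" %in% names(data)) {
    stop("`data` must contain a `restecg` column.", call. = FALSE)
  }
  y <- as.integer(data$restecg)
  if (!all(y %in% 0:2)) {
    stop("`restecg` values must be in {0, 1, 2}.", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("`restecg` training labels contain a single class.", call. = FALSE)
  }
  screen <- correlation_screen(data, "restecg", correlation_threshold)
  sel <- screen$feature[screen$selected]
  if (length(sel) == 0L) {
    stop(paste0(
      "No feature reaches |r| >= ", correlation_threshold,
      " with restecg. Computed correlations: ",
      paste(sprintf("%s=%.3f", screen$feature, screen$correlation),
            collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(lapply(data[sel], as.numeric)))
  fit <- e1071::svm(x, factor(y, levels = 0:2), type = "C-classification",
                    kernel = "radial")
  structure(
    list(fit = fit, features = sel, screen = screen,
         threshold = correlation_threshold, n = nrow(data)),
    class = "restecg_model")
}

#' @export
predict.restecg_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("Missing selected predictor(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(lapply(newdata[object$features], as.numeric)))
  as.integer(as.character(stats::predict(object$fit, x)))
}

#' @exportS3Method generics::tidy
tidy.oldpeak_model <- function(x, ...) x$screen

#' @exportS3Method generics::tidy
tidy.restecg_model <- function(x, ...) x$screen

#' @exportS3Method generics::glance
glance.oldpeak_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 threshold = x$threshold,
                 features = paste(x$features, collapse = ","))
}

#' @exportS3Method generics::glance
glance.restecg_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 threshold = x$threshold,
                 features = paste(x$features, collapse = ","))
}
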