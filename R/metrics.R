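#' Confusion-matrix evaluation with macro averaging
#'
#' Builds the confusion matrix (rows = true classes, columns = predicted)
#' and derives accuracy (`trace / total`) plus per-class precision, recall
#' and F1 with their unweighted (macro) means. A per-class metric whose
#' denominator is zero (a class never predicted, or absent from the truth)
#' is defined as 0, with a warning.
#'
#' @param predictions Predicted labels.
#' @param truth True labels of the same length.
#' @param levels Class set; defaults to the union of factor levels of the
#'   two inputs. A label outside this set is an error.
#' @return A `metric_report`: list with `confusion` (matrix), `accuracy`,
#'   `per_class` (tibble), `macro_precision`, `macro_recall`, `macro_f1`,
#'   `n`. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @examples
#' truth <- factor(c("green", "green", "red", "red"))
#' pred <- factor(c("green", "red", "red", "red"))
#' glance(evaluate_classifier(pred, truth))
#' @export
evaluate_classifier <- function(predictions, truth, levels = NULL) {
  if (length(predictions) != length(truth)) {
    stop("`predictions` and `truth` must have equal length.", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- union(base::levels(as.factor(truth)),
                    base::levels(as.factor(predictions)))
  }
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  outside <- setdiff(unique(c(predictions, truth)), levels)
  if (length(outside) > 0L) {
    stop("Label(s) outside the class set: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  tf <- factor(truth, levels = levels)
  pf <- factor(predictions, levels = levels)
  cm <- table(truth = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(levels),
               dimnames = list(truth = levels, predicted = levels))
  n <- sum(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)

  zero_den <- pred_tot == 0 | true_tot == 0
  if (any(zero_den)) {
    warning("Zero-denominator metric(s) for class(es) ",
            paste(levels[zero_den], collapse = ", "),
            ": reported as 0.", call. = FALSE)
  }
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    class = levels, support = as.integer(true_tot),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1))
  structure(list(
    confusion = cm,
    accuracy = sum(tp) / n,
    per_class = per_class,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    n = n), class = "metric_report")
}

# macro-F1 on labels directly (tuning hot path; no warnings)
macro_f1 <- function(predictions, truth, levels) {
  tf <- factor(as.character(truth), levels = levels)
  pf <- factor(as.character(predictions), levels = levels)
  cm <- table(tf, pf)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  mean(ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$confusion)
  cat(sprintf(
    "accuracy %.3f | macro precision %.3f | macro recall %.3f | macro F1 %.3f (n = %d)\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metric_report <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.metric_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1,
                 n = x$n)
}

# Mann-Whitney AUC from scores: P(score_pos > score_neg) with tie credit 1/2.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC-AUC per class
#'
#' Area under the ROC curve for each class against the rest, computed by the
#' rank-statistic (Mann-Whitney) formulation on that class's predicted
#' probability column; ties receive half credit. A class absent from the
#' truth has no defined AUC and is reported as `NA`.
#'
#' @param probabilities Numeric matrix (or data frame) of class
#'   probabilities, one column per class, rows summing to 1.
#' @param truth True labels; values must match the probability column names.
#' @return Tibble with `class`, `auc`, `n_positive`.
#' @export
roc_auc_report <- function(probabilities, truth) {
  probabilities <- as.matrix(probabilities)
  if (is.null(colnames(probabilities))) {
    stop("`probabilities` must have class names as column names.",
         call. = FALSE)
  }
  row_sums <- rowSums(probabilities)
  if (any(abs(row_sums - 1) > 1e-6)) {
    stop("Probability rows must sum to 1.", call. = FALSE)
  }
  truth <- as.character(truth)
  if (length(truth) != nrow(probabilities)) {
    stop("`truth` length must match the probability rows.", call. = FALSE)
  }
  classes <- colnames(probabilities)
  purrr::map_dfr(classes, function(cl) {
    pos <- truth == cl
    tibble::tibble(class = cl,
                   auc = rank_auc(probabilities[, cl], pos),
                   n_positive = sum(pos))
  })
}

#' @rdname autoplot_cardiorisk
#' @exportS3Method ggplot2::autoplot
autoplot.metric_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted zone", y = "True zone",
                  title = sprintf("Accuracy %.1f%% (n = %d)",
                                  100 * object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}
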