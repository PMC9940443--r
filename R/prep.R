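#' Chained-equation imputation
#'
#' Fills missing values by iterated per-column regression, the chained-
#' equations scheme: initialize missing entries from the column mean (mode
#' for categoricals), then cycle through the incomplete columns, regressing
#' each on all other attributes over the originally observed rows and
#' replacing its missing entries with the model predictions. One completed
#' dataset is produced. Iteration stops after `max_iter` cycles or when the
#' largest absolute change in any imputed value falls below `tol`.
#'
#' Categorical columns (identified from the heart-disease schema, or via
#' `categorical_cols`) are imputed on their numeric coding and then rounded
#' and clamped to their admissible domain, so an imputed `restecg` is always
#' one of 0, 1, 2.
#'
#' @param data Data frame; missing entries are `NA`.
#' @param max_iter Maximum number of chained cycles.
#' @param tol Convergence tolerance on the largest absolute change in an
#'   imputed value between cycles.
#' @param categorical_cols Names of columns to treat as categorical;
#'   defaults to the schema's categorical attributes present in `data`.
#' @param seed Optional seed, accepted for interface uniformity; the
#'   regression-mean scheme is deterministic.
#' @return A tibble with no missing values; observed entries unchanged.
#' @examples
#' tbl <- tibble::tibble(a = rnorm(50), b = 2 * rnorm(50))
#' tbl$b[1:5] <- NA
#' mice_impute(tbl)
#' @export
mice_impute <- function(data, max_iter = 10, tol = 1e-3,
                        categorical_cols = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) return(data)
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (!setequal(num_cols, names(data))) {
    stop("All columns must be numeric (encode categoricals first).",
         call. = FALSE)
  }
  if (is.null(categorical_cols)) {
    categorical_cols <- intersect(names(uci_domains()), names(data))
  }
  mask <- is.na(as.data.frame(data))
  all_missing <- names(data)[colSums(!mask) == 0L]
  if (length(all_missing) > 0L) {
    stop("Column(s) entirely missing, cannot impute: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  incomplete <- names(data)[colSums(mask) > 0L]
  if (length(incomplete) == 0L) return(data)

  clamp_domain <- function(v, col) {
    if (!col %in% categorical_cols) return(v)
    dom <- uci_domains()[[col]]
    if (is.null(dom)) dom <- sort(unique(stats::na.omit(data[[col]])))
    pmin(pmax(round(v), min(dom)), max(dom))
  }

  work <- as.data.frame(data)
  # initialization: column mean; mode for categoricals
  for (col in incomplete) {
    obs <- work[[col]][!mask[, col]]
    fill <- if (col %in% categorical_cols) {
      as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
    } else {
      mean(obs)
    }
    work[[col]][mask[, col]] <- fill
  }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (col in incomplete) {
      others <- setdiff(names(work), col)
      fml <- stats::reformulate(others, response = col)
      fit <- stats::lm(fml, data = work[!mask[, col], , drop = FALSE])
      pred <- stats::predict(fit, newdata = work[mask[, col], , drop = FALSE])
      pred[!is.finite(pred)] <- mean(work[[col]][!mask[, col]])
      pred <- clamp_domain(pred, col)
      delta <- max(delta, max(abs(pred - work[[col]][mask[, col]])))
      work[[col]][mask[, col]] <- pred
    }
    if (delta < tol) break
  }
  tibble::as_tibble(work)
}

#' Robust (median/IQR) scaling
#'
#' Centers each selected column on its median and divides by its
#' interquartile range, so that after scaling the column median is exactly 0
#' and the IQR exactly 1. Against mean/SD standardization this keeps heavy
#' outliers from inflating the scale estimate. A zero-IQR (near-constant)
#' column is centered only, with a warning.
#'
#' The fitted centers and scales are returned as a `scaler` attribute so the
#' identical transform can be applied to fresh records
#' ([apply_scaler()]) or inverted ([invert_scaler()]).
#'
#' @param data Data frame with no missing values in the scaled columns.
#' @param cols Columns to scale; defaults to the schema's continuous
#'   attributes present in `data`.
#' @return The data with scaled columns, carrying a `scaler` attribute
#'   (tibble: `column`, `center`, `scale`).
#' @export
robust_scale <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) cols <- intersect(names(uci_ranges()), names(data))
  if (length(cols) == 0L) stop("No columns to scale.", call. = FALSE)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  state <- purrr::map_dfr(cols, function(cl) {
    v <- data[[cl]]
    if (anyNA(v)) stop("Column `", cl, "` has missing values; impute first.",
                       call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    if (iqr == 0) {
      warning("Column `", cl, "` has zero IQR: centered only.",
              call. = FALSE)
      iqr <- 1
    }
    tibble::tibble(column = cl, center = q[2], scale = iqr)
  })
  out <- apply_scaler(data, state)
  attr(out, "scaler") <- state
  out
}

#' @rdname robust_scale
#' @param state A scaler state tibble (`column`, `center`, `scale`) as
#'   produced by [robust_scale()] (also retrievable via
#'   `attr(scaled, "scaler")`).
#' @export
apply_scaler <- function(data, state) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(state))) {
    cl <- state$column[[i]]
    data[[cl]] <- (data[[cl]] - state$center[[i]]) / state$scale[[i]]
  }
  data
}

#' @rdname robust_scale
#' @export
invert_scaler <- function(data, state) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(state))) {
    cl <- state$column[[i]]
    data[[cl]] <- data[[cl]] * state$scale[[i]] + state$center[[i]]
  }
  data
}

#' Ordinal encoding of the categorical attributes
#'
#' Maps every categorical attribute onto consecutive codes `0 .. K-1` using
#' the fixed dictionary given by the schema's domain order (`cp` 1-4 becomes
#' 0-3, `slope` 1-3 becomes 0-2; already 0-based attributes are unchanged).
#' The mapping is recorded in an `encoder` attribute and is invertible with
#' [decode_categoricals()].
#'
#' @param data Data frame with categorical values inside their schema
#'   domains.
#' @param cols Columns to encode; defaults to the schema's categorical
#'   attributes present in `data` (excluding `num`).
#' @return The encoded data, carrying an `encoder` attribute.
#' @export
encode_categoricals <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) {
    cols <- intersect(setdiff(names(uci_domains()), "num"), names(data))
  }
  state <- purrr::map_dfr(cols, function(cl) {
    dom <- uci_domains()[[cl]]
    if (is.null(dom)) dom <- sort(unique(stats::na.omit(data[[cl]])))
    tibble::tibble(column = cl, from = list(dom),
                   to = list(seq_along(dom) - 1L))
  })
  for (i in seq_len(nrow(state))) {
    cl <- state$column[[i]]
    v <- data[[cl]]
    ok <- is.na(v) | v %in% state$from[[i]]
    if (!all(ok)) {
      stop(sprintf("Column `%s`: unseen categorical value(s) %s.", cl,
                   paste(unique(v[!ok]), collapse = ", ")), call. = FALSE)
    }
    data[[cl]] <- state$to[[i]][match(v, state$from[[i]])]
  }
  attr(data, "encoder") <- state
  data
}

#' @rdname encode_categoricals
#' @param state An encoder state as produced by [encode_categoricals()]
#'   (also retrievable via `attr(encoded, "encoder")`).
#' @export
decode_categoricals <- function(data, state) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(state))) {
    cl <- state$column[[i]]
    data[[cl]] <- state$from[[i]][match(data[[cl]], state$to[[i]])]
  }
  data
}

#' Random oversampling to balanced classes
#'
#' Duplicates minority-class records, drawn uniformly with replacement,
#' until every class matches the majority-class count. All original records
#' are retained; the majority class is untouched.
#'
#' @param data Labeled data frame.
#' @param label Name of the label column (default `"zone"`).
#' @param seed Seed for the duplication draw.
#' @return The oversampled tibble (original rows first, duplicates
#'   appended).
#' @export
oversample <- function(data, label = "zone", seed = NULL) {
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) {
    stop("Label column `", label, "` not found.", call. = FALSE)
  }
  y <- data[[label]]
  counts <- table(droplevels(factor(y)))
  if (length(counts) < 2L) {
    stop("Oversampling needs at least two classes.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  target <- max(counts)
  extra_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(y == cl)
    need <- target - length(idx)
    if (need <= 0L) return(integer(0))
    sample(idx, need, replace = TRUE)
  }))
  dplyr::bind_rows(data, data[extra_idx, , drop = FALSE])
}

#' 70/30 train/test split
#'
#' Partitions the table into a training part of `round(0.7 n)` records and a
#' test part with the remainder; no record appears in both. With
#' `stratified = TRUE` the draw is per class, preserving class proportions
#' to within one record per class.
#'
#' @param data Data frame to split.
#' @param seed Seed for the partition draw.
#' @param stratified Stratify by `label`?
#' @param label Label column used for stratification.
#' @param train_frac Training fraction (default 0.7).
#' @return A list with `train` and `test` tibbles.
#' @export
split_70_30 <- function(data, seed = NULL, stratified = FALSE,
                        label = "zone", train_frac = 0.7) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    if (!label %in% names(data)) {
      stop("Label column `", label, "` not found.", call. = FALSE)
    }
    classes <- unique(as.character(data[[label]]))
    if (n < length(classes)) {
      stop("Fewer records than classes; cannot stratify.", call. = FALSE)
    }
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(data[[label]] == cl)
      sample(idx, round(train_frac * length(idx)))
    }))
  } else {
    train_idx <- sample.int(n, round(train_frac * n))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE])
}

#' The full preprocessing recipe
#'
#' Chains the table preparation steps: zone labeling, chained-equation
#' imputation, robust scaling, ordinal encoding, oversampling and the 70/30
#' split. The default step order oversamples *before* splitting, mirroring
#' the source protocol; because duplicated minority records can then land in
#' both partitions, a leakage warning is emitted and `split_first = TRUE`
#' provides the leakage-free order (split, then oversample the training part
#' only).
#'
#' @param data A 12-attribute table with a `num` column (e.g. from
#'   [read_uci_csv()] or [simulate_cohort()]).
#' @param scheme Zone scheme, `"three"` or `"two"`.
#' @param seed Seed governing imputation, oversampling and the split.
#' @param split_first Use the leakage-free order (split before
#'   oversampling)?
#' @param stratified Stratify the split by zone?
#' @return A list with `train`, `test` (fully numeric tibbles with a `zone`
#'   factor column), `scaler`, `encoder` and a `steps` character vector
#'   recording the applied order.
#' @export
preprocess_recipe <- function(data, scheme = c("three", "two"), seed = 1,
                              split_first = FALSE, stratified = TRUE) {
  scheme <- match.arg(scheme)
  labeled <- add_zone_label(data, scheme)
  zone <- labeled$zone
  feats <- labeled[intersect(uci_used_columns(), names(labeled))]
  imputed <- mice_impute(feats, seed = seed)
  scaled <- robust_scale(imputed)
  scaler <- attr(scaled, "scaler")
  encoded <- encode_categoricals(scaled)
  encoder <- attr(encoded, "encoder")
  encoded$zone <- zone
  if (split_first) {
    parts <- split_70_30(encoded, seed = seed, stratified = stratified)
    train <- oversample(parts$train, seed = seed)
    test <- parts$test
    steps <- c("zone", "impute", "scale", "encode", "split", "oversample")
  } else {
    warning(paste("Oversampling before the split duplicates minority",
                  "records across partitions (information leakage);",
                  "use `split_first = TRUE` for the leakage-free order."),
            call. = FALSE)
    balanced <- oversample(encoded, seed = seed)
    parts <- split_70_30(balanced, seed = seed, stratified = stratified)
    train <- parts$train
    test <- parts$test
    steps <- c("zone", "impute", "scale", "encode", "oversample", "split")
  }
  list(train = train, test = test, scaler = scaler, encoder = encoder,
       steps = steps, scheme = scheme, seed = seed)
}
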