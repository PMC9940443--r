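#' ECG-derived feature summary
#'
#' One-call feature extraction for a raw single-channel recording: runs
#' R-peak detection, cuts the post-R ST windows, and reports the per-session
#' slope summary together with its ordinal `slope` category and the
#' detected beat count.
#'
#' @param raw An `ecg_signal` at stage `"raw"`.
#' @param coeffs Filter coefficient set (`"canonical"`/`"paper"`).
#' @param window_ms Integration window (ms) for peak detection.
#' @param offset_ms,length_ms ST window geometry (ms).
#' @param summary Beat aggregation, `"mean"` or `"median"`.
#' @param quiet Suppress the off-design-rate message.
#' @return A one-row tibble: `n_beats`, `hr_bpm` (median RR estimate),
#'   `st_slope` (a.u./sample), `slope_category` (1/2/3), plus a `per_beat`
#'   list-column of the per-beat slopes.
#' @export
ecg_features <- function(raw, coeffs = c("canonical", "paper"),
                         window_ms = 150, offset_ms = 57.14,
                         length_ms = 120, summary = c("mean", "median"),
                         quiet = FALSE) {
  coeffs <- match.arg(coeffs)
  summary <- match.arg(summary)
  peaks <- detect_r_peaks(raw, coeffs = coeffs, window_ms = window_ms,
                          quiet = quiet)
  segs <- extract_st_segments(raw, peaks, offset_ms = offset_ms,
                              length_ms = length_ms)
  sl <- st_slopes(segs, summary = summary)
  hr <- if (nrow(peaks) >= 2) {
    60 * ecg_fs(raw) / stats::median(diff(peaks$index))
  } else {
    NA_real_
  }
  tibble::tibble(
    n_beats = nrow(peaks),
    hr_bpm = hr,
    st_slope = sl$summary,
    slope_category = if (is.na(sl$summary)) NA_integer_ else
      slope_to_category(sl$summary),
    per_beat = list(sl$per_beat))
}

#' Run the end-to-end risk-zoning pipeline
#'
#' Binds the stages — cohort input (synthetic or a UCI-dialect CSV),
#' preprocessing recipe, stacking ensemble, held-out evaluation — and
#' returns the fitted model with its metric report, ROC-AUC table and a
#' fully serializable run manifest echoing every effective parameter.
#'
#' @param config Named list. Recognized entries (with defaults):
#'   `scheme` ("three"), `seed` (1), `input` (path to a UCI CSV; when `NULL`
#'   a cohort is simulated), `n` (920), `effect_size` (1), `missing_rate`
#'   (0), `split_first` (FALSE), `base_learners` (scheme default),
#'   `n_folds` (5), `out_dir` (when set, writes `manifest.json` and
#'   `metrics.csv` there).
#' @return A list: `model` (`stacking_model`), `report` (`metric_report`),
#'   `auc` (tibble), `prep` (recipe output), `manifest` (list).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    scheme = "three", seed = 1, input = NULL, n = 920, effect_size = 1,
    missing_rate = 0, split_first = FALSE, base_learners = NULL,
    n_folds = 5, out_dir = NULL), config)

  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("Input file not found: ", cfg$input, call. = FALSE)
  }
  data <- if (is.null(cfg$input)) {
    simulate_cohort(n = cfg$n, effect_size = cfg$effect_size,
                    missing_rate = cfg$missing_rate, scheme = cfg$scheme,
                    seed = cfg$seed,
                    class_proportions = if (cfg$scheme == "three") {
                      c(413, 258, 249) / 920
                    } else {
                      c(413, 507) / 920
                    })
  } else {
    read_uci_csv(cfg$input)
  }

  prep <- preprocess_recipe(data, scheme = cfg$scheme, seed = cfg$seed,
                            split_first = cfg$split_first)
  spec <- stacking_spec(base_learners = cfg$base_learners,
                        scheme = cfg$scheme, n_folds = cfg$n_folds)
  model <- build_stacking(prep$train, spec, seed = cfg$seed)
  probs <- predict(model, prep$test, type = "prob")
  pred <- predict(model, prep$test, type = "zone")
  report <- evaluate_classifier(pred, prep$test$zone,
                                levels = model$levels)
  auc <- roc_auc_report(probs, prep$test$zone)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cardiorisk")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    steps = prep$steps,
    base_learners = spec$base_learners,
    n_train = nrow(prep$train), n_test = nrow(prep$test),
    metrics = as.list(glance(report)),
    auc = stats::setNames(as.list(auc$auc), auc$class))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    readr::write_csv(tidy(report), file.path(cfg$out_dir, "metrics.csv"))
  }
  list(model = model, report = report, auc = auc, prep = prep,
       manifest = manifest)
}
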