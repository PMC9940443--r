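#' The 14-attribute heart-disease schema
#'
#' Column order, domains and ranges of the processed UCI heart-disease
#' dialect. Twelve attributes are used for modelling; `ca` (fluoroscopy
#' vessel count) and `thal` (thallium stress test) require in-hospital tests
#' and are dropped on read. `num` is the disease-severity target (0-4).
#'
#' @return `uci_columns()`: the 14 column names in file order.
#'   `uci_used_columns()`: the 12 modelling attributes.
#'   `uci_domains()`: named list of admissible values for the categorical
#'   attributes. `uci_ranges()`: named list of `c(min, max)` for the
#'   continuous attributes.
#' @export
uci_columns <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
    "thalach", "exang", "oldpeak", "slope", "ca", "thal", "num")
}

#' @rdname uci_columns
#' @export
uci_used_columns <- function() {
  setdiff(uci_columns(), c("ca", "thal", "num"))
}

#' @rdname uci_columns
#' @export
uci_domains <- function() {
  list(sex = 0:1, cp = 1:4, fbs = 0:1, restecg = 0:2,
       exang = 0:1, slope = 1:3, num = 0:4)
}

#' @rdname uci_columns
#' @export
uci_ranges <- function() {
  list(age = c(29, 77), trestbps = c(94, 200), chol = c(126, 564),
       thalach = c(71, 202), oldpeak = c(0, 6.2))
}

#' Read a heart-disease table in the UCI CSV dialect
#'
#' Comma-separated, `"?"` marks a missing value, 14 columns in the standard
#' order (an optional header row is detected by sniffing). `ca` and `thal`
#' are dropped; `num` is kept when present. Values outside the documented
#' attribute ranges produce a warning (`range_check = "warn"`, the default)
#' rather than a failure, since public copies of the source files contain
#' boundary oddities.
#'
#' @param path CSV path.
#' @param range_check `"warn"` (default), `"error"`, or `"none"`.
#' @return A tibble with the 12 modelling columns plus `num` if present;
#'   missing entries are `NA`.
#' @export
read_uci_csv <- function(path, range_check = c("warn", "error", "none")) {
  range_check <- match.arg(range_check)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("Empty file: returning a 0-row table.", call. = FALSE)
    cols <- c(uci_used_columns(), "num")
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  header <- grepl("age", lines[[1]], fixed = TRUE)
  body <- if (header) lines[-1] else lines
  fields <- strsplit(body, ",")
  nf <- lengths(fields)
  if (any(nf != 14L)) {
    bad <- which(nf != 14L)[[1]]
    stop(sprintf("Line %d: expected 14 comma-separated fields, found %d.",
                 bad + as.integer(header), nf[[bad]]), call. = FALSE)
  }
  parse_col <- function(j) {
    v <- trimws(vapply(fields, `[[`, character(1), j))
    v[v == "?"] <- NA_character_
    suppressWarnings(as.numeric(v))
  }
  cols <- lapply(seq_len(14L), parse_col)
  names(cols) <- uci_columns()
  out <- tibble::as_tibble(cols)[c(uci_used_columns(), "num")]
  if (range_check != "none") {
    msgs <- character(0)
    for (nm in names(uci_ranges())) {
      r <- uci_ranges()[[nm]]
      n_out <- sum(out[[nm]] < r[1] | out[[nm]] > r[2], na.rm = TRUE)
      if (n_out > 0) msgs <- c(msgs, sprintf("%s: %d value(s) outside [%g, %g]",
                                             nm, n_out, r[1], r[2]))
    }
    if (length(msgs) > 0L) {
      txt <- paste("Out-of-range values:", paste(msgs, collapse = "; "))
      if (range_check == "warn") warning(txt, call. = FALSE) else
        stop(txt, call. = FALSE)
    }
  }
  message(sprintf("Read %d record(s), %d column(s) (ca/thal dropped).",
                  nrow(out), ncol(out)))
  out
}

#' Map disease severity to a risk zone
#'
#' The `num` target codes angiographic disease severity 0-4. Under the
#' three-level scheme, 0 maps to the green (low-risk) zone, 1 to yellow
#' (moderate), and 2-4 to red (high); under the two-level scheme 0 is green
#' and 1-4 red.
#'
#' @param num Integer vector with values in 0-4.
#' @param scheme `"three"` (green/yellow/red) or `"two"` (green/red).
#' @return Factor with levels `green, yellow, red` (three) or `green, red`
#'   (two).
#' @examples
#' map_num_to_zone(0:4, "three")
#' map_num_to_zone(0:4, "two")
#' @export
map_num_to_zone <- function(num, scheme = c("three", "two")) {
  scheme <- match.arg(scheme)
  num <- as.integer(num)
  if (anyNA(num) || !all(num %in% 0:4)) {
    stop("`num` values must be integers in {0, ..., 4}.", call. = FALSE)
  }
  if (scheme == "three") {
    factor(ifelse(num == 0L, "green", ifelse(num == 1L, "yellow", "red")),
           levels = c("green", "yellow", "red"))
  } else {
    factor(ifelse(num == 0L, "green", "red"), levels = c("green", "red"))
  }
}

#' Attach a `zone` label column
#'
#' Convenience wrapper applying [map_num_to_zone()] to the `num` column and
#' appending the result as `zone`.
#'
#' @param data Data frame with a `num` column.
#' @param scheme Zone scheme passed to [map_num_to_zone()].
#' @return The input with a `zone` factor column appended.
#' @export
add_zone_label <- function(data, scheme = c("three", "two")) {
  if (!"num" %in% names(data)) {
    stop("`data` must contain a `num` column.", call. = FALSE)
  }
  dplyr::mutate(data, zone = map_num_to_zone(.data$num, scheme))
}
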