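#' Read interval ground-truth annotations
#'
#' CSV with columns start_s, end_s, label. Intervals must be ordered and
#' non-overlapping; offenders are listed in the error.
#'
#' @param path CSV path
#' @return data.frame(start_s, end_s, label)
#' @export
read_interval_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop_input(path, ": interval CSV needs columns ", paste(need, collapse = ", "))
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (any(df$end_s <= df$start_s))
    stop_input("intervals with end <= start at rows: ",
               paste(which(df$end_s <= df$start_s), collapse = ", "))
  if (nrow(df) > 1) {
    bad <- which(df$start_s[-1] < df$end_s[-nrow(df)]) + 1L
    if (length(bad))
      stop_input("overlapping or out-of-order intervals at rows: ",
                 paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Write interval annotations
#' @param df data.frame(start_s, end_s, label)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_interval_labels <- function(df, path) {
  validate_intervals(df)
  utils::write.csv(df[c("start_s", "end_s", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Convert interval labels to the fixed window grid
#'
#' Each window takes the label of the interval covering most of it; ties go
#' to the earlier interval. The trailing partial window (when the annotated
#' span is not a multiple of the window) is kept iff at least half a window
#' is covered, mirroring the classifiers' windowing.
#'
#' @param intervals data.frame(start_s, end_s, label), ordered,
#'   non-overlapping
#' @param window_seconds window duration (default 0.5)
#' @return an [interaction_timeline()]
#' @export
intervals_to_windows <- function(intervals, window_seconds = 0.5) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) stop_input("no intervals")
  t0 <- intervals$start_s[1]
  total <- max(intervals$end_s) - t0
  n_full <- floor(total / window_seconds)
  n <- n_full + as.integer(total - n_full * window_seconds >= window_seconds / 2)
  if (n == 0) stop_input("annotated span shorter than half a window")
  lab <- character(n)
  for (w in seq_len(n)) {
    ws <- t0 + (w - 1) * window_seconds
    we <- ws + window_seconds
    ov <- pmin(intervals$end_s, we) - pmax(intervals$start_s, ws)
    ov[ov < 0] <- 0
    lab[w] <- intervals$label[which.max(ov)]  # which.max: first (earlier) on tie
  }
  interaction_timeline(lab, window_seconds, t0)
}

#' Write a windowed label series or timeline to CSV
#'
#' Columns: window_index, start_s, end_s, label.
#'
#' @param x a [label_series()] or [interaction_timeline()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_windowed_labels <- function(x, path) {
  utils::write.csv(as_window_df(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a windowed label CSV
#'
#' Binary 0/1 files load as a [label_series()] (`kind` as given); four-class
#' files load as an [interaction_timeline()].
#'
#' @param path CSV path written by [write_windowed_labels()]
#' @param kind kind for binary series (default "gaze")
#' @return a [label_series()] or [interaction_timeline()]
#' @export
read_windowed_labels <- function(path, kind = "gaze") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_index", "start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop_input(path, ": windowed CSV needs columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop_input(path, ": empty windowed CSV")
  w <- df$end_s[1] - df$start_s[1]
  if (all(df$label %in% c(0, 1, "0", "1")))
    label_series(as.integer(df$label), w, kind, df$start_s[1])
  else
    interaction_timeline(df$label, w, df$start_s[1])
}

#' Write an evaluation report
#'
#' JSON carries the full report; CSV mirrors the per-class performance table
#' with the support column and a trailing support-weighted row.
#'
#' @param report a [classification_report()]
#' @param path output path
#' @param format "json" or "csv"
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "classification_report"))
  if (format == "json") {
    jsonlite::write_json(list(
      per_class = report$per_class,
      accuracy = report$accuracy,
      weighted = report$weighted
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- report$per_class
    df$precision <- round_half_away(df$precision, 2)
    df$recall <- round_half_away(df$recall, 2)
    df$f1 <- round_half_away(df$f1, 2)
    wrow <- data.frame(class = "Weighted score",
                       precision = round_half_away(report$weighted$precision, 2),
                       recall = round_half_away(report$weighted$recall, 2),
                       f1 = round_half_away(report$weighted$f1, 2),
                       support = sum(df$support))
    utils::write.csv(rbind(df, wrow), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
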