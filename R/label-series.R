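#' Windowed binary label series
#'
#' Container for 0/1 labels on a fixed window grid, the common currency of the
#' gaze and dialogue classifiers. Windows are half-open intervals
#' `[start_time + i*w, start_time + (i+1)*w)`.
#'
#' @param labels integer vector of 0/1 window labels
#' @param window_seconds window duration in seconds (default 0.5)
#' @param kind "gaze" or "voice"
#' @param start_time stream start in seconds
#' @return an object of class `label_series`
#' @export
label_series <- function(labels, window_seconds = 0.5, kind = c("gaze", "voice"),
                         start_time = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stop_input("window_seconds must be > 0")
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop_input("labels must be 0/1")
  structure(
    list(labels = labels, window_seconds = window_seconds,
         kind = kind, start_time = start_time),
    class = "label_series"
  )
}

#' @export
length.label_series <- function(x) length(x$labels)

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series kind=%s windows=%d window=%.3gs start=%.3gs>\n",
              x$kind, length(x$labels), x$window_seconds, x$start_time))
  invisible(x)
}

#' Majority-vote aggregation of per-frame labels onto the window grid
#'
#' Each full window receives the most frequent label among its frames. Ties
#' resolve to the previous window's (already resolved) label, and to 0 for the
#' first window. A trailing partial window is kept iff it holds at least half
#' a window's worth of frames, otherwise it is dropped.
#'
#' @param per_frame_labels 0/1 vector, one entry per frame (or per audio
#'   segment; `fps` is then segments per second)
#' @param fps frames per second
#' @param window_seconds window duration in seconds
#' @param kind label kind passed through to the result
#' @param start_time stream start in seconds
#' @return a [label_series()]
#' @export
aggregate_frame_labels <- function(per_frame_labels, fps, window_seconds = 0.5,
                                   kind = "gaze", start_time = 0) {
  if (length(per_frame_labels) == 0L) stop_input("empty frame sequence")
  if (!is_scalar_num(fps) || fps <= 0) stop_input("fps must be > 0")
  if (!is_scalar_num(window_seconds) || window_seconds <= 0)
    stop_input("window_seconds must be > 0")
  fpw <- fps * window_seconds
  if (fpw < 1) stop_input("fps * window_seconds must be >= 1")
  x <- as.integer(per_frame_labels)
  n <- length(x)
  win <- floor((seq_len(n) - 1L) / fpw)   # 0-based window index per frame
  n_full <- floor(n / fpw)
  last <- max(win)
  keep_partial <- FALSE
  if (last >= n_full) {                    # trailing partial window exists
    keep_partial <- sum(win == last) >= fpw / 2
    if (!keep_partial) {
      x <- x[win < n_full]
      win <- win[win < n_full]
    }
  }
  if (length(x) == 0L) stop_input("no complete window in frame sequence")
  ones <- tapply(x, win, sum)
  tot <- tapply(x, win, length)
  out <- integer(length(ones))
  prev <- 0L
  for (i in seq_along(ones)) {
    if (2 * ones[[i]] > tot[[i]]) prev <- 1L
    else if (2 * ones[[i]] < tot[[i]]) prev <- 0L
    # tie: keep prev
    out[i] <- prev
  }
  label_series(out, window_seconds, kind, start_time)
}

#' Convert a label series to a windowed data frame
#'
#' @param x a [label_series()] or [interaction_timeline()]
#' @return data.frame with window_index, start_s, end_s, label
#' @export
as_window_df <- function(x) {
  n <- length(x$labels)
  data.frame(
    window_index = seq_len(n) - 1L,
    start_s = x$start_time + (seq_len(n) - 1L) * x$window_seconds,
    end_s = x$start_time + seq_len(n) * x$window_seconds,
    label = x$labels,
    stringsAsFactors = FALSE
  )
}
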