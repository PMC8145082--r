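#' Find class transitions in a timeline
#'
#' A transition is a window index at which the label changes. Each record
#' carries the 1-based `boundary_index` (first window of the new class), the
#' classes on each side and the flanking run lengths in windows.
#'
#' @param timeline an [interaction_timeline()]
#' @return list with `records` (data.frame: boundary_index, from_class,
#'   to_class, pre_run, post_run) and `freq` (from x to count matrix)
#' @export
find_transitions <- function(timeline) {
  stopifnot(inherits(timeline, "interaction_timeline"))
  lab <- timeline$labels
  if (length(lab) == 0) stop_input("empty timeline")
  r <- rle(lab)
  k <- length(r$lengths)
  freq <- matrix(0L, 4, 4, dimnames = list(from = INTERACTION_CLASSES,
                                           to = INTERACTION_CLASSES))
  if (k == 1) {
    records <- data.frame(boundary_index = integer(0), from_class = character(0),
                          to_class = character(0), pre_run = integer(0),
                          post_run = integer(0), stringsAsFactors = FALSE)
    return(list(records = records, freq = freq))
  }
  ends <- cumsum(r$lengths)
  records <- data.frame(
    boundary_index = ends[-k] + 1L,
    from_class = r$values[-k],
    to_class = r$values[-1],
    pre_run = r$lengths[-k],
    post_run = r$lengths[-1],
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(records)))
    freq[records$from_class[i], records$to_class[i]] <-
      freq[records$from_class[i], records$to_class[i]] + 1L
  list(records = records, freq = freq)
}

#' Keep transitions flanked by sufficiently long continuous runs
#'
#' Only transitions preceded and followed by a single continuous class for at
#' least `min_run_seconds` (1.5 s, i.e. 3 windows at the 0.5-s default)
#' qualify for timing-error analysis; the boundary is inclusive ("at least").
#'
#' @param records transition records from [find_transitions()]
#' @param window_seconds window duration of the source timeline
#' @param min_run_seconds minimum flanking run (default 1.5)
#' @return the qualifying subset of `records`
#' @export
qualifying_transitions <- function(records, window_seconds = 0.5,
                                   min_run_seconds = 1.5) {
  k <- min_run_seconds / window_seconds
  if (abs(k - round(k)) > 1e-9)
    stop_input("min_run_seconds must be a multiple of window_seconds")
  k <- round(k)
  records[records$pre_run >= k & records$post_run >= k, , drop = FALSE]
}

#' Attribute classification errors to transition timing shifts
#'
#' A misclassified window is transition-attributable iff it lies within
#' `radius` windows (default 2, i.e. a 0.5-1 s shift) of a qualifying
#' ground-truth transition boundary AND its predicted label equals the truth
#' on the other side of that boundary: windows before the boundary predicted
#' as the post-class mark the transition early; windows at or after the
#' boundary predicted as the pre-class mark it late. Such errors are early or
#' late markings of a real transition rather than substantive mistakes.
#'
#' @param truth,pred [interaction_timeline()] objects on the same grid
#' @param min_run_seconds flanking-run filter passed to
#'   [qualifying_transitions()]
#' @param radius attribution radius in windows (default 2)
#' @return list with `total_errors`, `transition_errors`, `percentage`
#'   (1 decimal), and the logical `attributable` mask over windows
#' @export
transition_error_analysis <- function(truth, pred, min_run_seconds = 1.5,
                                      radius = 2L) {
  stopifnot(inherits(truth, "interaction_timeline"),
            inherits(pred, "interaction_timeline"))
  if (length(truth$labels) != length(pred$labels))
    stop_input("truth and prediction lengths differ")
  n <- length(truth$labels)
  err <- which(pred$labels != truth$labels)
  rec <- qualifying_transitions(find_transitions(truth)$records,
                                truth$window_seconds, min_run_seconds)
  attributable <- logical(n)
  for (w in err) {
    for (j in seq_len(nrow(rec))) {
      b <- rec$boundary_index[j]
      if (abs(w - b) > radius) next
      side_label <- if (w < b) rec$to_class[j] else rec$from_class[j]
      if (pred$labels[w] == side_label) { attributable[w] <- TRUE; break }
    }
  }
  total <- length(err)
  trans <- sum(attributable)
  list(total_errors = total, transition_errors = trans,
       percentage = percentage(trans, total), attributable = attributable)
}
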