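#' Four-class interaction timeline
#'
#' 0.5-second windows labelled with one of the four doctor-patient-computer
#' interaction classes: `SG+D` (screen gaze + dialogue), `D` (dialogue away
#' from the screen), `SG` (screen gaze without dialogue), `Other` (neither).
#'
#' @param labels character vector over the four class labels
#' @param window_seconds window duration (default 0.5)
#' @param start_time timeline start in seconds
#' @return an `interaction_timeline`
#' @export
interaction_timeline <- function(labels, window_seconds = 0.5, start_time = 0) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), INTERACTION_CLASSES)
  if (length(bad)) stop_input("unknown interaction labels: ",
                              paste(bad, collapse = ", "))
  structure(list(labels = labels, window_seconds = window_seconds,
                 start_time = start_time),
            class = "interaction_timeline")
}

#' @export
length.interaction_timeline <- function(x) length(x$labels)

#' @export
print.interaction_timeline <- function(x, ...) {
  cat(sprintf("<interaction_timeline windows=%d window=%.3gs>\n",
              length(x$labels), x$window_seconds))
  print(table(factor(x$labels, INTERACTION_CLASSES)))
  invisible(x)
}

#' Fuse gaze and voice series into the four-class timeline
#'
#' Per window: gaze & voice -> SG+D; voice only -> D; gaze only -> SG;
#' neither -> Other. The two series must share the same window grid; on
#' unequal lengths the result is truncated to the shorter series with a
#' warning recording the dropped count (video and audio tails often differ).
#'
#' @param gaze a [label_series()] of kind "gaze"
#' @param voice a [label_series()] of kind "voice"
#' @return an [interaction_timeline()]
#' @export
fuse_streams <- function(gaze, voice) {
  stopifnot(inherits(gaze, "label_series"), inherits(voice, "label_series"))
  if (!isTRUE(all.equal(gaze$window_seconds, voice$window_seconds)) ||
      !isTRUE(all.equal(gaze$start_time, voice$start_time)))
    stop_input("gaze and voice series are not on the same window grid ",
               "(window_seconds/start_time differ); resample explicitly")
  n <- min(length(gaze$labels), length(voice$labels))
  dropped <- max(length(gaze$labels), length(voice$labels)) - n
  if (dropped > 0)
    warning("fuse_streams: series lengths differ; dropped ", dropped,
            " trailing window(s) from the longer series", call. = FALSE)
  g <- gaze$labels[seq_len(n)]
  v <- voice$labels[seq_len(n)]
  lab <- ifelse(g == 1L & v == 1L, "SG+D",
         ifelse(g == 0L & v == 1L, "D",
         ifelse(g == 1L & v == 0L, "SG", "Other")))
  interaction_timeline(lab, gaze$window_seconds, gaze$start_time)
}

#' Recover the (gaze, voice) pair from timeline labels
#'
#' Inverse of the fusion map, exact per window.
#'
#' @param timeline an [interaction_timeline()]
#' @return list with `gaze` and `voice` [label_series()]
#' @export
unfuse_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "interaction_timeline"))
  g <- as.integer(timeline$labels %in% c("SG+D", "SG"))
  v <- as.integer(timeline$labels %in% c("SG+D", "D"))
  list(gaze = label_series(g, timeline$window_seconds, "gaze", timeline$start_time),
       voice = label_series(v, timeline$window_seconds, "voice", timeline$start_time))
}
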