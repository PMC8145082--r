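KEYPOINTS <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear")

kp_cols <- function() {
  as.vector(t(outer(KEYPOINTS, c("x", "y", "c"), paste, sep = "_")))
}

#' Face-keypoint stream
#'
#' A data frame with one row per video frame holding the five facial keypoints
#' the gaze rule consumes: nose, left/right eye, left/right ear, each as
#' `<name>_x`, `<name>_y` (pixels) and `<name>_c` (detection confidence in
#' [0,1]; confidence at or below the presence threshold means "not
#' estimated"). Also carries `timestamp` (seconds, strictly increasing per
#' person) and `person_id`.
#'
#' @param df data.frame with the columns described above
#' @return the validated data frame with class `keypoint_stream`
#' @export
keypoint_stream <- function(df) {
  need <- c("timestamp", "person_id", kp_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("keypoint stream missing columns: ",
                               paste(miss, collapse = ", "))
  cc <- paste0(KEYPOINTS, "_c")
  cv <- as.matrix(df[cc])
  if (any(!is.finite(cv)) || any(cv < 0) || any(cv > 1))
    stop_input("keypoint confidences must be finite and in [0,1]")
  # non-finite coordinates are only tolerated on absent (zero-confidence) keypoints
  xbad <- !is.finite(as.matrix(df[paste0(KEYPOINTS, "_x")])) & cv > 0
  ybad <- !is.finite(as.matrix(df[paste0(KEYPOINTS, "_y")])) & cv > 0
  if (any(xbad) || any(ybad)) {
    row <- which(rowSums(xbad) + rowSums(ybad) > 0)[1]
    stop_input("non-finite keypoint coordinate at frame row ", row)
  }
  for (p in split(seq_len(nrow(df)), df$person_id)) {
    ts <- df$timestamp[p]
    if (length(ts) > 1 && any(diff(ts) <= 0))
      stop_input("timestamps must strictly increase within a person's stream")
  }
  class(df) <- c("keypoint_stream", "data.frame")
  df
}

#' Gaze-rule configuration
#'
#' The screen-gaze rule declares a frame "screen gaze" iff (1) both ears are
#' estimated, (2) both eyes and the nose are estimated, and (3) the nose is
#' centered between the eyes within a tolerance of `tolerance_factor` times
#' the inter-eye distance (default one half). The default axis convention is
#' horizontal: offsets and distances are measured on x only, since head yaw is
#' the motion of interest; `axis = "euclidean"` uses planar distances instead.
#'
#' @param presence_threshold keypoint present iff confidence strictly exceeds
#'   this (default 0, i.e. any positive confidence)
#' @param tolerance_factor fraction of the inter-eye distance allowed between
#'   nose and eye midpoint (default 0.5)
#' @param axis "horizontal" or "euclidean"
#' @return a `gaze_config` list
#' @export
gaze_config <- function(presence_threshold = 0, tolerance_factor = 0.5,
                        axis = c("horizontal", "euclidean")) {
  axis <- match.arg(axis)
  if (!is_scalar_num(presence_threshold) || presence_threshold < 0 ||
      presence_threshold >= 1)
    stop_config("presence_threshold must be in [0, 1)")
  if (!is_scalar_num(tolerance_factor) || tolerance_factor <= 0)
    stop_config("tolerance_factor must be > 0")
  structure(list(presence_threshold = presence_threshold,
                 tolerance_factor = tolerance_factor, axis = axis),
            class = "gaze_config")
}

#' Classify frames as screen gaze / no screen gaze
#'
#' Vectorized over the rows of the stream; boundary equality (nose offset
#' exactly equal to the tolerance) counts as screen gaze.
#'
#' @param frames a [keypoint_stream()] (one or more rows)
#' @param cfg a [gaze_config()]
#' @return integer vector, 1 = screen gaze, 0 = no screen gaze
#' @export
classify_frame_gaze <- function(frames, cfg = gaze_config()) {
  if (!inherits(frames, "keypoint_stream")) frames <- keypoint_stream(frames)
  thr <- cfg$presence_threshold
  present <- function(k) frames[[paste0(k, "_c")]] > thr
  ok <- present("left_ear") & present("right_ear") &
    present("left_eye") & present("right_eye") & present("nose")
  mid_x <- (frames$left_eye_x + frames$right_eye_x) / 2
  if (cfg$axis == "horizontal") {
    offset <- abs(frames$nose_x - mid_x)
    eye_d <- abs(frames$left_eye_x - frames$right_eye_x)
  } else {
    mid_y <- (frames$left_eye_y + frames$right_eye_y) / 2
    offset <- sqrt((frames$nose_x - mid_x)^2 + (frames$nose_y - mid_y)^2)
    eye_d <- sqrt((frames$left_eye_x - frames$right_eye_x)^2 +
                    (frames$left_eye_y - frames$right_eye_y)^2)
  }
  centered <- offset <= cfg$tolerance_factor * eye_d
  centered[is.na(centered)] <- FALSE
  as.integer(ok & centered)
}

#' Select the primary (closest-to-camera) person in a multi-person stream
#'
#' Clinic recordings assume the doctor faces the camera; among detected
#' persons the one with the largest mean inter-eye pixel distance (over frames
#' where both eyes are estimated) is taken as the doctor. Ties break to the
#' lower person id.
#'
#' @param frames a [keypoint_stream()] possibly containing several person_ids
#' @param presence_threshold confidence threshold for "eye estimated"
#' @return the selected person_id
#' @export
select_primary_person <- function(frames, presence_threshold = 0) {
  if (!inherits(frames, "keypoint_stream")) frames <- keypoint_stream(frames)
  ok <- frames$left_eye_c > presence_threshold &
    frames$right_eye_c > presence_threshold
  if (!any(ok)) stop_input("no classifiable person")
  d <- abs(frames$left_eye_x - frames$right_eye_x)
  means <- tapply(d[ok], frames$person_id[ok], mean)
  ids <- as.numeric(names(means))
  best <- which(means == max(means))
  ids[best][which.min(ids[best])]
}

#' Classify a keypoint stream into 0.5-second gaze windows
#'
#' Applies the per-frame gaze rule, then majority-votes frames onto the window
#' grid. Frames at which the selected person is undetected (all confidences
#' zero, or the frame is missing from the stream on a regular fps grid) count
#' as no screen gaze, keeping the grid aligned with the audio stream.
#'
#' @param frames a [keypoint_stream()] for a single person (see
#'   [select_primary_person()])
#' @param cfg a [gaze_config()]
#' @param fps video frame rate
#' @param window_seconds window duration (default 0.5)
#' @return a [label_series()] of kind "gaze"
#' @export
classify_gaze_stream <- function(frames, cfg = gaze_config(), fps,
                                 window_seconds = 0.5) {
  if (!inherits(frames, "keypoint_stream")) frames <- keypoint_stream(frames)
  if (length(unique(frames$person_id)) > 1)
    stop_input("stream contains several persons; run select_primary_person first")
  lab <- classify_frame_gaze(frames, cfg)
  aggregate_frame_labels(lab, fps = fps, window_seconds = window_seconds,
                         kind = "gaze",
                         start_time = 0)
}
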