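#' Default body-keypoint index map
#'
#' Indices of the five facial keypoints inside the 25-point body model's
#' `pose_keypoints_2d` array (x, y, confidence triples): nose 0, right eye 15,
#' left eye 16, right ear 17, left ear 18. Pose backends differ, so the map
#' is configuration, not code.
#'
#' @return named integer vector of 0-based keypoint indices
#' @export
default_index_map <- function() {
  c(nose = 0L, right_eye = 15L, left_eye = 16L, right_ear = 17L, left_ear = 18L)
}

frame_from_people <- function(people, frame_index, fps, index_map) {
  rows <- list()
  if (length(people) == 0) {
    r <- as.list(rep(0, length(kp_cols())))
    names(r) <- kp_cols()
    rows[[1]] <- c(list(timestamp = frame_index / fps, person_id = 0L), r)
  } else {
    for (p in seq_along(people)) {
      kp <- people[[p]]$pose_keypoints_2d
      if (is.null(kp)) stop_input("person record without pose_keypoints_2d")
      kp <- as.numeric(unlist(kp))
      r <- list(timestamp = frame_index / fps, person_id = p - 1L)
      for (nm in names(index_map)) {
        i <- index_map[[nm]] * 3L
        if (i + 3 > length(kp))
          stop_input("keypoint index ", index_map[[nm]],
                     " out of range for ", length(kp) / 3, "-point record")
        r[[paste0(nm, "_x")]] <- kp[i + 1]
        r[[paste0(nm, "_y")]] <- kp[i + 2]
        r[[paste0(nm, "_c")]] <- kp[i + 3]
      }
      rows[[p]] <- r
    }
  }
  rows
}

#' Read a pose-estimator keypoint stream
#'
#' Accepts either a directory of per-frame JSON files (each with a `people`
#' array of `pose_keypoints_2d` triples, ordered by filename) or a single
#' JSON-lines file with one frame object per line. Frames with an empty
#' people list become all-zero-confidence frames so the window grid stays
#' intact.
#'
#' @param path directory of `*.json` files or a `.jsonl` file
#' @param fps frame rate used to assign timestamps (default 30)
#' @param index_map keypoint index map, see [default_index_map()]
#' @return a [keypoint_stream()] (possibly multi-person)
#' @export
read_keypoint_stream <- function(path, fps = 30, index_map = default_index_map()) {
  need <- c("nose", "right_eye", "left_eye", "right_ear", "left_ear")
  if (!all(need %in% names(index_map)))
    stop_config("index_map must name: ", paste(need, collapse = ", "))
  rows <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(files)) stop_input(path, ": no .json frame files")
    for (i in seq_along(files)) {
      obj <- tryCatch(jsonlite::read_json(files[i]),
                      error = function(e) stop_input(files[i], ": malformed JSON (",
                                                     conditionMessage(e), ")"))
      rows <- c(rows, frame_from_people(obj$people, i - 1L, fps, index_map))
    }
  } else {
    if (!file.exists(path)) stop_input(path, ": no such file or directory")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop_input(path, ": empty keypoint file")
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) stop_input(path, " line ", i,
                                                     ": malformed JSON"))
      fi <- if (!is.null(obj$frame_index)) obj$frame_index else i - 1L
      rows <- c(rows, frame_from_people(obj$people, fi, fps, index_map))
    }
  }
  keypoint_stream(do.call(rbind, lapply(rows, as.data.frame)))
}

#' Write a keypoint stream as JSON lines
#'
#' One frame object per line in the same dialect [read_keypoint_stream()]
#' consumes (a `people` array of 25-point `pose_keypoints_2d` triples with
#' the five facial slots filled).
#'
#' @param stream a [keypoint_stream()]
#' @param path output `.jsonl` path
#' @param fps frame rate converting timestamps back to frame indices
#' @param index_map keypoint index map
#' @return `path`, invisibly
#' @export
write_keypoint_stream <- function(stream, path, fps = 30,
                                  index_map = default_index_map()) {
  con <- file(path, "w")
  on.exit(close(con))
  frames <- split(seq_len(nrow(stream)), round(stream$timestamp * fps))
  for (fi in names(frames)) {
    people <- lapply(frames[[fi]], function(r) {
      kp <- rep(0, 25 * 3)
      for (nm in names(index_map)) {
        i <- index_map[[nm]] * 3L
        kp[i + 1] <- stream[[paste0(nm, "_x")]][r]
        kp[i + 2] <- stream[[paste0(nm, "_y")]][r]
        kp[i + 3] <- stream[[paste0(nm, "_c")]][r]
      }
      list(pose_keypoints_2d = kp)
    })
    writeLines(jsonlite::toJSON(list(frame_index = as.integer(fi),
                                     people = people),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
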