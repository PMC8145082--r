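#' Voice-activity-detection configuration
#'
#' Audio is cut into short equal segments (default 5 ms) and each segment gets
#' a binary voice decision. The self-contained reference backend compares the
#' segment level in dBFS against an adaptive noise floor plus an activation
#' margin; `aggressiveness` (0-3, default 3 = strictest non-speech filtering)
#' maps onto that margin as 0 -> 3 dB, 1 -> 6 dB, 2 -> 9 dB, 3 -> 12 dB. An
#' explicit `delta_db` overrides the mapping. An `external` backend slot is
#' provided for plugging in an engine-backed per-segment classifier.
#'
#' @param segment_ms segment length in milliseconds (default 5)
#' @param aggressiveness integer 0-3 (default 3)
#' @param delta_db activation margin in dB above the noise floor, or NULL to
#'   derive it from `aggressiveness`
#' @param noise_floor_percentile percentile of per-segment RMS levels used as
#'   the noise floor (default 10)
#' @param backend "reference" or a function(segments_matrix, sample_rate)
#'   returning one 0/1 decision per segment
#' @return a `vad_config`
#' @export
vad_config <- function(segment_ms = 5, aggressiveness = 3, delta_db = NULL,
                       noise_floor_percentile = 10, backend = "reference") {
  if (!is_scalar_num(segment_ms) || segment_ms <= 0)
    stop_config("segment_ms must be > 0")
  if (!aggressiveness %in% 0:3) stop_config("aggressiveness must be in 0..3")
  if (is.null(delta_db)) delta_db <- c(3, 6, 9, 12)[aggressiveness + 1]
  if (!is.function(backend) && !identical(backend, "reference"))
    stop_config("backend must be \"reference\" or a function")
  structure(list(segment_ms = segment_ms, aggressiveness = aggressiveness,
                 delta_db = delta_db,
                 noise_floor_percentile = noise_floor_percentile,
                 backend = backend),
            class = "vad_config")
}

#' Cut audio into consecutive equal-length segments
#'
#' @param audio an [audio_buffer()]
#' @param segment_ms segment length in milliseconds
#' @return a matrix with one column per segment (rows = samples); a trailing
#'   remainder shorter than one segment is dropped
#' @export
segment_audio <- function(audio, segment_ms = 5) {
  stopifnot(inherits(audio, "audio_buffer"))
  if (length(audio$samples) == 0L) stop_input("empty audio")
  len <- round(audio$sample_rate * segment_ms / 1000)
  if (len < 1) stop_input("segment shorter than one sample")
  n_seg <- length(audio$samples) %/% len
  if (n_seg == 0L) stop_input("audio shorter than one segment")
  matrix(audio$samples[seq_len(n_seg * len)], nrow = len)
}

segment_dbfs <- function(segments) {
  rms <- sqrt(colMeans(segments^2))
  db <- ifelse(rms > 0, 20 * log10(rms), -Inf)
  pmax(db, -96)
}

#' Estimate the noise floor of a recording
#'
#' The given percentile of per-segment RMS levels, in dBFS (20 log10 of RMS,
#' clamped at -96 dB for digital silence).
#'
#' @param audio an [audio_buffer()]
#' @param percentile percentile in [0, 100] (default 10)
#' @param segment_ms segment length used for the per-segment levels
#' @return noise floor in dBFS
#' @export
estimate_noise_floor <- function(audio, percentile = 10, segment_ms = 5) {
  segs <- segment_audio(audio, segment_ms)
  if (ncol(segs) < 10) stop_input("audio too short to estimate a noise floor (need >= 10 segments)")
  unname(stats::quantile(segment_dbfs(segs), percentile / 100))
}

#' Reference energy voice-activity detector
#'
#' A segment is voiced iff its level in dBFS strictly exceeds the noise floor
#' plus the activation margin.
#'
#' @param segments segment matrix from [segment_audio()]
#' @param noise_floor_db noise floor in dBFS
#' @param delta_db activation margin in dB
#' @return 0/1 vector, one decision per segment
#' @export
reference_vad <- function(segments, noise_floor_db, delta_db = 12) {
  if (!is_scalar_num(noise_floor_db)) stop_input("noise_floor_db must be finite")
  as.integer(segment_dbfs(segments) > noise_floor_db + delta_db)
}

#' Classify audio into 0.5-second dialogue windows
#'
#' Per-segment voice decisions (reference detector or external backend) are
#' majority-voted per window with the same tie-break and trailing-partial
#' rules as the gaze aggregation.
#'
#' @param audio an [audio_buffer()]
#' @param cfg a [vad_config()]
#' @param window_seconds window duration (default 0.5)
#' @return a [label_series()] of kind "voice"
#' @export
classify_dialogue <- function(audio, cfg = vad_config(), window_seconds = 0.5) {
  stopifnot(inherits(audio, "audio_buffer"))
  dur <- length(audio$samples) / audio$sample_rate
  if (dur < window_seconds) stop_input("audio spans less than one window")
  segs <- segment_audio(audio, cfg$segment_ms)
  if (is.function(cfg$backend)) {
    dec <- as.integer(cfg$backend(segs, audio$sample_rate))
    if (length(dec) != ncol(segs))
      stop_config("external VAD backend returned ", length(dec),
                  " decisions for ", ncol(segs), " segments")
  } else {
    floor_db <- estimate_noise_floor(audio, cfg$noise_floor_percentile,
                                     cfg$segment_ms)
    dec <- reference_vad(segs, floor_db, cfg$delta_db)
  }
  aggregate_frame_labels(dec, fps = 1000 / cfg$segment_ms,
                         window_seconds = window_seconds, kind = "voice")
}
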