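#' Head-geometry model configuration
#'
#' The simulator stands in for pose estimation with a simple head-centred
#' geometry: eyes sit at azimuths +/- `eye_azimuth` on a circle of radius
#' `eye_radius`, the nose protrudes at azimuth 0 on radius `nose_radius`, and
#' ears sit at +/- 90 degrees. A keypoint's image x-coordinate is
#' `radius * sin(azimuth + yaw) * pixel_scale`. The ear on the far side of a
#' head turn is occluded (confidence 0) once |yaw| exceeds
#' `ear_occlusion_yaw`. Under this projection the screen-gaze rule flips at
#' the closed-form boundary yaw returned by [gaze_boundary_yaw()].
#'
#' @param eye_azimuth eye azimuth in degrees (default 30)
#' @param eye_radius head-circle radius for the eyes (default 1)
#' @param nose_radius nose radius (default 1.8; must exceed
#'   `eye_radius * cos(eye_azimuth)` so the nose protrudes)
#' @param ear_occlusion_yaw yaw beyond which the far ear is lost (default 30)
#' @param screen_yaw_sd yaw spread (degrees) while facing the screen (default 5)
#' @param away_yaw_mean mean yaw when facing the patient: 45 for a
#'   semi-inclusive layout, 90 for a fully inclusive one
#' @param away_yaw_sd yaw spread when facing away (default 10)
#' @param pixel_scale pixels per model unit (default 200)
#' @param jitter_px Gaussian pixel noise sd on keypoint coordinates (default 0.5)
#' @param dropout_rate per-frame, per-keypoint probability of a missed
#'   detection (default 0)
#' @return a `head_model_config`
#' @export
head_model_config <- function(eye_azimuth = 30, eye_radius = 1,
                              nose_radius = 1.8, ear_occlusion_yaw = 30,
                              screen_yaw_sd = 5, away_yaw_mean = 45,
                              away_yaw_sd = 10, pixel_scale = 200,
                              jitter_px = 0.5, dropout_rate = 0) {
  if (eye_azimuth <= 0 || eye_azimuth >= 90)
    stop_config("eye_azimuth must be in (0, 90)")
  if (nose_radius <= eye_radius * cos(eye_azimuth * pi / 180))
    stop_config("nose_radius must exceed eye_radius * cos(eye_azimuth)")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_config("dropout_rate must be in [0,1]")
  structure(list(eye_azimuth = eye_azimuth, eye_radius = eye_radius,
                 nose_radius = nose_radius,
                 ear_occlusion_yaw = ear_occlusion_yaw,
                 screen_yaw_sd = screen_yaw_sd, away_yaw_mean = away_yaw_mean,
                 away_yaw_sd = away_yaw_sd, pixel_scale = pixel_scale,
                 jitter_px = jitter_px, dropout_rate = dropout_rate),
            class = "head_model_config")
}

#' Layout-specific head model
#'
#' Semi-inclusive seating needs only a ~45 degree head turn to face the
#' patient; fully inclusive seating needs ~90 degrees.
#'
#' @param layout "semi-inclusive" or "fully-inclusive"
#' @param ... overrides passed to [head_model_config()]
#' @return a `head_model_config`
#' @export
layout_head_config <- function(layout = c("semi-inclusive", "fully-inclusive"),
                               ...) {
  layout <- match.arg(layout)
  head_model_config(away_yaw_mean = if (layout == "fully-inclusive") 90 else 45,
                    ...)
}

#' Analytic yaw boundary of the gaze rule under the head model
#'
#' With eyes at +/- alpha on radius r and the nose on radius r_n, the nose
#' offset from the eye midpoint is (r_n - r cos alpha) sin(yaw) and the
#' inter-eye distance is 2 r sin(alpha) cos(yaw), so the half-inter-eye
#' tolerance is crossed at yaw* = atan(r sin(alpha) / (r_n - r cos(alpha))).
#'
#' @param cfg a [head_model_config()]
#' @param tolerance_factor gaze-rule tolerance (default 0.5)
#' @return boundary yaw in degrees
#' @export
gaze_boundary_yaw <- function(cfg = head_model_config(), tolerance_factor = 0.5) {
  a <- cfg$eye_azimuth * pi / 180
  atan(2 * tolerance_factor * cfg$eye_radius * sin(a) /
         (cfg$nose_radius - cfg$eye_radius * cos(a))) * 180 / pi
}

#' Project facial keypoints for given head yaws
#'
#' Vectorised over `yaw`; returns one frame per yaw on a 1/fps grid. Jitter
#' and dropout are applied only when configured (see [perturb_stream()]).
#'
#' @param yaw head yaw(s) in degrees, positive = turning away; |yaw| <= 180
#' @param cfg a [head_model_config()]
#' @param fps frame rate used to lay down timestamps (default 30)
#' @param person_id person identifier (default 0)
#' @return a [keypoint_stream()]
#' @export
project_keypoints <- function(yaw, cfg = head_model_config(), fps = 30,
                              person_id = 0L) {
  if (any(abs(yaw) > 180)) stop_input("|yaw| must be <= 180 degrees")
  d2r <- pi / 180
  n <- length(yaw)
  cx <- 320; cy <- 240
  px <- function(radius, azimuth_deg)
    cx + radius * sin((azimuth_deg + yaw) * d2r) * cfg$pixel_scale
  a <- cfg$eye_azimuth
  df <- data.frame(
    timestamp = (seq_len(n) - 1L) / fps,
    person_id = as.integer(person_id),
    nose_x = px(cfg$nose_radius, 0), nose_y = rep(cy + 40, n), nose_c = 0.9,
    left_eye_x = px(cfg$eye_radius, a), left_eye_y = rep(cy, n), left_eye_c = 0.9,
    right_eye_x = px(cfg$eye_radius, -a), right_eye_y = rep(cy, n),
    right_eye_c = 0.9,
    left_ear_x = px(cfg$eye_radius, 90), left_ear_y = rep(cy + 10, n),
    left_ear_c = 0.9,
    right_ear_x = px(cfg$eye_radius, -90), right_ear_y = rep(cy + 10, n),
    right_ear_c = 0.9
  )
  # the ear on the far side of the turn is occluded by the head
  df$right_ear_c[yaw > cfg$ear_occlusion_yaw] <- 0
  df$left_ear_c[yaw < -cfg$ear_occlusion_yaw] <- 0
  keypoint_stream(df)
}

#' Speech model configuration
#'
#' Dialogue states contain speech bursts (lognormal durations, clamped below
#' at `burst_min_s`) separated by short turn-taking gaps drawn uniformly from
#' `gap_range`. Voiced stretches are white noise at `voiced_dbfs`; everything
#' else is microphone noise at `silence_dbfs`.
#'
#' @param burst_mean_s,burst_sd_s mean and sd (seconds) of the burst-duration
#'   lognormal (defaults 2.5 and 1.0)
#' @param burst_min_s minimum utterance length (default 0.6)
#' @param gap_range turn-taking gap range in seconds (default c(0.2, 0.4))
#' @param voiced_dbfs speech level in dBFS (default -20)
#' @param silence_dbfs microphone noise floor in dBFS (default -60)
#' @return a `speech_model_config`
#' @export
speech_model_config <- function(burst_mean_s = 2.5, burst_sd_s = 1.0,
                                burst_min_s = 0.6, gap_range = c(0.2, 0.4),
                                voiced_dbfs = -20, silence_dbfs = -60) {
  if (burst_mean_s <= 0 || burst_sd_s <= 0 || burst_min_s <= 0)
    stop_config("burst durations must be positive")
  if (length(gap_range) != 2 || any(gap_range <= 0) || diff(gap_range) < 0)
    stop_config("gap_range must be an increasing positive pair")
  structure(list(burst_mean_s = burst_mean_s, burst_sd_s = burst_sd_s,
                 burst_min_s = burst_min_s, gap_range = gap_range,
                 voiced_dbfs = voiced_dbfs, silence_dbfs = silence_dbfs),
            class = "speech_model_config")
}

#' Scenario script for a simulated consultation
#'
#' @param states character vector of interaction classes, one per segment
#' @param durations segment durations in seconds (> 0, total >= 1.5 s)
#' @param layout clinic layout the session emulates
#' @param seed RNG seed making the session reproducible
#' @return a `scenario_script`
#' @export
scenario_script <- function(states, durations,
                            layout = c("semi-inclusive", "fully-inclusive"),
                            seed = 1L) {
  layout <- match.arg(layout)
  states <- as.character(states)
  if (length(states) != length(durations)) stop_input("states/durations lengths differ")
  bad <- setdiff(unique(states), INTERACTION_CLASSES)
  if (length(bad)) stop_input("unknown states: ", paste(bad, collapse = ", "))
  if (any(durations <= 0)) stop_input("durations must be > 0")
  if (sum(durations) < 1.5) stop_input("script must span at least 3 windows")
  structure(list(states = states, durations = as.numeric(durations),
                 layout = layout, seed = as.integer(seed)),
            class = "scenario_script")
}

#' Sample a consultation script on the 0.5-second coding grid
#'
#' States alternate under a simple kernel dominated by the D <-> SG+D
#' exchange seen in real consultations; segment durations are lognormal with
#' the given mean, clamped to [2, 20] s and rounded to the coding grid so
#' scripted transitions fall on window boundaries.
#'
#' @param total_seconds session length (default 180)
#' @param layout clinic layout
#' @param seed RNG seed
#' @param mean_state_s mean segment duration (default 8)
#' @return a [scenario_script()]
#' @export
sample_script <- function(total_seconds = 180,
                          layout = c("semi-inclusive", "fully-inclusive"),
                          seed = 1L, mean_state_s = 8) {
  layout <- match.arg(layout)
  set.seed(seed)
  weights <- c("SG+D" = 0.35, "D" = 0.45, "SG" = 0.12, "Other" = 0.08)
  sdlog <- sqrt(log(1 + (mean_state_s / 2 / mean_state_s)^2))
  meanlog <- log(mean_state_s) - sdlog^2 / 2
  states <- character(0); durs <- numeric(0); tot <- 0
  prev <- sample(names(weights), 1, prob = weights)
  while (tot < total_seconds) {
    w <- weights[names(weights) != prev]
    s <- sample(names(w), 1, prob = w)
    d <- min(20, max(2, stats::rlnorm(1, meanlog, sdlog)))
    d <- round(d * 2) / 2                      # snap to the 0.5-s grid
    d <- min(d, total_seconds - tot)
    if (d < 2) d <- total_seconds - tot        # absorb the tail
    states <- c(states, s); durs <- c(durs, d); tot <- tot + d
    prev <- s
  }
  scenario_script(states, durs, layout, seed)
}

#' Add keypoint jitter and detection dropout to a stream
#'
#' @param stream a [keypoint_stream()]
#' @param jitter_px Gaussian pixel noise sd
#' @param dropout_rate independent per-keypoint dropout probability
#'   (confidence set to 0)
#' @param seed RNG seed
#' @return the perturbed [keypoint_stream()]
#' @export
perturb_stream <- function(stream, jitter_px = 0, dropout_rate = 0,
                           seed = NULL) {
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_input("dropout_rate must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(stream)
  for (k in KEYPOINTS) {
    if (jitter_px > 0) {
      stream[[paste0(k, "_x")]] <- stream[[paste0(k, "_x")]] +
        stats::rnorm(n, 0, jitter_px)
      stream[[paste0(k, "_y")]] <- stream[[paste0(k, "_y")]] +
        stats::rnorm(n, 0, jitter_px)
    }
    if (dropout_rate > 0) {
      drop <- stats::runif(n) < dropout_rate
      stream[[paste0(k, "_c")]][drop] <- 0
    }
  }
  stream
}

# per-sample voiced indicator for one dialogue interval [s, e)
voiced_mask_for_interval <- function(s, e, sr, speech_cfg) {
  sdlog <- sqrt(log(1 + (speech_cfg$burst_sd_s / speech_cfg$burst_mean_s)^2))
  meanlog <- log(speech_cfg$burst_mean_s) - sdlog^2 / 2
  t <- s
  out <- list()
  while (t < e) {
    burst <- max(speech_cfg$burst_min_s, stats::rlnorm(1, meanlog, sdlog))
    b_end <- min(t + burst, e)
    out[[length(out) + 1]] <- c(t, b_end)
    t <- b_end + stats::runif(1, speech_cfg$gap_range[1], speech_cfg$gap_range[2])
  }
  out
}

#' Generate a synthetic consultation session
#'
#' Discretises the script to the window grid for the ground truth, draws a
#' head-yaw trajectory (screen-facing yaws in SG+D/SG segments, away yaws in
#' D/Other segments), projects it to keypoints with the configured jitter and
#' dropout, and synthesises audio with speech bursts and turn-taking gaps in
#' dialogue segments. Deterministic under the script's seed.
#'
#' @param script a [scenario_script()]
#' @param head_cfg a [head_model_config()]; defaults to the script's layout
#' @param speech_cfg a [speech_model_config()]
#' @param fps video frame rate (default 30)
#' @param sample_rate audio sample rate in Hz (default 16000)
#' @param audio generate the waveform (TRUE, default) or only the per-segment
#'   voice decisions on the `segment_ms` grid (FALSE, faster)
#' @param segment_ms segment grid used when `audio = FALSE` (default 5)
#' @return list with `keypoints` ([keypoint_stream()]), `audio`
#'   ([audio_buffer()] or NULL), `voice_segments` (0/1 per segment, or NULL),
#'   `truth` ([interaction_timeline()]), `fps`, `script`
#' @export
generate_session <- function(script, head_cfg = NULL,
                             speech_cfg = speech_model_config(), fps = 30,
                             sample_rate = 16000, audio = TRUE,
                             segment_ms = 5) {
  stopifnot(inherits(script, "scenario_script"))
  if (is.null(head_cfg)) head_cfg <- layout_head_config(script$layout)
  set.seed(script$seed)
  total <- sum(script$durations)
  if (total < 0.5) stop_input("script shorter than one window")
  starts <- cumsum(c(0, script$durations))[seq_along(script$durations)]
  ends <- starts + script$durations

  # ground truth: the script on the window grid (majority state per window)
  truth <- intervals_to_windows(
    data.frame(start_s = starts, end_s = ends, label = script$states,
               stringsAsFactors = FALSE))

  # head yaw: per-segment mean plus per-frame spread, halved between levels
  n_frames <- round(total * fps)
  t_frames <- (seq_len(n_frames) - 1L) / fps
  seg_of <- findInterval(t_frames, starts)
  yaw <- numeric(n_frames)
  for (i in seq_along(script$states)) {
    idx <- which(seg_of == i)
    if (!length(idx)) next
    facing_screen <- script$states[i] %in% c("SG+D", "SG")
    mu <- if (facing_screen) 0 else head_cfg$away_yaw_mean
    sd <- if (facing_screen) head_cfg$screen_yaw_sd else head_cfg$away_yaw_sd
    seg_mu <- stats::rnorm(1, mu, sd / 2)
    yaw[idx] <- stats::rnorm(length(idx), seg_mu, sd / 2)
  }
  kp <- project_keypoints(yaw, head_cfg, fps = fps)
  kp <- perturb_stream(kp, head_cfg$jitter_px, head_cfg$dropout_rate)

  # voice: burst/gap structure inside dialogue segments
  voiced_iv <- list()
  for (i in seq_along(script$states)) {
    if (!script$states[i] %in% c("SG+D", "D")) next
    voiced_iv <- c(voiced_iv,
                   voiced_mask_for_interval(starts[i], ends[i], sample_rate,
                                            speech_cfg))
  }
  buf <- NULL; voice_segments <- NULL
  if (audio) {
    n_samp <- round(total * sample_rate)
    amp_sil <- 10^(speech_cfg$silence_dbfs / 20)
    amp_voc <- 10^(speech_cfg$voiced_dbfs / 20)
    s <- stats::rnorm(n_samp) * amp_sil
    for (iv in voiced_iv) {
      i0 <- floor(iv[1] * sample_rate) + 1L
      i1 <- min(n_samp, ceiling(iv[2] * sample_rate))
      if (i1 >= i0) s[i0:i1] <- stats::rnorm(i1 - i0 + 1L) * amp_voc
    }
    buf <- audio_buffer(pmin(1, pmax(-1, s)), sample_rate)
  } else {
    seg_s <- segment_ms / 1000
    n_seg <- floor(total / seg_s)
    mid <- (seq_len(n_seg) - 0.5) * seg_s
    voice_segments <- integer(n_seg)
    for (iv in voiced_iv)
      voice_segments[mid >= iv[1] & mid < iv[2]] <- 1L
  }
  list(keypoints = kp, audio = buf, voice_segments = voice_segments,
       truth = truth, fps = fps, script = script)
}

#' Run the full classification pipeline on a session
#'
#' Gaze rule + windowing on the keypoint stream, VAD + windowing on the audio
#' (or directly on pre-computed segment decisions), fused to the four-class
#' timeline.
#'
#' @param session output of [generate_session()], or a list with `keypoints`,
#'   `fps` and either `audio` or `voice_segments`
#' @param gaze_cfg a [gaze_config()]
#' @param vad_cfg a [vad_config()]
#' @param window_seconds window duration (default 0.5)
#' @return an [interaction_timeline()]
#' @export
classify_session <- function(session, gaze_cfg = gaze_config(),
                             vad_cfg = vad_config(), window_seconds = 0.5) {
  gaze <- classify_gaze_stream(session$keypoints, gaze_cfg, fps = session$fps,
                               window_seconds = window_seconds)
  if (!is.null(session$audio)) {
    voice <- classify_dialogue(session$audio, vad_cfg, window_seconds)
  } else {
    voice <- aggregate_frame_labels(session$voice_segments,
                                    fps = 1000 / vad_cfg$segment_ms,
                                    window_seconds = window_seconds,
                                    kind = "voice")
  }
  fuse_streams(gaze, voice)
}
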