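test_that("keypoint projection: frontal pose passes the rule, profile fails, boundary is sharp", {
  cfg <- head_model_config(jitter_px = 0)
  f0 <- project_keypoints(0, cfg)
  expect_equal(f0$nose_x, (f0$left_eye_x + f0$right_eye_x) / 2)
  expect_equal(classify_frame_gaze(f0), 1L)
  f90 <- project_keypoints(90, cfg)
  expect_equal(f90$right_ear_c, 0)
  expect_equal(classify_frame_gaze(f90), 0L)
  # closed-form boundary: atan(0.5 / 0.9340) ~ 28.2 degrees at the defaults
  th <- gaze_boundary_yaw(cfg)
  expect_equal(th, atan(sin(pi / 6) / (1.8 - cos(pi / 6))) * 180 / pi)
  expect_equal(th, 28.2, tolerance = 0.01)
  expect_equal(classify_frame_gaze(project_keypoints(th - 1, cfg)), 1L)
  expect_equal(classify_frame_gaze(project_keypoints(th + 1, cfg)), 0L)
  expect_error(project_keypoints(200, cfg), "yaw")
  expect_error(head_model_config(nose_radius = 0.5), "nose_radius")
})

test_that("empirical yaw sweep locates the analytic rule boundary within a degree", {
  cfg <- head_model_config(jitter_px = 0, ear_occlusion_yaw = 90)
  yaw <- seq(0, 60, by = 0.1)
  lab <- classify_frame_gaze(project_keypoints(yaw, cfg))
  emp <- yaw[max(which(lab == 1))]
  expect_equal(emp, gaze_boundary_yaw(cfg), tolerance = 1)
})

test_that("perturbation: identity at zero noise, total dropout, binomial dropout rate", {
  kp <- project_keypoints(seq(0, 50, length.out = 100), head_model_config(jitter_px = 0))
  expect_equal(perturb_stream(kp, 0, 0, seed = 1), kp)
  gone <- perturb_stream(kp, 0, 1, seed = 1)
  expect_true(all(as.matrix(gone[paste0(KEYPOINTS, "_c")]) == 0))
  big <- project_keypoints(rep(0, 2000), head_model_config(jitter_px = 0))
  p <- 0.1
  pert <- perturb_stream(big, 0, p, seed = 9)
  n <- 2000 * 5
  frac <- mean(as.matrix(pert[paste0(KEYPOINTS, "_c")]) == 0)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("session generation is deterministic and honours a clean script", {
  scr <- scenario_script(c("SG+D", "D", "SG", "Other"), rep(5, 4),
                         "semi-inclusive", seed = 4)
  a <- generate_session(scr)
  b <- generate_session(scr)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_equal(length(a$truth$labels), 40)
  expect_equal(a$truth$labels[1], "SG+D")
  # end-to-end agreement up to one window at each scripted boundary
  pred <- classify_session(a)
  mism <- which(pred$labels != a$truth$labels)
  boundaries <- find_transitions(a$truth)$records$boundary_index
  expect_true(all(vapply(mism, function(w) any(abs(w - boundaries) <= 1),
                         logical(1))))
  # all-screen-gaze script with zero noise gives an all-ones gaze series
  quiet <- generate_session(
    scenario_script("SG", 5, seed = 2),
    head_cfg = head_model_config(jitter_px = 0, dropout_rate = 0, screen_yaw_sd = 1))
  gaze <- classify_gaze_stream(quiet$keypoints, fps = quiet$fps)
  expect_true(all(gaze$labels == 1))
})

test_that("segment-decision mode matches the scripted voice pattern without audio", {
  scr <- scenario_script(c("D", "Other", "D"), c(3, 3, 3), seed = 6)
  ses <- generate_session(scr, audio = FALSE)
  expect_null(ses$audio)
  expect_length(ses$voice_segments, 9 / 0.005)
  voice <- aggregate_frame_labels(ses$voice_segments, 200, 0.5, kind = "voice")
  # silent middle block stays silent
  expect_true(all(voice$labels[8:11] == 0))
  expect_true(mean(voice$labels[1:6]) > 0.8)
})

test_that("layout effect: fully inclusive separates gaze states more and never scores worse", {
  semi <- layout_head_config("semi-inclusive")
  fully <- layout_head_config("fully-inclusive")
  th <- gaze_boundary_yaw(semi)
  expect_gt(abs(fully$away_yaw_mean - th), abs(semi$away_yaw_mean - th))
  sp <- speech_model_config(gap_range = c(0.20, 0.24))
  acc <- function(layout, seed) {
    scr <- sample_script(90, layout, seed = seed)
    ses <- generate_session(scr, speech_cfg = sp)
    mean(classify_session(ses)$labels == ses$truth$labels)
  }
  accs_semi <- vapply(1:3, function(s) acc("semi-inclusive", 300 + s), numeric(1))
  accs_fully <- vapply(1:3, function(s) acc("fully-inclusive", 300 + s), numeric(1))
  expect_gte(mean(accs_fully), mean(accs_semi))
})

test_that("recovery under default noise: scripted timeline reproduced at >= 0.95 accuracy", {
  # ten 3-minute sessions, five per layout, generator defaults throughout
  accs <- vapply(1:10, function(i) {
    layout <- if (i %% 2) "semi-inclusive" else "fully-inclusive"
    scr <- sample_script(180, layout, seed = 400 + i)
    ses <- generate_session(scr, sample_rate = 8000)
    mean(classify_session(ses)$labels == ses$truth$labels)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("lengthening turn gaps beyond 0.5 s increases D windows classified Other", {
  scr <- scenario_script(c("D", "SG", "D"), c(20, 3, 20), seed = 12)
  d_to_other <- function(gaps) {
    ses <- generate_session(scr, speech_cfg = speech_model_config(gap_range = gaps))
    pred <- classify_session(ses)
    sum(ses$truth$labels == "D" & pred$labels == "Other")
  }
  short <- d_to_other(c(0.20, 0.24))
  long <- d_to_other(c(0.7, 0.9))
  expect_gt(long, short)
})
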