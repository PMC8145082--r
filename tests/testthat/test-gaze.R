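test_that("frame gaze rule: ear and nose-centering conditions with inclusive tolerance", {
  # nose exactly at the eye midpoint, everything estimated
  expect_equal(classify_frame_gaze(keypoint_stream(make_frame(nose_x = 120))), 1L)
  # missing ear vetoes regardless of nose position
  expect_equal(classify_frame_gaze(keypoint_stream(
    make_frame(nose_x = 120, ear_c = c(0.9, 0)))), 0L)
  # inter-eye 40 -> tolerance 20: offset 1 in, offset 21 out, offset 20 on the
  # boundary counts as screen gaze
  off <- function(nx) classify_frame_gaze(keypoint_stream(make_frame(nose_x = nx)))
  expect_equal(off(121), 1L)
  expect_equal(off(141), 0L)
  expect_equal(off(140), 1L)
  # missing eye or nose also vetoes
  expect_equal(classify_frame_gaze(keypoint_stream(
    make_frame(eye_c = c(0, 0.9)))), 0L)
  expect_equal(classify_frame_gaze(keypoint_stream(make_frame(nose_c = 0))), 0L)
})

test_that("malformed keypoints are rejected naming the frame", {
  bad <- make_frame()
  bad$nose_c <- 1.2
  expect_error(keypoint_stream(bad), "confidence")
  bad2 <- rbind(make_frame(), make_frame(timestamp = 1 / 30))
  bad2$left_eye_x[2] <- NaN
  expect_error(keypoint_stream(bad2), "frame row 2")
})

test_that("primary person selection: largest mean inter-eye distance, tie to lower id", {
  a <- make_stream(5, le_x = 100, re_x = 160)          # inter-eye 60
  b <- make_stream(5, le_x = 100, re_x = 125)          # inter-eye 25
  b$person_id <- 1L
  both <- keypoint_stream(rbind(a, b))
  expect_equal(select_primary_person(both), 0)
  b2 <- make_stream(5, le_x = 100, re_x = 160)
  b2$person_id <- 5L
  expect_equal(select_primary_person(keypoint_stream(rbind(a, b2))), 0)
  single <- make_stream(3)
  expect_equal(select_primary_person(single), 0)
  blind <- make_stream(3, eye_c = c(0, 0))
  expect_error(select_primary_person(blind), "no classifiable person")
})

test_that("window vote: majority, tie to previous window, partial-window rule", {
  expect_equal(aggregate_frame_labels(rep(1, 15), 30, 0.5)$labels, 1L)
  expect_equal(aggregate_frame_labels(c(rep(1, 8), rep(0, 7)), 30, 0.5)$labels, 1L)
  expect_equal(aggregate_frame_labels(c(rep(1, 7), rep(0, 8)), 30, 0.5)$labels, 0L)
  # fps 4 -> 2 frames/window; tie (1,0) after a 0-window stays 0
  expect_equal(aggregate_frame_labels(c(0, 0, 1, 0), 4, 0.5)$labels, c(0L, 0L))
  # tie in the very first window resolves to 0; after a 1-window stays 1
  expect_equal(aggregate_frame_labels(c(1, 0), 4, 0.5)$labels, 0L)
  expect_equal(aggregate_frame_labels(c(1, 1, 1, 0), 4, 0.5)$labels, c(1L, 1L))
  # trailing partial: 15 + 8 frames keeps the partial, 15 + 7 drops it
  expect_length(aggregate_frame_labels(rep(1, 23), 30, 0.5)$labels, 2)
  expect_length(aggregate_frame_labels(rep(1, 22), 30, 0.5)$labels, 1)
  expect_error(aggregate_frame_labels(integer(0), 30, 0.5), "empty")
})

test_that("window vote equals the brute-force oracle on random streams", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- sample(0:1, 300, TRUE)
    fps <- sample(c(4, 10, 24, 30), 1)
    expect_equal(aggregate_frame_labels(x, fps, 0.5)$labels,
                 oracle_vote(x, fps, 0.5), info = paste("seed", seed))
  }
  # non-multiple lengths exercise the partial rule
  set.seed(99)
  x <- sample(0:1, 307, TRUE)
  expect_equal(aggregate_frame_labels(x, 30, 0.5)$labels, oracle_vote(x, 30, 0.5))
})

test_that("stream classification matches frame-wise oracle across a yaw sweep", {
  yaw <- seq(0, 120, length.out = 240)
  kp <- project_keypoints(yaw, head_model_config(jitter_px = 0), fps = 30)
  got <- classify_gaze_stream(kp, fps = 30)
  per_frame <- vapply(seq_len(nrow(kp)),
                      function(i) oracle_frame_gaze(kp[i, ]), integer(1))
  expect_equal(got$labels, oracle_vote(per_frame, 30, 0.5))
  expect_s3_class(got, "label_series")
  expect_equal(got$kind, "gaze")
})

test_that("gaze invariants: determinism, tolerance monotonicity, ear necessity, mirror symmetry", {
  set.seed(42)
  yaw <- runif(300, -90, 90)
  kp <- perturb_stream(project_keypoints(yaw, fps = 30), jitter_px = 2, seed = 1)
  # determinism
  expect_identical(classify_gaze_stream(kp, fps = 30),
                   classify_gaze_stream(kp, fps = 30))
  # enlarging the tolerance never flips screen-gaze to no-screen-gaze
  lab_small <- classify_frame_gaze(kp, gaze_config(tolerance_factor = 0.3))
  lab_big <- classify_frame_gaze(kp, gaze_config(tolerance_factor = 0.8))
  expect_true(all(lab_big >= lab_small))
  # zero ear confidence forces an all-zero series
  deaf <- kp
  deaf$left_ear_c <- 0; deaf$right_ear_c <- 0
  expect_true(all(classify_gaze_stream(keypoint_stream(deaf), fps = 30)$labels == 0))
  # mirror about x = 320 with left/right swap leaves labels unchanged
  mir <- kp
  for (p in c("eye", "ear")) {
    for (s in c("x", "y", "c")) {
      l <- paste0("left_", p, "_", s); r <- paste0("right_", p, "_", s)
      tmp <- mir[[l]]; mir[[l]] <- mir[[r]]; mir[[r]] <- tmp
    }
  }
  for (col in grep("_x$", names(mir), value = TRUE)) mir[[col]] <- 640 - mir[[col]]
  expect_equal(classify_frame_gaze(keypoint_stream(mir)), classify_frame_gaze(kp))
})

test_that("multi-person streams must be resolved before windowing", {
  a <- make_stream(4)
  b <- make_stream(4)
  b$person_id <- 1L
  expect_error(classify_gaze_stream(keypoint_stream(rbind(a, b)), fps = 8),
               "select_primary_person")
})
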