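tone <- function(dur, sr = 16000, amp = 0.5, freq = 440)
  amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)[-1])

test_that("segmentation arithmetic and remainder rule", {
  a <- audio_buffer(rep(0, 16000), 16000)
  segs <- segment_audio(a, 5)
  expect_equal(nrow(segs), 80)    # 16 kHz x 5 ms
  expect_equal(ncol(segs), 200)   # 1 s -> 200 segments
  a2 <- audio_buffer(rep(0, 16040), 16000)  # 1.0025 s
  expect_equal(ncol(segment_audio(a2, 5)), 200)  # 40-sample remainder dropped
  expect_error(segment_audio(audio_buffer(numeric(0)), 5), "empty")
})

test_that("noise floor: clamped silence, full-scale square wave, brute-force percentile", {
  silence <- audio_buffer(rep(0, 16000))
  expect_equal(estimate_noise_floor(silence), -96)
  square <- audio_buffer(rep(c(1, -1), 8000))
  for (p in c(0, 10, 50, 100))
    expect_equal(estimate_noise_floor(square, p), 0)
  # known-amplitude blocks vs quantile over per-segment RMS values
  set.seed(3)
  amps <- rep(c(0.001, 0.01, 0.1, 0.5), each = 40)  # 160 segments of 80 samples
  x <- unlist(lapply(amps, function(a) rep(a, 80)))
  buf <- audio_buffer(x)
  rms_db <- pmax(-96, 20 * log10(sqrt(colMeans(matrix(x, 80)^2))))
  expect_equal(estimate_noise_floor(buf, 25),
               unname(quantile(rms_db, 0.25)))
  expect_error(estimate_noise_floor(audio_buffer(rep(0, 100))), "too short")
})

test_that("reference detector: strict threshold above floor plus margin", {
  zero <- matrix(0, 80, 1)
  expect_equal(reference_vad(zero, -60, 6), 0L)
  loud <- matrix(rep(c(1, -1), 40), 80, 1)     # 0 dBFS
  expect_equal(reference_vad(loud, -60, 6), 1L)
  # RMS exactly at floor + margin stays no_voice (strict inequality)
  amp <- 10^(-54 / 20)
  seg <- matrix(rep(c(amp, -amp), 40), 80, 1)
  expect_equal(reference_vad(seg, -60, 6), 0L)
})

test_that("aggressiveness maps onto the activation margin; explicit delta wins", {
  expect_equal(vad_config(aggressiveness = 0)$delta_db, 3)
  expect_equal(vad_config(aggressiveness = 3)$delta_db, 12)
  expect_equal(vad_config(aggressiveness = 3, delta_db = 5)$delta_db, 5)
  expect_error(vad_config(aggressiveness = 7), "aggressiveness")
})

test_that("dialogue windows: silence totality and 60/40 vs 40/60 majorities", {
  sr <- 16000
  silence <- audio_buffer(rnorm(3 * sr) * 1e-4, sr)
  expect_equal(classify_dialogue(silence)$labels, rep(0L, 6))
  # 0.3 s voice + 0.2 s near-silence per window -> majority voice
  set.seed(11)
  win_voiced <- c(rnorm(0.3 * sr) * 0.3, rnorm(0.2 * sr) * 1e-4)
  buf <- audio_buffer(pmin(1, pmax(-1, rep(win_voiced, 8))), sr)
  got <- classify_dialogue(buf)
  expect_equal(got$labels, rep(1L, 8))
  expect_equal(got$kind, "voice")
  # 0.2 s voice + 0.3 s silence -> majority silence
  win_quiet <- c(rnorm(0.2 * sr) * 0.3, rnorm(0.3 * sr) * 1e-4)
  buf2 <- audio_buffer(pmin(1, pmax(-1, rep(win_quiet, 8))), sr)
  expect_equal(classify_dialogue(buf2)$labels, rep(0L, 8))
})

test_that("windowed VAD equals brute-force per-segment decision + vote", {
  sr <- 8000
  set.seed(21)
  voiced <- runif(40) < 0.5
  x <- unlist(lapply(voiced, function(v)
    rnorm(0.25 * sr) * if (v) 0.3 else 1e-4))      # 10 s in 0.25-s blocks
  buf <- audio_buffer(pmin(1, pmax(-1, x)), sr)
  cfg <- vad_config()
  got <- classify_dialogue(buf, cfg)
  segs <- matrix(buf$samples[seq_len((length(buf$samples) %/% 40) * 40)], 40)
  db <- pmax(-96, 20 * log10(sqrt(colMeans(segs^2))))
  fl <- unname(quantile(db, 0.10))
  dec <- as.integer(db > fl + 12)
  expect_equal(got$labels, oracle_vote(dec, 200, 0.5))
})

test_that("amplitude scaling with a consistent floor leaves decisions unchanged", {
  set.seed(5)
  segs <- matrix(rnorm(80 * 50) * rep(runif(50, 0.001, 0.5), each = 80), 80)
  base <- reference_vad(segs, -40, 12)
  half <- reference_vad(segs / 2, -40 + 20 * log10(0.5), 12)
  expect_equal(half, base)
})

test_that("window-count contract matches the gaze rule on the same duration", {
  sr <- 16000
  # durations representable in whole frames at 30 fps
  for (dur in c(1, 1.2, 1.3, 2.7, 2.9)) {
    buf <- audio_buffer(rnorm(round(dur * sr)) * 0.2, sr)
    n_audio <- length(classify_dialogue(buf)$labels)
    n_gaze <- length(aggregate_frame_labels(rep(1, round(dur * 30)), 30, 0.5)$labels)
    expect_equal(n_audio, n_gaze, info = paste("duration", dur))
  }
})

test_that("external backend is called and validated", {
  buf <- audio_buffer(rnorm(16000) * 0.1)
  all_on <- function(segs, sr) rep(1L, ncol(segs))
  expect_equal(classify_dialogue(buf, vad_config(backend = all_on))$labels,
               rep(1L, 2))
  broken <- function(segs, sr) c(1L, 0L)
  expect_error(classify_dialogue(buf, vad_config(backend = broken)),
               "backend")
  expect_error(vad_config(backend = "webrtc"), "backend")
})

test_that("WAV round trip preserves samples to 16-bit precision", {
  set.seed(8)
  x <- round(runif(4000, -0.9, 0.9) * 32768) / 32768
  buf <- audio_buffer(x, 8000)
  path <- tempfile(fileext = ".wav")
  write_wav(buf, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$samples, x, tolerance = 1 / 32768)
  unlink(path)
})
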