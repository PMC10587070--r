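# Acoustic front end: spectrogram pair, channel difference, detection,
# classification, syllable onsets, clock alignment.

make_tone_scene <- function(f, fs = 48000, dur = 0.5, amp = 0.2) {
  t <- (seq_len(dur * fs) - 1) / fs
  w <- amp * sin(2 * pi * f * t)
  structure(list(parabolic = w, reference = w, sample_rate_hz = fs),
            class = "acoustic_scene")
}

test_that("spectrogram pair puts energy in the right bin and shares axes", {
  sc <- make_tone_scene(8000)
  sp <- compute_spectrogram_pair(sc)
  peak_bin <- apply(sp$par_db, 2, which.max)
  expect_true(all(abs(sp$freq_hz[peak_bin] - 8000) < 100))
  expect_equal(dim(sp$par_db), dim(sp$ref_db))

  # silence: all frames at floor
  sc0 <- structure(list(parabolic = numeric(48000),
                        reference = numeric(48000), sample_rate_hz = 48000),
                   class = "acoustic_scene")
  sp0 <- compute_spectrogram_pair(sc0)
  expect_true(all(sp0$par_db <= -180))
  expect_error(compute_spectrogram_pair(
    structure(list(parabolic = numeric(0), reference = numeric(0),
                   sample_rate_hz = 48000), class = "acoustic_scene")),
    "empty")
})

test_that("channel difference cancels identical channels", {
  sp <- compute_spectrogram_pair(make_tone_scene(8000))
  d <- channel_difference(sp)
  expect_true(all(abs(d$diff_db) < 1e-9))
  expect_true(all(abs(d$frame_diff_db) < 1e-9))
})

test_that("segment detection merges across gaps and is threshold-monotone", {
  # all-zero difference map -> nothing
  sp <- compute_spectrogram_pair(make_tone_scene(8000))
  d <- channel_difference(sp)
  expect_equal(nrow(detect_target_segments(d)), 0)

  # two bursts separated by more than the merge gap stay separate
  cfg <- synth_config()
  ev <- call_events(c(0.5, 1.5), c(0.8, 1.8), c("trill", "trill"))
  sc <- generate_acoustic_scene(ev, call_events(), cfg, seed = 1,
                                duration_s = 2.5)
  d2 <- channel_difference(compute_spectrogram_pair(sc))
  seg_wide <- detect_target_segments(d2, detection_params(max_gap_s = 1))
  seg_tight <- detect_target_segments(d2, detection_params(max_gap_s = 0.15))
  expect_equal(nrow(seg_wide), 1)
  expect_equal(nrow(seg_tight), 2)

  # raising the threshold never adds a segment (monotone)
  n_low <- nrow(detect_target_segments(d2, detection_params(threshold_db = 6)))
  n_high <- nrow(detect_target_segments(d2,
                                        detection_params(threshold_db = 14)))
  expect_lte(n_high, n_low)
})

test_that("the rule cascade classifies every synthetic call type", {
  cfg <- synth_config()
  fs <- cfg$sample_rate_hz
  for (ty in c("phee", "trill", "twitter", "trillphee", "compound")) {
    dur <- mean(cfg$duration_range_s[[ty]])
    syl <- callcortex:::syllable_times(1, 1 + dur, ty, cfg)
    off <- if (ty == "twitter") max(syl) + cfg$twitter_syllable_duty_s
           else 1 + dur
    ev <- call_events(1, off, ty, list(syl))
    w <- synthesize_call_waveform(ev[1, ], fs, cfg)
    expect_equal(classify_call_type(w, fs), ty, label = ty)
  }
  # unclassifiable input gets an explicit unknown
  set.seed(1)
  expect_equal(classify_call_type(rnorm(4800, 0, 0.01), fs), "unknown")
})

test_that("syllable onsets are recovered within 5 ms", {
  cfg <- synth_config(twitter_syllable_jitter_s = 0)
  fs <- cfg$sample_rate_hz
  syl <- (0:6) / 7
  ev <- call_events(0, 6 / 7 + 0.045, "twitter", list(syl))
  w <- synthesize_call_waveform(ev[1, ], fs, cfg)
  on <- detect_syllable_onsets(w, fs)
  expect_length(on, 7)
  expect_lt(max(abs(on - syl)), 0.005)
  expect_true(all(diff(on) > 0))
  # silence: empty with a warning
  expect_warning(o0 <- detect_syllable_onsets(numeric(9600), fs), "bursts")
  expect_length(o0, 0)
})

test_that("clock alignment recovers offset and drift", {
  s <- generate_sync(1200, drift_ppm = 0, seed = 1, offset_s = 0)
  cm0 <- align_clocks(s$audio, s$audio)
  expect_lt(abs(cm0$offset_s), 1e-9)
  expect_lt(abs(cm0$drift), 1e-12)

  s1 <- generate_sync(1200, drift_ppm = 0, seed = 1, offset_s = 1.234)
  cm1 <- align_clocks(s1$audio, s1$neural)
  expect_lt(abs(cm1$offset_s - 1.234), 1e-3)

  s2 <- generate_sync(1200, drift_ppm = 100, seed = 1, offset_s = 0.5)
  cm2 <- align_clocks(s2$audio, s2$neural)
  expect_lt(abs(cm2$drift * 1e6 - 100), 5)
  # applying then inverting is identity within 1 ms
  t <- c(0, 250, 1200)
  expect_lt(max(abs(cm2$to_audio(cm2$to_neural(t)) - t)), 1e-3)

  bad <- structure(list(times = seq(0, 20, by = 2), period_s = 2),
                   class = "sync_pulses")
  expect_error(align_clocks(s$audio, bad), "mismatch")
})

test_that("end-to-end detection on a mixed scene is accurate", {
  cfg <- synth_config()
  targets <- generate_call_sequence(cfg, 150, seed = 21)
  cfg_non <- synth_config(call_rates_per_min = c(phee = 2, trill = 2,
                                                 twitter = 0, trillphee = 0,
                                                 compound = 0))
  nontargets <- generate_call_sequence(cfg_non, 150, seed = 22)
  nontargets$is_target <- rep(FALSE, nrow(nontargets))
  expect_gt(nrow(targets), 4)
  scene <- generate_acoustic_scene(targets, nontargets, cfg, seed = 23,
                                   duration_s = 150)
  det <- detect_calls(scene)
  sc <- score_detection(det, targets)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$type_accuracy, 0.8)
})
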