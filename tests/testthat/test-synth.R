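# Synthetic-data generator: call sequences, waveforms, scenes, LFP,
# spikes, sync, and the round-trip/determinism contracts.

test_that("call sequence respects rates, spacing and syllable structure", {
  cfg0 <- synth_config(call_rates_per_min = c(phee = 0, trill = 0,
                                              twitter = 0, trillphee = 0,
                                              compound = 0))
  expect_equal(nrow(generate_call_sequence(cfg0, 600, seed = 1)), 0)

  # deterministic twitter syllable grid at 7 Hz, zero jitter
  cfg <- synth_config(twitter_syllable_jitter_s = 0)
  s <- callcortex:::syllable_times(2, 3, "twitter", cfg)
  expect_equal(s - 2, (0:6) / 7)

  ev <- generate_call_sequence(synth_config(), 300, seed = 42)
  expect_s3_class(ev, "call_events")
  expect_true(all(ev$offset_s > ev$onset_s))
  expect_true(!is.unsorted(ev$onset_s))
  # targets never overlap
  if (nrow(ev) > 1) {
    expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
  }
  expect_error(generate_call_sequence(synth_config(), -5), "duration")
  expect_error(synth_config(call_rates_per_min = c(phee = -1, trill = 0,
                                                   twitter = 0,
                                                   trillphee = 0,
                                                   compound = 0)),
               "rates")
})

test_that("per-type counts follow a Poisson process at the configured rate", {
  # oracle: Poisson mean/variance; trill at 6/min over 3600 s has mean 360
  cfg <- synth_config(call_rates_per_min = c(phee = 0, trill = 6,
                                             twitter = 0, trillphee = 0,
                                             compound = 0))
  counts <- vapply(1:100, function(s)
    nrow(generate_call_sequence(cfg, 3600, seed = s)), 0L)
  se <- sqrt(360 / 100)
  expect_lt(abs(mean(counts) - 360), 3 * se)
})

test_that("call waveforms carry their configured FM structure", {
  cfg <- synth_config()
  fs <- 48000
  # degenerate FM: trill with zero depth is a pure tone
  cfg0 <- synth_config(trill_fm_depth_hz = 0)
  ev <- call_events(0, 0.5, "trill")
  w <- synthesize_call_waveform(ev[1, ], fs, cfg0)
  spec <- Mod(stats::fft(w * callcortex:::hann(length(w))))^2
  f_peak <- (which.max(spec[1:(length(w) / 2)]) - 1) * fs / length(w)
  expect_lt(abs(f_peak - cfg0$trill_carrier_hz), 20)

  # twitter with 5 syllables has exactly 5 envelope bursts
  syl <- (0:4) / 7
  ev5 <- call_events(0, 4 / 7 + 0.045, "twitter", list(syl))
  w5 <- synthesize_call_waveform(ev5[1, ], fs, cfg)
  eb <- callcortex:::envelope_bursts(w5, fs)
  expect_equal(nrow(eb$bursts), 5)

  # phee instantaneous frequency drifts at the configured linear slope
  evp <- call_events(0, 2, "phee")
  wp <- synthesize_call_waveform(evp[1, ], fs, cfg)
  z <- analytic_signal(wp)
  fi <- diff(callcortex:::unwrap_phase(Arg(z))) * fs / (2 * pi)
  fi <- block_mean(fi, 4800)  # 10 Hz track
  t <- (seq_along(fi) - 0.5) / 10
  slope <- unname(stats::coef(stats::lm(fi ~ t))[2])
  expect_lt(abs(slope - cfg$phee_fm_slope_hz_per_s), 25)
  expect_gt(min(fi), 5000)  # fundamental above 5 kHz

  # aliasing guard
  expect_error(synthesize_call_waveform(evp[1, ], 8000, cfg), "liasing")
})

test_that("acoustic scenes apply the front gain to targets only", {
  cfg <- synth_config()
  fs <- cfg$sample_rate_hz
  # noise only: per-frame channel level difference about 0 dB
  sc0 <- generate_acoustic_scene(call_events(), call_events(), cfg,
                                 seed = 1, duration_s = 2)
  spec <- compute_spectrogram_pair(sc0)
  d <- channel_difference(spec)
  expect_lt(max(abs(d$frame_diff_db)), 3)

  # one target at 20 dB gain: in-call band energy ratio 20 +/- 1 dB
  ev <- call_events(0.5, 1.5, "phee")
  sc1 <- generate_acoustic_scene(ev, call_events(), cfg, seed = 2,
                                 duration_s = 2.5)
  band <- c(4000, 20000)
  inband <- function(x) sum(bandpass(x, fs, band)[
    round(0.6 * fs):round(1.4 * fs)]^2)
  ratio_db <- 10 * log10(inband(sc1$parabolic) / inband(sc1$reference))
  expect_lt(abs(ratio_db - 20), 1)

  # non-target only: difference within the noise floor during the call
  sc2 <- generate_acoustic_scene(call_events(), ev, cfg, seed = 3,
                                 duration_s = 2.5)
  d2 <- channel_difference(compute_spectrogram_pair(sc2))
  during <- d2$time_s > 0.6 & d2$time_s < 1.4
  expect_lt(max(abs(d2$frame_diff_db[during])), 3)

  # overlapping identical targets rejected
  bad <- call_events(c(0.5, 1.0), c(1.5, 2.0), c("phee", "phee"))
  expect_error(generate_acoustic_scene(bad, call_events(), cfg), "overlap")
})

test_that("adding a call raises scene energy by the call energy", {
  cfg <- synth_config(noise_rms = 0)
  ev <- call_events(0.5, 1.2, "trill")
  sc <- generate_acoustic_scene(ev, call_events(), cfg, seed = 1,
                                duration_s = 2)
  w <- synthesize_call_waveform(ev[1, ], cfg$sample_rate_hz, cfg)
  gain2 <- 10^(cfg$target_gain_db / 10)
  expect_equal(sum(sc$parabolic^2) + sum(sc$reference^2),
               (gain2 + 1) * sum(w^2), tolerance = 1e-10)
})

test_that("LFP generator: null config is flat, kappa -> Inf locks exactly", {
  ev <- spaced_events(12, "trill", spacing = 8)
  null_mod <- lapply(synth_config()$beta_mod, function(m)
    list(depth = 0, start = m$start))
  cfg <- synth_config(beta_mod = null_mod)
  lfp <- generate_lfp(ev, cfg, seed = 5, n_channels = 1)
  tp <- band_power_timecourse(lfp, ev, beta_band())
  wm <- mean(callcortex:::window_trial_means(tp, c(-0.1, 0.2)))
  expect_lt(abs(wm - 1), 0.25)

  expect_error(synth_config(beta_mod = list(phee = list(depth = 2,
                                                        start = 0))),
               "depth")

  # degenerate von Mises: all syllable-onset phases equal (the trough)
  ev2 <- phase_lock_events(6)
  cfg2 <- synth_config(theta_kappa = 1e9, theta_bg_rms_uv = 1e-6,
                       lfp_bg_rms_uv = 1e-6, beta_rms_uv = 1e-6)
  lfp2 <- generate_lfp(ev2, cfg2, seed = 6, n_channels = 1)
  pl <- phase_lock_site(lfp2, ev2)
  expect_gt(pl$vs, 0.995)
  expect_lt(abs(abs(pl$mean_phase) - pi), 0.1)
})

test_that("spike generator matches its rate law", {
  # null: homogeneous Poisson; ISIs pass an exponentiality check
  ev <- two_type_events(10)
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 5,
                      spike_gains = uniform_spike_gains())
  spk <- generate_spike_trains(ev, cfg, seed = 2, duration_s = 600)
  isi <- diff(spk$times[[1]])
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", 1 / mean(isi)))
  expect_gt(ks$p.value, 0.01)

  # pre-window gain 3 at baseline 5 Hz: empirical pre rate ~ 15 Hz
  g <- c(early = 1, pre = 3, during = 1, post = 1)
  cfg3 <- synth_config(n_units = 1, unit_baseline_hz = 5,
                       spike_gains = uniform_spike_gains(g))
  ev100 <- spaced_events(100, "trill", spacing = 10, start = 6)
  spk3 <- generate_spike_trains(ev100, cfg3, seed = 3)
  pre_counts <- vapply(ev100$onset_s, function(on)
    sum(spk3$times[[1]] >= on - 0.5 & spk3$times[[1]] < on), 0)
  rate <- mean(pre_counts) / 0.5
  se <- sqrt(15 / (100 * 0.5)) / sqrt(1)  # Poisson count oracle
  expect_lt(abs(rate - 15), 3 * sqrt(15 * 0.5 * 100) / (0.5 * 100))

  # silenced during-window
  g0 <- c(early = 1, pre = 1, during = 0, post = 1)
  cfg0 <- synth_config(n_units = 1, unit_baseline_hz = 5,
                       spike_gains = uniform_spike_gains(g0))
  spk0 <- generate_spike_trains(ev100, cfg0, seed = 4)
  inside <- unlist(lapply(seq_len(nrow(ev100)), function(i) {
    d <- ev100$offset_s[i] - ev100$onset_s[i]
    spk0$times[[1]] >= ev100$onset_s[i] &
      spk0$times[[1]] < ev100$onset_s[i] + 0.8 * d
  }))
  expect_equal(sum(inside), 0)
  expect_error(synth_config(spike_gains = uniform_spike_gains(
    c(early = -1, pre = 1, during = 1, post = 1))), "gains")
})

test_that("sync trains relate the two clocks by offset and drift", {
  s0 <- generate_sync(10, drift_ppm = 0, seed = 1, offset_s = 3)
  expect_length(s0$audio$times, 6)
  expect_equal(s0$neural$times - s0$audio$times, rep(3, 6))

  s1 <- generate_sync(3600, drift_ppm = 100, seed = 1, offset_s = 0)
  expect_equal(s1$neural$times[length(s1$neural$times)] -
                 s1$audio$times[length(s1$audio$times)],
               3600 * 100e-6, tolerance = 1e-9)

  # inversion oracle: align_clocks recovers offset and drift
  s2 <- generate_sync(600, drift_ppm = 80, seed = 7)
  cm <- align_clocks(s2$audio, s2$neural)
  expect_lt(abs(cm$to_neural(100) - (s2$neural$times[1] +
                                       100 * (1 + 80e-6))), 1e-3)
  expect_lt(abs(cm$drift * 1e6 - 80), 5)
})

test_that("identical (config, seed) give bit-identical outputs", {
  cfg <- synth_config()
  ev1 <- generate_call_sequence(cfg, 200, seed = 9)
  ev2 <- generate_call_sequence(cfg, 200, seed = 9)
  expect_identical(ev1, ev2)
  lf1 <- generate_lfp(ev1[1:min(3, nrow(ev1)), ], cfg, seed = 9,
                      n_channels = 1, duration_s = 40)
  lf2 <- generate_lfp(ev1[1:min(3, nrow(ev1)), ], cfg, seed = 9,
                      n_channels = 1, duration_s = 40)
  expect_identical(lf1$samples, lf2$samples)
  sp1 <- generate_spike_trains(ev1, cfg, seed = 9)
  sp2 <- generate_spike_trains(ev1, cfg, seed = 9)
  expect_identical(sp1$times, sp2$times)
})

test_that("annotations round-trip exactly through CSV", {
  ev <- generate_call_sequence(synth_config(), 300, seed = 13)
  expect_gt(nrow(ev), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ev, path)
  back <- read_annotations(path)
  expect_equal(back$onset_s, ev$onset_s, tolerance = 1e-6)
  expect_equal(back$call_type, ev$call_type)
  expect_equal(unlist(back$syllable_onsets_s),
               unlist(ev$syllable_onsets_s), tolerance = 1e-6)
})
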