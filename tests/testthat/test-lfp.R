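# LFP band-power analysis: normalization, bootstrap-SD criterion, window
# tests, start times, cross-type comparisons, profile embedding.

lfp_from_vector <- function(x, fs = 1000) {
  structure(list(samples = matrix(x, nrow = 1), sample_rate_hz = fs),
            class = "lfp_channels")
}

test_that("band power is baseline-normalized and scale-invariant", {
  ev <- spaced_events(15, "trill", spacing = 8)
  cfg <- synth_config()
  lfp <- generate_lfp(ev, cfg, seed = 31, n_channels = 1)
  tp <- band_power_timecourse(lfp, ev, beta_band())
  # baseline mean is 1 per trial by construction
  bm <- callcortex:::window_trial_means(tp, c(-3, -1))
  expect_equal(bm, rep(1, nrow(tp$power)), tolerance = 1e-12)
  # scaling the whole channel leaves the result unchanged
  lfp2 <- lfp
  lfp2$samples <- lfp2$samples * 37.5
  tp2 <- band_power_timecourse(lfp2, ev, beta_band())
  expect_equal(tp$power, tp2$power, tolerance = 1e-4)
  # trial averaging with n = 1 equals the single trial
  tp1 <- band_power_timecourse(lfp, ev[1, ], beta_band())
  expect_equal(nrow(tp1$power), 1)
  # short calls are excluded
  ev_short <- call_events(c(20, 60), c(20.15, 60.5), c("trill", "trill"))
  tps <- band_power_timecourse(lfp, ev_short, beta_band())
  expect_equal(nrow(tps$power), 1)
  expect_equal(tps$n_dropped, 1)
})

test_that("morlet TFR is flat on noise and localizes an injected burst", {
  fs <- 1000
  set.seed(5)
  x <- rnorm(120 * fs)
  on <- seq(8, 113, by = 5)
  lfp <- lfp_from_vector(x)
  ev <- call_events(on, on + 0.5, rep("trill", length(on)))
  tfr0 <- morlet_tfr(lfp, ev, freqs = c(10, 20, 30))
  expect_lt(mean(abs(tfr0$power - 1)), 0.25)
  expect_lt(max(abs(tfr0$power - 1)), 3)

  for (o in on) {
    idx <- round(o * fs):round((o + 0.5) * fs)
    x[idx] <- x[idx] + 1.5 * sin(2 * pi * 20 * idx / fs)
  }
  tfr <- morlet_tfr(lfp_from_vector(x), ev, freqs = c(10, 20, 30))
  post <- tfr$time_s > 0.1 & tfr$time_s < 0.4
  gain <- rowMeans(tfr$power[, post])
  expect_gt(gain[2], 10)
  expect_lt(gain[1], 3)
  expect_lt(gain[3], 3)
})

test_that("bootstrap baseline SD obeys its limits", {
  ev <- spaced_events(30, "trill", spacing = 8)
  # constant power: SD exactly 0
  tp <- structure(list(power = matrix(1, 30, 1400),
                       time_s = seq(-3.5, 3.5, length.out = 1400),
                       durations_s = rep(0.5, 30), baseline = c(-3, -1),
                       out_rate_hz = 200),
                  class = "trial_power")
  expect_equal(bootstrap_baseline_sd(tp, reps = 50, seed = 1), 0)

  # iid noise with abundant trials: SD scales ~ 1/sqrt(n_draw) (CLT
  # oracle; needs many distinct trials so resampling variance does not
  # saturate at the finite-sample average)
  set.seed(7)
  tpn <- tp
  tpn$power <- matrix(rnorm(2000 * 1400, 1, 0.5), 2000, 1400)
  tpn$durations_s <- rep(0.5, 2000)
  s50 <- bootstrap_baseline_sd(tpn, n_draw = 50, reps = 400, seed = 2)
  s200 <- bootstrap_baseline_sd(tpn, n_draw = 200, reps = 400, seed = 3)
  expect_equal(s50 / s200, 2, tolerance = 0.25)

  # determinism
  expect_identical(bootstrap_baseline_sd(tpn, reps = 100, seed = 9),
                   bootstrap_baseline_sd(tpn, reps = 100, seed = 9))
  # degenerate contract: baseline shorter than a segment
  tps <- tp
  tps$time_s <- seq(-0.05, 0.05, length.out = 1400)
  expect_error(bootstrap_baseline_sd(tps), "segment")
})

test_that("window modulation test detects suppression and self-compares null", {
  ev <- spaced_events(60, "trill", dur = 0.6, spacing = 8)
  cfg <- synth_config(beta_mod = list(
    phee = list(depth = 0.5, start = -0.6),
    trill = list(depth = 0.5, start = -0.5),
    twitter = list(depth = 0.4, start = -0.4),
    trillphee = list(depth = 0.45, start = 0.3),
    compound = list(depth = 0.4, start = -0.3)))
  lfp <- generate_lfp(ev, cfg, seed = 41, n_channels = 1)
  tp <- band_power_timecourse(lfp, ev, beta_band())
  sdb <- bootstrap_baseline_sd(tp, reps = 300, seed = 1)
  mt <- test_window_modulation(tp, c(-0.1, 0.2), sdb)
  expect_true(mt$significant)
  expect_equal(mt$direction, "suppression")
  # window == baseline: no direction, p near 1
  mt0 <- test_window_modulation(tp, c(-3, -1), sdb)
  expect_equal(mt0$direction, "none")
  expect_gt(mt0$p, 0.9)
  # degenerate input flagged
  tpc <- tp
  tpc$power <- matrix(1, nrow(tp$power), ncol(tp$power))
  mtd <- test_window_modulation(tpc, c(-0.1, 0.2), 0)
  expect_true(mtd$degenerate)

  # per-trial duration window
  mtdur <- test_window_modulation(tp, "duration", sdb)
  expect_equal(mtdur$direction, "suppression")
})

test_that("relative power recovery matches direct envelope arithmetic", {
  # dual route: the pipeline's measured window power vs the same ratio
  # computed straight from the raw band power of the identical recording
  ev <- spaced_events(200, "trill", dur = 0.6, spacing = 8)
  cfg <- synth_config()  # trill depth 0.3, start -0.3
  lfp <- generate_lfp(ev, cfg, seed = 43, n_channels = 1)
  tp <- band_power_timecourse(lfp, ev, beta_band())
  win <- c(0.1, 0.5)  # fully inside the suppressed span [-0.3, dur]
  measured <- mean(callcortex:::window_trial_means(tp, win))

  fs <- lfp$sample_rate_hz
  p_raw <- Mod(analytic_signal(bandpass(lfp$samples[1, ], fs,
                                        c(12, 30))))^2
  ratio <- vapply(ev$onset_s, function(on) {
    w <- mean(p_raw[round((on + win[1]) * fs):round((on + win[2]) * fs)])
    b <- mean(p_raw[round((on - 3) * fs):round((on - 1) * fs)])
    w / b
  }, 0)
  expect_equal(measured, mean(ratio), tolerance = 0.02)
  # the grand mean sits near the closed form 1 - depth; the mean of
  # per-trial ratios carries a small (+~3%) Jensen bias plus beta-band
  # sampling noise across the 200 suppressed windows
  expect_lt(abs(mean(ratio) - 0.7), 0.1)
})

test_that("start-time search finds a step suppression and respects nulls", {
  ev <- spaced_events(120, "trill", dur = 0.6, spacing = 8)
  cfg <- synth_config(beta_mod = list(
    phee = list(depth = 0.5, start = -0.6),
    trill = list(depth = 0.5, start = -0.5),
    twitter = list(depth = 0.4, start = -0.4),
    trillphee = list(depth = 0.45, start = 0.3),
    compound = list(depth = 0.4, start = -0.3)))
  lfp <- generate_lfp(ev, cfg, seed = 47, n_channels = 1)
  tp <- band_power_timecourse(lfp, ev, beta_band())
  sdb <- bootstrap_baseline_sd(tp, reps = 300, seed = 2)
  st <- find_modulation_start_time(tp, sdb, "suppression")
  expect_true(st$found)
  expect_gte(st$start_s, -0.55)
  expect_lte(st$start_s, -0.35)
})

test_that("cross-type comparison behaves under null, separation, shuffling", {
  set.seed(11)
  null_vals <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  res0 <- compare_across_call_types(null_vals)
  expect_gt(res0$omnibus_p, 0.001)

  sep <- list(a = rnorm(30, 0, 0.1), b = rnorm(30, 10, 0.1))
  res1 <- compare_across_call_types(sep)
  expect_lt(res1$omnibus_p, 1e-6)

  # permuting labels destroys significance
  pooled <- unlist(sep)
  perm <- sample(pooled)
  res2 <- compare_across_call_types(list(a = perm[1:30], b = perm[31:60]))
  expect_gt(res2$omnibus_p, 0.001)

  expect_error(compare_across_call_types(list(a = rnorm(5))), "2 call types")
})

test_that("beta-profile embedding separates constructed type templates", {
  set.seed(13)
  t10 <- seq(-1.5, 2.4, by = 0.1)
  templ <- list(a = 1 - 0.5 * exp(-(t10 - 0)^2 / 0.3),
                b = 1 - 0.5 * exp(-(t10 - 1)^2 / 0.3),
                c = 1 - 0.25 * exp(-(t10 + 0.5)^2 / 0.2))
  profiles <- do.call(rbind, lapply(rep(names(templ), each = 8),
                                    function(k) templ[[k]] +
                                      rnorm(length(t10), 0, 0.02)))
  labels <- rep(names(templ), each = 8)
  emb <- embed_beta_profiles(profiles, labels)
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_true(all(emb$explained >= 0 & emb$explained <= 1))
  wb <- within_between_distance(emb)
  # combinatorics: k types of m members -> k * m(m-1)/2 within pairs
  expect_equal(wb$n_within, 3 * choose(8, 2))
  expect_equal(wb$n_between, choose(24, 2) - 3 * choose(8, 2))
  expect_lt(mean(wb$within), mean(wb$between))
  expect_lt(wb$p, 1e-6)

  # duplicated profiles: zero within-type distance
  dup <- do.call(rbind, lapply(rep("a", 4), function(k) templ$a))
  emb2 <- embed_beta_profiles(rbind(dup, profiles[9:16, ]),
                              c(rep("a", 4), rep("b", 8)))
  d2 <- within_between_distance(emb2)
  expect_lt(min(d2$within), 1e-9)

  # labels shuffled: p no longer extreme
  set.seed(14)
  res_shuf <- within_between_distance(emb, sample(labels))
  expect_gt(res_shuf$p, 1e-4)

  expect_error(embed_beta_profiles(matrix(1, 5, 10), rep("a", 5)),
               "degenerate")
})

test_that("peak features recover magnitude and time of the extremum", {
  t <- seq(-3.5, 3.5, by = 0.005)
  v <- 1 - 0.4 * exp(-(t - 0.3)^2 / 0.05)
  tp <- structure(list(power = rbind(v, v), time_s = t,
                       durations_s = c(1, 1), baseline = c(-3, -1),
                       out_rate_hz = 200),
                  class = "trial_power")
  pk <- extract_peak_features(tp, "suppression")
  expect_equal(pk$peak_time_s, 0.3, tolerance = 0.01)
  expect_equal(pk$peak_magnitude, min(v), tolerance = 1e-9)

  # late vs early suppression orders the peak times
  v_late <- 1 - 0.4 * exp(-(t - 1.2)^2 / 0.05)
  tp$power <- rbind(v_late, v_late)
  pk_late <- extract_peak_features(tp, "suppression")
  expect_gt(pk_late$peak_time_s, pk$peak_time_s)

  tp$power <- matrix(1, 2, length(t))
  expect_true(extract_peak_features(tp, "suppression")$degenerate)
})
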