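# Single-neuron modulation: rasters, z-scored profiles, window tests,
# circular-shift shuffles, cross-type tallies.

test_that("raster building applies the exclusion rules", {
  ev <- two_type_events(12, types = c("trill", "trill"))
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 5,
                      spike_gains = uniform_spike_gains())
  spk <- generate_spike_trains(ev, cfg, seed = 61)
  # a 150 ms call is excluded
  ev2 <- ev
  ev2$offset_s[1] <- ev2$onset_s[1] + 0.15
  ra <- build_raster(spk, ev2, 1)
  expect_equal(length(ra$trials), nrow(ev) - 1)
  expect_equal(ra$n_excluded, 1)
  expect_true(ra$tested)

  # a silent unit yields empty rows, not missing trials
  spk0 <- spk
  spk0$times[[1]] <- numeric(0)
  ra0 <- build_raster(spk0, ev, 1)
  expect_equal(length(ra0$trials), nrow(ev))
  expect_true(all(vapply(ra0$trials, length, 0L) == 0))

  # translation invariance: shifting spikes and events together
  spk5 <- spk
  spk5$times[[1]] <- spk5$times[[1]] + 5
  spk5$duration_s <- spk$duration_s + 5
  ev5 <- ev
  ev5$onset_s <- ev$onset_s + 5
  ev5$offset_s <- ev$offset_s + 5
  ev5$syllable_onsets_s <- lapply(ev$syllable_onsets_s, `+`, 5)
  ra5 <- build_raster(spk5, ev5, 1)
  expect_equal(build_raster(spk, ev, 1)$trials, ra5$trials,
               tolerance = 1e-9)

  # under 15 surviving calls: not tested, not an error
  ra_small <- build_raster(spk, ev[1:10, ], 1)
  expect_false(ra_small$tested)
})

test_that("rate normalization is per-trial z with degeneracy flags", {
  ev <- two_type_events(10, types = c("trill", "trill"))
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 8,
                      spike_gains = uniform_spike_gains())
  spk <- generate_spike_trains(ev, cfg, seed = 62)
  ra <- build_raster(spk, ev, 1)
  prof <- normalize_rates(ra)
  expect_equal(rowMeans(prof$z), rep(0, nrow(prof$z)), tolerance = 1e-12)
  expect_equal(apply(prof$z, 1, stats::sd), rep(1, nrow(prof$z)),
               tolerance = 1e-9)

  # constant-rate trial (no spikes) gives an all-zero flagged row
  ra$trials[[1]] <- numeric(0)
  prof0 <- normalize_rates(ra)
  expect_true(all(prof0$z[1, ] == 0))
  expect_true(1 %in% prof0$degenerate_trials)

  # doubling the rate leaves z unchanged: duplicate every spike epsilon
  # apart, which doubles every bin count
  ra2 <- ra
  ra2$trials <- lapply(ra$trials, function(tr) sort(c(tr, tr + 1e-6)))
  expect_equal(normalize_rates(ra2)$z, prof0$z, tolerance = 1e-9)
})

test_that("window tests recover generated gains in the right windows", {
  ev <- spaced_events(50, "trill", dur = 1.0, spacing = 22, start = 12)
  g <- c(early = 1, pre = 3, during = 0.2, post = 1)
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 5,
                      spike_gains = uniform_spike_gains(g))
  spk <- generate_spike_trains(ev, cfg, seed = 63)
  prof <- normalize_rates(build_raster(spk, ev, 1))
  res <- test_spike_modulation(prof, n_boot = 500, seed = 64)
  w <- res$windows
  expect_true(w$significant[w$window == "pre"])
  expect_equal(w$direction[w$window == "pre"], "activated")
  expect_true(w$significant[w$window == "during"])
  expect_equal(w$direction[w$window == "during"], "suppressed")
  expect_true(res$modulated)
  # z elevated in the pre window on the trial average
  pre_idx <- prof$time_s >= -0.5 & prof$time_s < 0
  base_idx <- prof$time_s >= -8 & prof$time_s < -4
  expect_gt(mean(prof$z[, pre_idx]), mean(prof$z[, base_idx]) + 0.2)
})

test_that("results are invariant to trial order", {
  ev <- spaced_events(30, "trill", dur = 0.8, spacing = 22, start = 12)
  g <- c(early = 1, pre = 2, during = 1, post = 1)
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 5,
                      spike_gains = uniform_spike_gains(g))
  spk <- generate_spike_trains(ev, cfg, seed = 65)
  ra <- build_raster(spk, ev, 1)
  prof1 <- normalize_rates(ra)
  set.seed(1)
  perm <- sample(length(ra$trials))
  ra2 <- ra
  ra2$trials <- ra$trials[perm]
  ra2$durations_s <- ra$durations_s[perm]
  prof2 <- normalize_rates(ra2)
  r1 <- test_spike_modulation(prof1, n_boot = 400, seed = 66)
  r2 <- test_spike_modulation(prof2, n_boot = 400, seed = 66)
  expect_equal(r1$windows$significant, r2$windows$significant)
  expect_equal(r1$windows$direction, r2$windows$direction)
})

test_that("circular-shift shuffles restore the null and are reproducible", {
  ev <- spaced_events(40, "trill", dur = 1.0, spacing = 22, start = 12)
  g <- c(early = 1, pre = 3, during = 0.3, post = 1)
  cfg <- synth_config(n_units = 1, unit_baseline_hz = 5,
                      spike_gains = uniform_spike_gains(g))
  spk <- generate_spike_trains(ev, cfg, seed = 67)
  ra <- build_raster(spk, ev, 1)
  # the modulated unit itself flags strongly...
  res <- test_spike_modulation(normalize_rates(ra), n_boot = 300, seed = 1)
  expect_gte(mean(res$windows$significant), 0.5)
  # ...but shuffled proportions collapse toward the nominal level
  sh <- shuffle_control(ra, reps = 20, seed = 68, n_boot = 200)
  expect_lte(sh$prop_windows, 0.1)
  # fixed seed reproduces exactly
  sh2 <- shuffle_control(ra, reps = 20, seed = 68, n_boot = 200)
  expect_identical(sh$per_rep, sh2$per_rep)
  # a shift of exactly the span length is the identity
  tr <- ra$trials[[which.max(vapply(ra$trials, length, 0L))]]
  span <- ra$span
  shifted <- sort(((tr - span[1] + (span[2] - span[1])) %%
                     (span[2] - span[1])) + span[1])
  expect_equal(shifted, sort(tr), tolerance = 1e-9)
})

test_that("cross-type tallies reproduce the worked Venn arithmetic", {
  mk <- function(modulated, sig = "pre:activated", tested = TRUE) {
    w <- data.frame(window = c("early", "pre", "during", "post"),
                    significant = FALSE, direction = "none")
    if (modulated) {
      parts <- strsplit(sig, ":")[[1]]
      w$significant[w$window == parts[1]] <- TRUE
      w$direction[w$window == parts[1]] <- parts[2]
    }
    list(windows = w, modulated = modulated, tested = tested)
  }
  # 11 A-only, 9 B-only, 6 both of which 2 differ -> 22/26 = 85%
  a <- c(lapply(1:11, function(i) mk(TRUE)),          # A-only
         lapply(1:9, function(i) mk(FALSE)),          # B-only
         lapply(1:4, function(i) mk(TRUE)),           # both, same
         lapply(1:2, function(i) mk(TRUE)),           # both, different
         lapply(1:4, function(i) mk(FALSE)))          # neither
  b <- c(lapply(1:11, function(i) mk(FALSE)),
         lapply(1:9, function(i) mk(TRUE)),
         lapply(1:4, function(i) mk(TRUE)),
         lapply(1:2, function(i) mk(TRUE, "during:suppressed")),
         lapply(1:4, function(i) mk(FALSE)))
  tl <- tally_modulation(a, b)
  expect_equal(tl$modulated, 26)
  expect_equal(tl$different, 22)
  expect_equal(round(100 * tl$diff_proportion), 85)

  # 9 A-only, 11 B-only, 5 both of which 2 differ -> 22/25 = 88%
  a2 <- c(lapply(1:9, function(i) mk(TRUE)),
          lapply(1:11, function(i) mk(FALSE)),
          lapply(1:3, function(i) mk(TRUE)),
          lapply(1:2, function(i) mk(TRUE)))
  b2 <- c(lapply(1:9, function(i) mk(FALSE)),
          lapply(1:11, function(i) mk(TRUE)),
          lapply(1:3, function(i) mk(TRUE)),
          lapply(1:2, function(i) mk(TRUE, "post:activated")))
  tl2 <- tally_modulation(a2, b2)
  expect_equal(tl2$modulated, 25)
  expect_equal(round(100 * tl2$diff_proportion), 88)

  # all A-only: proportion 100%
  tl3 <- tally_modulation(lapply(1:5, function(i) mk(TRUE)),
                          lapply(1:5, function(i) mk(FALSE)))
  expect_equal(tl3$diff_proportion, 1)
  # zero modulated: flagged undefined
  tl0 <- tally_modulation(lapply(1:3, function(i) mk(FALSE)),
                          lapply(1:3, function(i) mk(FALSE)))
  expect_true(tl0$undefined)
  expect_true(is.na(tl0$diff_proportion))
})
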