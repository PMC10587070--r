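# Trial-aligned LFP band power: Morlet time-frequency maps, Hilbert band
# power at 200 Hz normalized to a [-3, -1] s baseline, the bootstrap-SD
# modulation criterion, modulation start times, cross-type comparisons, and
# the PCA embedding of beta temporal profiles.

#' Band definition
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low, high) {
  stopifnot(low > 0, low < high)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical bands: beta 12-30 Hz, theta 4-8 Hz, phase band 5-10 Hz
#' @rdname band_definition
#' @export
beta_band <- function() band_definition("beta", 12, 30)

#' @rdname band_definition
#' @export
theta_band <- function() band_definition("theta", 4, 8)

#' @rdname band_definition
#' @export
phase_band <- function() band_definition("phase", 5, 10)

#' Morlet time-frequency representation, baseline-normalized
#'
#' Width-7 complex Morlet wavelets (sd_t = width / (2 pi f)), convolved by
#' FFT over the whole channel; per-trial power epochs are averaged and each
#' frequency row is divided by its mean over the baseline window.
#'
#' @param lfp An `lfp_channels` object.
#' @param events `call_events`; trials without full epoch context are
#'   dropped (counted in `n_dropped`).
#' @param channel Channel index.
#' @param freqs Frequency grid (Hz).
#' @param epoch Epoch window (s, relative to onset), default `c(-3.5, 3.5)`.
#' @param baseline Baseline window, default `c(-3, -1)`.
#' @param width Wavelet width in cycles (default 7).
#' @return A `morlet_tfr`: `power` (freq x time, relative), `freqs`,
#'   `time_s`, `n_trials`, `n_dropped`.
#' @export
morlet_tfr <- function(lfp, events, channel = 1,
                       freqs = seq(4, 40, by = 2), epoch = c(-3.5, 3.5),
                       baseline = c(-3, -1), width = 7) {
  x <- lfp$samples[channel, ]
  fs <- lfp$sample_rate_hz
  n <- length(x)
  i_ep <- round(epoch[1] * fs):round(epoch[2] * fs)
  on_idx <- round(events$onset_s * fs) + 1
  ok <- on_idx + i_ep[1] >= 1 & on_idx + i_ep[length(i_ep)] <= n
  n_dropped <- sum(!ok)
  on_idx <- on_idx[ok]
  if (length(on_idx) == 0) stop("no events with full epoch context")
  # zero-pad to a smooth length covering the longest wavelet so the FFT
  # convolution is linear (no wrap-around) and fast
  nw_max <- 2 * ceiling(4 * width / (2 * pi * min(freqs)) * fs) + 1
  m <- stats::nextn(n + nw_max, c(2, 3, 5))
  Xf <- stats::fft(c(x, numeric(m - n)))
  pow <- matrix(0, nrow = length(freqs), ncol = length(i_ep))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sd_t <- width / (2 * pi * f)
    tw <- seq(-4 * sd_t, 4 * sd_t, by = 1 / fs)
    w <- exp(-tw^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * f * tw)
    w <- w / sum(abs(w))
    nw <- length(w)
    wf <- stats::fft(c(w, complex(real = numeric(m - nw))))
    conv <- stats::fft(Xf * wf, inverse = TRUE) / m
    p <- Mod(conv[seq_len(n) + floor(nw / 2)])^2  # center-aligned
    trials <- vapply(on_idx, function(i0) p[i0 + i_ep], numeric(length(i_ep)))
    pow[k, ] <- rowMeans(trials)
  }
  time_s <- i_ep / fs
  base <- time_s >= baseline[1] & time_s <= baseline[2]
  pow <- pow / rowMeans(pow[, base, drop = FALSE])
  structure(list(power = pow, freqs = freqs, time_s = time_s,
                 n_trials = length(on_idx), n_dropped = n_dropped),
            class = "morlet_tfr")
}

#' Trial-aligned, baseline-normalized band-power time courses
#'
#' Band-pass (zero-phase Butterworth), analytic amplitude by Hilbert
#' transform, squared to power, block-averaged down to 200 Hz, epoched
#' around each vocal onset, and divided per trial by the mean over the
#' `[-3, -1]` s baseline.  Calls shorter than `min_call_dur_s` (200 ms) and
#' calls without full epoch context are excluded.
#'
#' @param lfp An `lfp_channels` object.
#' @param events `call_events`.
#' @param band A [band_definition()] (e.g. [beta_band()]).
#' @param channel Channel index.
#' @param epoch Epoch window (s), default `c(-3.5, 3.5)`.
#' @param baseline Baseline window, default `c(-3, -1)`.
#' @param out_rate_hz Output rate (default 200).
#' @param min_call_dur_s Exclusion threshold on call duration (default 0.2).
#' @param trace Optional precomputed full-record power trace from
#'   [band_power_trace()] (lets several call types share one filtering
#'   pass over the same channel).
#' @return A `trial_power`: `power` (trials x time, relative, baseline
#'   mean 1 per trial), `time_s`, `durations_s`, `band`, `n_dropped`.
#' @export
band_power_timecourse <- function(lfp, events, band = beta_band(),
                                  channel = 1, epoch = c(-3.5, 3.5),
                                  baseline = c(-3, -1), out_rate_hz = 200,
                                  min_call_dur_s = 0.2, trace = NULL) {
  fs <- lfp$sample_rate_hz
  stopifnot(fs %% out_rate_hz == 0)
  p200 <- trace %||% band_power_trace(lfp, band, channel, out_rate_hz)
  durs <- events$offset_s - events$onset_s
  long_enough <- durs >= min_call_dur_s
  grid <- seq(round(epoch[1] * out_rate_hz), round(epoch[2] * out_rate_hz))
  on_bin <- round(events$onset_s * out_rate_hz)
  inside <- on_bin + grid[1] >= 1 & on_bin + grid[length(grid)] <= length(p200)
  keep <- long_enough & inside
  if (!any(keep)) stop("all trials excluded")
  mat <- t(vapply(on_bin[keep], function(b) p200[b + grid],
                  numeric(length(grid))))
  time_s <- grid / out_rate_hz
  base <- time_s >= baseline[1] & time_s <= baseline[2]
  mat <- mat / rowMeans(mat[, base, drop = FALSE])
  structure(list(power = mat, time_s = time_s,
                 durations_s = durs[keep], band = band,
                 baseline = baseline, out_rate_hz = out_rate_hz,
                 n_dropped = sum(!keep)),
            class = "trial_power")
}

#' Full-record band-power trace
#'
#' Band-pass, analytic amplitude squared, block-averaged to `out_rate_hz`.
#'
#' @inheritParams band_power_timecourse
#' @return Numeric power trace at `out_rate_hz`.
#' @export
band_power_trace <- function(lfp, band = beta_band(), channel = 1,
                             out_rate_hz = 200) {
  fs <- lfp$sample_rate_hz
  x <- lfp$samples[channel, ]
  p <- Mod(analytic_signal(bandpass(x, fs, c(band$low, band$high))))^2
  block_mean(p, fs / out_rate_hz)
}

#' Bootstrap standard deviation of baseline power
#'
#' Draws `n_draw` trials (without replacement when that many exist, with
#' replacement otherwise), averages their baseline traces, segments the
#' average into non-overlapping `segment_s` windows, and takes the SD of
#' the segment means; the mean SD over `reps` repetitions is returned.
#' This equalizes the criterion across call types with very different
#' trial counts.
#'
#' @param power A `trial_power` (or `norm_profile` for spikes).
#' @param n_draw Trials per draw (default 200).
#' @param segment_s Segment length (default 0.2 s).
#' @param reps Bootstrap repetitions (default 1000).
#' @param seed Integer seed.
#' @param baseline Baseline window; defaults to the object's.
#' @return Scalar SD (units of the trace).
#' @export
bootstrap_baseline_sd <- function(power, n_draw = 200, segment_s = 0.2,
                                  reps = 1000, seed = 1,
                                  baseline = power$baseline) {
  mat <- power_matrix(power)
  time_s <- power$time_s
  base_idx <- which(time_s >= baseline[1] & time_s <= baseline[2])
  rate <- 1 / (time_s[2] - time_s[1])
  seg_len <- round(segment_s * rate)
  if (length(base_idx) < seg_len) stop("baseline shorter than one segment")
  nseg <- floor(length(base_idx) / seg_len)
  base_idx <- base_idx[seq_len(nseg * seg_len)]
  bm <- mat[, base_idx, drop = FALSE]
  n <- nrow(bm)
  set.seed(substream_seed(seed, "bootsd"))
  sds <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n_draw, replace = n < n_draw)
    avg <- colMeans(bm[idx, , drop = FALSE])
    stats::sd(block_mean(avg, seg_len))
  }, 0)
  mean(sds)
}

power_matrix <- function(power) {
  if (inherits(power, "trial_power")) power$power
  else if (inherits(power, "norm_profile")) power$z
  else stop("unsupported power object")
}

# Per-trial mean of the trace within a window; `window` is c(lo, hi) or
# "duration" for the per-trial (0, duration) window.
window_trial_means <- function(power, window) {
  mat <- power_matrix(power)
  time_s <- power$time_s
  if (identical(window, "duration")) {
    durs <- power$durations_s
    vapply(seq_len(nrow(mat)), function(i) {
      idx <- time_s >= 0 & time_s <= durs[i]
      mean(mat[i, idx])
    }, 0)
  } else {
    idx <- time_s >= window[1] & time_s <= window[2]
    if (!any(idx)) stop("window outside the time axis")
    rowMeans(mat[, idx, drop = FALSE])
  }
}

#' Test band-power modulation in an analysis window
#'
#' A site is significantly modulated when (a) the per-trial window means
#' differ from the per-trial baseline means by a two-sided signed-rank test
#' and (b) the trial-averaged window mean is more than `n_sd` bootstrap
#' standard deviations away from the trial-averaged baseline mean.
#' Direction is the sign of the median paired difference.
#'
#' @param power A `trial_power` (or spike `norm_profile`).
#' @param window `c(lo, hi)` seconds, or `"duration"` for the per-trial
#'   call-duration window.
#' @param sd Bootstrap baseline SD from [bootstrap_baseline_sd()].
#' @param baseline Baseline window; defaults to the object's.
#' @param alpha Significance level (default 0.05).
#' @param n_sd SD multiple (default 2).
#' @return A `modulation_test` list: `median_power`, `p`, `passes_2sd`,
#'   `significant`, `direction` ("suppression"/"activation"/"none"),
#'   `degenerate`.
#' @export
test_window_modulation <- function(power, window, sd,
                                   baseline = power$baseline,
                                   alpha = 0.05, n_sd = 2) {
  wm <- window_trial_means(power, window)
  bm <- window_trial_means(power, baseline)
  d <- wm - bm
  # zero-variance input (a constant power matrix) leaves p undefined;
  # identical windows on varying data are evidence of no difference (p = 1)
  zero_diff <- all(abs(d) < 1e-12)
  degenerate <- length(d) < 2 ||
    (zero_diff && stats::sd(as.vector(power_matrix(power))) < 1e-12)
  p <- if (degenerate) NA_real_
       else if (zero_diff) 1
       else suppressWarnings(stats::wilcox.test(wm, bm, paired = TRUE,
                                                exact = FALSE)$p.value)
  gap <- mean(wm) - mean(bm)
  passes_2sd <- is.finite(sd) && sd > 0 && abs(gap) > n_sd * sd
  significant <- !degenerate && !is.na(p) && p < alpha && passes_2sd
  direction <- if (!significant) "none"
               else if (stats::median(d) < 0) "suppression" else "activation"
  structure(list(window = window, median_power = stats::median(wm),
                 mean_gap = gap, p = p, sd = sd, passes_2sd = passes_2sd,
                 significant = significant, direction = direction,
                 degenerate = degenerate, n = length(wm)),
            class = "modulation_test")
}

#' Find the modulation start time
#'
#' Slides a 100 ms window in 5 ms steps over the union of the analysis
#' windows ([-0.5, 0], [-0.1, 0.2], the call duration, [0.3, 0.9]) and
#' returns the midpoint of the earliest window that is signed-rank
#' significant, beyond `n_sd` bootstrap SDs, and modulated in the given
#' direction.
#'
#' @param power A `trial_power` or `norm_profile`.
#' @param sd Bootstrap baseline SD.
#' @param direction `"suppression"` or `"activation"` (from
#'   [test_window_modulation()]).
#' @param win_len_s Sliding window length (default 0.1).
#' @param step_s Step (default 0.005, one sample at 200 Hz).
#' @param search Search span; default `[-0.5, max(0.9, median duration)]`.
#' @param alpha Significance level.
#' @param n_sd SD multiple.
#' @return A `start_time` list: `start_s` (window midpoint), `direction`,
#'   `found`.
#' @export
find_modulation_start_time <- function(power, sd, direction,
                                       win_len_s = 0.1, step_s = 0.005,
                                       search = NULL, alpha = 0.05,
                                       n_sd = 2) {
  stopifnot(direction %in% c("suppression", "activation"))
  med_dur <- stats::median(power$durations_s %||% 0.9)
  search <- search %||% c(-0.5, max(0.9, med_dur))
  bm <- window_trial_means(power, power$baseline)
  mat <- power_matrix(power)
  time_s <- power$time_s
  lo_grid <- seq(search[1], search[2] - win_len_s, by = step_s)
  want_sign <- if (direction == "suppression") -1 else 1
  for (lo in lo_grid) {
    idx <- time_s >= lo & time_s <= lo + win_len_s
    wm <- rowMeans(mat[, idx, drop = FALSE])
    gap <- mean(wm) - mean(bm)
    if (sign(gap) != want_sign || abs(gap) <= n_sd * sd) next
    p <- suppressWarnings(stats::wilcox.test(wm, bm, paired = TRUE,
                                             exact = FALSE)$p.value)
    if (!is.na(p) && p < alpha) {
      return(structure(list(start_s = lo + win_len_s / 2,
                            direction = direction, found = TRUE),
                       class = "start_time"))
    }
  }
  structure(list(start_s = NA_real_, direction = direction, found = FALSE),
            class = "start_time")
}

#' Compare a quantity across call types
#'
#' Kruskal-Wallis omnibus test plus Bonferroni-adjusted pairwise two-sided
#' rank-sum comparisons.
#'
#' @param values_by_type Named list (>= 2 types, >= 2 values each) of
#'   numeric vectors (e.g. per-site window powers or start times).
#' @return List with `omnibus_p`, `statistic`, and `pairwise` (data frame
#'   `type_a`, `type_b`, `p_adj`).
#' @export
compare_across_call_types <- function(values_by_type) {
  if (length(values_by_type) < 2) stop("need at least 2 call types")
  if (any(vapply(values_by_type, length, 0L) < 2)) {
    stop("each type needs at least 2 values")
  }
  kw <- stats::kruskal.test(values_by_type)
  x <- unlist(values_by_type, use.names = FALSE)
  g <- factor(rep(names(values_by_type),
                  vapply(values_by_type, length, 0L)))
  pw <- stats::pairwise.wilcox.test(x, g, p.adjust.method = "bonferroni",
                                    exact = FALSE)
  m <- pw$p.value
  pairs <- which(!is.na(m), arr.ind = TRUE)
  list(omnibus_p = kw$p.value, statistic = unname(kw$statistic),
       pairwise = data.frame(type_a = rownames(m)[pairs[, 1]],
                             type_b = colnames(m)[pairs[, 2]],
                             p_adj = m[pairs]))
}

#' Mean beta temporal profile of a site/type
#'
#' The trial-averaged relative power restricted to the profile window,
#' block-averaged down to `out_rate_hz`.
#'
#' @param power A `trial_power`.
#' @param window Profile window (default `c(-1.5, 2.5)` s).
#' @param out_rate_hz Profile rate (default 10 Hz).
#' @return Numeric profile vector.
#' @export
beta_profile <- function(power, window = c(-1.5, 2.5), out_rate_hz = 10) {
  idx <- power$time_s >= window[1] & power$time_s < window[2]
  avg <- colMeans(power$power[, idx, drop = FALSE])
  block_mean(avg, round(power$out_rate_hz / out_rate_hz))
}

#' Embed beta temporal profiles in principal-component space
#'
#' Pools the per-(site, type) profiles, performs PCA, and retains the
#' first three components.
#'
#' @param profiles Matrix (rows = site x type profiles) or list of equal
#'   length profile vectors (>= 4).
#' @param labels Call-type label per profile.
#' @return A `beta_embedding`: `scores` (n x 3), `explained` (variance
#'   fractions, length 3), `labels`.
#' @export
embed_beta_profiles <- function(profiles, labels) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  stopifnot(nrow(profiles) >= 4, length(labels) == nrow(profiles))
  if (all(apply(profiles, 2, stats::sd) < 1e-12)) {
    stop("degenerate (constant) profiles")
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = ev[seq_len(k)], labels = labels),
            class = "beta_embedding")
}

#' Within- vs between-type distances in the embedding
#'
#' All pairwise Euclidean distances between projected profiles are
#' partitioned by whether the pair shares a call type; the two sets are
#' compared with a two-sided rank-sum test.
#'
#' @param embedding A `beta_embedding` (or a score matrix).
#' @param labels Labels (defaults to the embedding's).
#' @return List with `within`, `between` (distance vectors), `p`
#'   (rank-sum), and counts.
#' @export
within_between_distance <- function(embedding, labels = NULL) {
  scores <- if (inherits(embedding, "beta_embedding")) embedding$scores
            else embedding
  labels <- labels %||% embedding$labels
  stopifnot(length(unique(labels)) >= 2)
  d <- as.matrix(stats::dist(scores))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  singles <- names(which(table(labels) == 1))
  if (length(singles)) {
    message("types with a single member contribute no within pairs: ",
            paste(singles, collapse = ", "))
  }
  p <- if (length(within) >= 1 && length(between) >= 1) {
    suppressWarnings(stats::wilcox.test(within, between,
                                        exact = FALSE)$p.value)
  } else NA_real_
  list(within = within, between = between, p = p,
       n_within = length(within), n_between = length(between))
}

#' Peak modulation magnitude and time
#'
#' The extremum of the trial-averaged relative power within the profile
#' window: the minimum for suppression, the maximum for activation.
#'
#' @param power A `trial_power`.
#' @param direction `"suppression"` or `"activation"`.
#' @param window Search window (default `c(-1.5, 2.5)` s).
#' @return List with `peak_magnitude`, `peak_time_s`, `degenerate`.
#' @export
extract_peak_features <- function(power, direction = "suppression",
                                  window = c(-1.5, 2.5)) {
  idx <- which(power$time_s >= window[1] & power$time_s <= window[2])
  avg <- colMeans(power$power[, idx, drop = FALSE])
  degenerate <- stats::sd(avg) < 1e-12
  k <- if (direction == "suppression") which.min(avg) else which.max(avg)
  list(peak_magnitude = avg[k], peak_time_s = power$time_s[idx[k]],
       degenerate = degenerate)
}
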