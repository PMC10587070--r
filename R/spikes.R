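# Single-neuron peri-call modulation: rasters, per-trial z-scored rate
# profiles, the signed-rank + bootstrap-2SD window test, circular-shift
# shuffle controls, and cross-type modulation tallies.

#' Build a peri-event spike raster
#'
#' Spike times re-referenced to each vocal onset over `span` (default
#' `[-10, 10]` s).  Calls shorter than 200 ms and calls whose span leaves
#' the recording are excluded; a unit is `tested` only with >= `min_calls`
#' surviving calls.
#'
#' @param spikes A `spike_trains` object.
#' @param events `call_events`, sorted.
#' @param unit Unit index.
#' @param span Peri-event span (s).
#' @param min_call_dur_s Call-duration exclusion threshold (default 0.2).
#' @param min_calls Tested threshold (default 15).
#' @return A `spike_raster`: `trials` (list of relative spike-time
#'   vectors), `durations_s`, `span`, `tested`, `n_excluded`.
#' @export
build_raster <- function(spikes, events, unit = 1, span = c(-10, 10),
                         min_call_dur_s = 0.2, min_calls = 15) {
  st <- spikes$times[[unit]]
  durs <- events$offset_s - events$onset_s
  rec_end <- spikes$duration_s
  ok <- durs >= min_call_dur_s & events$onset_s + span[1] >= 0
  if (is.finite(rec_end %||% NA)) {
    ok <- ok & events$onset_s + span[2] <= rec_end
  }
  trials <- lapply(events$onset_s[ok], function(on) {
    rel <- st - on
    rel[rel >= span[1] & rel < span[2]]
  })
  structure(list(trials = trials, durations_s = durs[ok], span = span,
                 tested = sum(ok) >= min_calls, n_excluded = sum(!ok)),
            class = "spike_raster")
}

#' Normalize a raster to per-trial z-scored rates
#'
#' Rates in 50 ms bins over the 20 s span centered at vocal onset,
#' standardized per trial; zero-variance (e.g. silent) trials get z = 0
#' and are flagged.
#'
#' @param raster A `spike_raster`.
#' @param bin_s Bin width (default 0.05 s).
#' @return A `norm_profile`: `z` (trials x bins), `time_s` (bin centers),
#'   `durations_s`, `baseline` (`c(-8, -4)`), `degenerate_trials`.
#' @export
normalize_rates <- function(raster, bin_s = 0.05) {
  if (length(raster$trials) == 0) stop("empty raster")
  span <- raster$span
  breaks <- seq(span[1], span[2], by = bin_s)
  centers <- breaks[-length(breaks)] + bin_s / 2
  counts <- t(vapply(raster$trials, function(tr) {
    hist(tr, breaks = breaks, plot = FALSE)$counts
  }, numeric(length(centers))))
  rates <- counts / bin_s
  mu <- rowMeans(rates)
  sdv <- apply(rates, 1, stats::sd)
  degenerate <- sdv < 1e-12
  z <- (rates - mu) / ifelse(degenerate, 1, sdv)
  z[degenerate, ] <- 0
  structure(list(z = z, time_s = centers, durations_s = raster$durations_s,
                 baseline = c(-8, -4), bin_s = bin_s,
                 degenerate_trials = which(degenerate)),
            class = "norm_profile")
}

# Per-trial mean z within a possibly per-trial window.
spike_window_means <- function(profile, window) {
  if (is.character(window)) {
    vapply(seq_len(nrow(profile$z)), function(i) {
      w <- spike_windows(profile$durations_s[i])[window, ]
      idx <- profile$time_s >= w[1] & profile$time_s < w[2]
      mean(profile$z[i, idx])
    }, 0)
  } else {
    idx <- profile$time_s >= window[1] & profile$time_s < window[2]
    if (!any(idx)) stop("window outside the raster span")
    rowMeans(profile$z[, idx, drop = FALSE])
  }
}

#' Test firing-rate modulation in the four peri-call windows
#'
#' Per window (early, pre, during, post): two-sided signed-rank test of
#' per-trial window means against per-trial baseline (`[-8, -4]` s) means,
#' plus the bootstrap-SD criterion (500 ms segments, draws capped at the
#' available trial count) on the trial-averaged trace.  Direction follows
#' the sign of the median paired difference.
#'
#' @param profile A `norm_profile`.
#' @param windows Window names (default all four).
#' @param n_boot Bootstrap repetitions for the SD (default 1000).
#' @param seed Seed for the bootstrap.
#' @param alpha Significance level (default 0.05).
#' @param tested Tested flag carried from the raster (default TRUE).
#' @return A `neuron_modulation`: data frame `windows` (window, p,
#'   passes_2sd, significant, direction), plus `modulated`, `tested`, `sd`.
#' @export
test_spike_modulation <- function(profile,
                                  windows = c("early", "pre", "during",
                                              "post"),
                                  n_boot = 1000, seed = 1, alpha = 0.05,
                                  tested = TRUE) {
  n <- nrow(profile$z)
  sd_b <- bootstrap_baseline_sd(profile, n_draw = n, segment_s = 0.5,
                                reps = n_boot, seed = seed)
  bm <- spike_window_means(profile, profile$baseline)
  rows <- lapply(windows, function(w) {
    wm <- spike_window_means(profile, w)
    d <- wm - bm
    degenerate <- all(abs(d) < 1e-12)
    p <- if (degenerate) NA_real_ else
      suppressWarnings(stats::wilcox.test(wm, bm, paired = TRUE,
                                          exact = FALSE)$p.value)
    gap <- mean(wm) - mean(bm)
    passes <- is.finite(sd_b) && sd_b > 0 && abs(gap) > 2 * sd_b
    sig <- !degenerate && !is.na(p) && p < alpha && passes
    data.frame(window = w, p = p, mean_gap = gap, passes_2sd = passes,
               significant = sig,
               direction = if (!sig) "none"
                           else if (stats::median(d) < 0) "suppressed"
                           else "activated")
  })
  tab <- do.call(rbind, rows)
  structure(list(windows = tab, modulated = any(tab$significant),
                 tested = tested, sd = sd_b, n_trials = n),
            class = "neuron_modulation")
}

#' Circular-shift shuffle control
#'
#' Per repetition, every trial's spikes are circularly shifted by an
#' independent uniform offset over the raster span, the normalization and
#' the full window test are re-run, and the proportion of flagged windows
#' is recorded; the mean proportion over repetitions estimates the null
#' rate of the combined criterion.
#'
#' @param raster A `spike_raster`.
#' @param reps Shuffle repetitions (default 100).
#' @param seed Seed.
#' @param n_boot Bootstrap repetitions inside each re-test (default 200;
#'   the criterion SD stabilizes quickly at raster-sized draws).
#' @param alpha Significance level.
#' @return List with `prop_windows` (mean proportion of significant
#'   windows), `prop_modulated` (mean proportion of reps with any
#'   significant window), `per_rep`.
#' @export
shuffle_control <- function(raster, reps = 100, seed = 1, n_boot = 200,
                            alpha = 0.05) {
  if (length(raster$trials) == 0) stop("empty raster")
  span <- raster$span
  len <- span[2] - span[1]
  set.seed(substream_seed(seed, "shuffle"))
  per_rep <- vapply(seq_len(reps), function(r) {
    sh <- raster
    sh$trials <- lapply(raster$trials, function(tr) {
      off <- stats::runif(1, 0, len)
      sort(((tr - span[1] + off) %% len) + span[1])
    })
    prof <- normalize_rates(sh)
    res <- test_spike_modulation(prof, n_boot = n_boot,
                                 seed = seed + r, alpha = alpha)
    mean(res$windows$significant)
  }, 0)
  list(prop_windows = mean(per_rep), prop_modulated = mean(per_rep > 0),
       per_rep = per_rep)
}

#' Tally cross-type modulation of a neuron population
#'
#' For neurons tested on both call types, counts A-only, B-only,
#' both-with-same and both-with-different modulation; "different" means a
#' differing direction in any window or a differing set of significant
#' windows.  The difference proportion is
#' `(A_only + B_only + both_different) / modulated`.
#'
#' @param profiles_a,profiles_b Lists of `neuron_modulation` objects, one
#'   per neuron, aligned.
#' @return List of Venn counts, `modulated`, `diff_proportion` (NA with a
#'   flag when no neuron is modulated).
#' @export
tally_modulation <- function(profiles_a, profiles_b) {
  stopifnot(length(profiles_a) == length(profiles_b))
  keep <- vapply(profiles_a, `[[`, TRUE, "tested") &
          vapply(profiles_b, `[[`, TRUE, "tested")
  a_mod <- vapply(profiles_a, `[[`, TRUE, "modulated") & keep
  b_mod <- vapply(profiles_b, `[[`, TRUE, "modulated") & keep
  sig_set <- function(p) {
    w <- p$windows
    paste(w$window[w$significant], w$direction[w$significant],
          collapse = ";")
  }
  both <- which(a_mod & b_mod)
  both_diff <- sum(vapply(both, function(i) {
    sig_set(profiles_a[[i]]) != sig_set(profiles_b[[i]])
  }, TRUE))
  a_only <- sum(a_mod & !b_mod)
  b_only <- sum(b_mod & !a_mod)
  modulated <- sum(a_mod | b_mod)
  diff_n <- a_only + b_only + both_diff
  list(n_tested = sum(keep), a_only = a_only, b_only = b_only,
       both = length(both), both_different = both_diff,
       both_same = length(both) - both_diff, modulated = modulated,
       different = diff_n,
       diff_proportion = if (modulated > 0) diff_n / modulated else NA_real_,
       undefined = modulated == 0)
}
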