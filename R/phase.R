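# Theta phase locking of call syllables: instantaneous phase of the
# 5-10 Hz filtered LFP, phases at syllable onsets, vector strength, and the
# Rayleigh test of circular uniformity.

#' Instantaneous phase of a band-limited LFP channel
#'
#' Zero-phase band-pass followed by the analytic-signal angle, wrapped to
#' `[-pi, pi)`.  Cosine convention: phase 0 at peaks, `pi` at troughs.
#'
#' @param x Numeric LFP trace (uV) or an `lfp_channels` object.
#' @param fs Sampling rate (ignored when `x` is `lfp_channels`).
#' @param band Analysis band (default `c(5, 10)` Hz, centered on the
#'   twitter syllable repetition rate).
#' @param channel Channel index when `x` is `lfp_channels`.
#' @return Phase time course (radians).
#' @export
instantaneous_phase <- function(x, fs = NULL, band = c(5, 10), channel = 1) {
  if (inherits(x, "lfp_channels")) {
    fs <- x$sample_rate_hz
    x <- x$samples[channel, ]
  }
  stopifnot(!is.null(fs))
  if (band[2] >= fs / 2) stop("band above Nyquist")
  wrap_phase(Arg(analytic_signal(bandpass(x, fs, band))))
}

#' Extract phases at syllable onsets
#'
#' Nearest-sample phase for each onset; onsets outside the recording are
#' dropped with a message.
#'
#' @param phase Phase time course from [instantaneous_phase()].
#' @param fs Sampling rate of `phase`.
#' @param onsets_s Syllable onset times (s).
#' @return A `syllable_phases` object (numeric vector of wrapped phases).
#' @export
phases_at_onsets <- function(phase, fs, onsets_s) {
  if (length(onsets_s) == 0) {
    return(structure(numeric(0), class = "syllable_phases"))
  }
  idx <- round(onsets_s * fs) + 1
  ok <- idx >= 1 & idx <= length(phase)
  if (any(!ok)) message(sum(!ok), " onsets outside the recording dropped")
  structure(phase[idx[ok]], class = "syllable_phases")
}

#' Vector strength
#'
#' Mean resultant length of the unit phasors `exp(i phi)`: 1 for perfect
#' locking, 0 for circular uniformity.
#'
#' @param phases Numeric phases (radians), `n >= 1`.
#' @return Scalar in `[0, 1]`.
#' @export
vector_strength <- function(phases) {
  phases <- unclass(phases)
  if (length(phases) == 0) stop("vector strength undefined for n = 0")
  Mod(mean(exp(1i * phases)))
}

#' Circular mean phase
#' @param phases Numeric phases (radians).
#' @return Mean direction in `[-pi, pi)`.
#' @export
mean_phase <- function(phases) {
  wrap_phase(Arg(mean(exp(1i * unclass(phases)))))
}

#' Rayleigh test of circular uniformity
#'
#' Statistic `2 n VS^2`, asymptotically chi-squared with 2 df under the
#' null, so the p = 0.001 critical value is 13.8.  The returned p-value
#' applies the standard small-sample series correction in `Z = n VS^2`
#' (`exp(-Z) (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`),
#' which converges to the chi-squared tail as n grows.
#'
#' @param phases Numeric phases, `n >= 2`.
#' @return A `rayleigh_test` list: `statistic`, `p`, `vs`, `n`,
#'   `mean_phase`.
#' @export
rayleigh_test <- function(phases) {
  phases <- unclass(phases)
  n <- length(phases)
  if (n < 2) stop("Rayleigh test needs n >= 2")
  vs <- vector_strength(phases)
  Z <- n * vs^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  structure(list(statistic = 2 * Z, p = min(max(p, 0), 1), vs = vs, n = n,
                 mean_phase = mean_phase(phases)),
            class = "rayleigh_test")
}

#' Rayleigh significance threshold
#'
#' The critical value of the `2 n VS^2` statistic at level `alpha` under
#' its chi-squared(2 df) null.
#'
#' @param alpha Significance level (default 0.001).
#' @return Scalar critical value (13.8 at `alpha = 0.001`, to one decimal).
#' @export
rayleigh_critical <- function(alpha = 0.001) {
  stats::qchisq(1 - alpha, df = 2)
}

#' Phase histogram
#'
#' Counts of phases in `n_bins` equal bins over `[-pi, pi)` (default 18
#' bins of 20 degrees).
#'
#' @param phases Numeric phases.
#' @param n_bins Number of bins.
#' @return Data frame with `bin_center_rad`, `count`.
#' @export
phase_histogram <- function(phases, n_bins = 18) {
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  h <- hist(wrap_phase(unclass(phases)), breaks = breaks, plot = FALSE)
  data.frame(bin_center_rad = h$mids, count = h$counts)
}

#' Phase locking of a call set at one site
#'
#' Convenience wrapper: instantaneous phase of the band-limited channel,
#' phases at all syllable onsets of the given events, vector strength and
#' Rayleigh test.
#'
#' @param lfp An `lfp_channels` object.
#' @param events `call_events` whose syllable onsets are pooled.
#' @param channel Channel index.
#' @param band Analysis band (default `c(5, 10)` Hz).
#' @param drop_first Drop the first syllable of each call (which defines
#'   t = 0)?  Default FALSE: all syllables enter.
#' @return A `rayleigh_test` augmented with `phases`.
#' @export
phase_lock_site <- function(lfp, events, channel = 1, band = c(5, 10),
                            drop_first = FALSE) {
  ph <- instantaneous_phase(lfp, band = band, channel = channel)
  onsets <- unlist(lapply(events$syllable_onsets_s, function(s) {
    if (drop_first) s[-1] else s
  }))
  phases <- phases_at_onsets(ph, lfp$sample_rate_hz, onsets)
  out <- rayleigh_test(phases)
  out$phases <- phases
  out
}
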