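# Synthetic vocal behavior: Poisson call sequences, FM call waveforms, and
# two-channel (parabolic/reference) acoustic scenes with a configurable
# front gain on target calls.

#' Generate a sequence of call events
#'
#' Each call type arrives as an independent Poisson process at its
#' configured rate; per-call durations are uniform over the type's range.
#' Target events never overlap one another: the event count is drawn first
#' (so counts stay exactly Poisson) and onsets are then placed by rejection
#' against already-occupied intervals.
#'
#' Twitter calls carry syllables repeating at the configured rate (~7 Hz)
#' with small Gaussian timing jitter; compound calls carry 2+ heterogeneous
#' syllables; other types are single-syllable.
#'
#' @param config A [synth_config()].
#' @param duration_s Scene duration (s), `> 0`.
#' @param seed Integer seed.
#' @return A `call_events` table sorted by onset.
#' @export
generate_call_sequence <- function(config, duration_s, seed = config$seed) {
  validate_synth_config(config)
  if (duration_s <= 0) stop("duration_s must be > 0")
  set.seed(substream_seed(seed, "calls"))
  edge <- 0.5
  occupied <- matrix(numeric(0), ncol = 2)
  rows <- list()
  for (ty in CALL_TYPES) {
    rate <- config$call_rates_per_min[[ty]]
    if (rate <= 0) next
    n <- stats::rpois(1, rate * duration_s / 60)
    if (n == 0) next
    rng <- config$duration_range_s[[ty]]
    durs <- stats::runif(n, rng[1], rng[2])
    for (d in durs) {
      placed <- FALSE
      hi <- duration_s - edge - d
      if (hi <= edge) next
      for (try in 1:1000) {
        on <- stats::runif(1, edge, hi)
        if (nrow(occupied) == 0 ||
            all(on + d + config$min_call_gap_s < occupied[, 1] |
                on > occupied[, 2] + config$min_call_gap_s)) {
          occupied <- rbind(occupied, c(on, on + d))
          rows[[length(rows) + 1]] <-
            list(onset = on, offset = on + d, type = ty)
          placed <- TRUE
          break
        }
      }
      if (!placed) warning("could not place a ", ty,
                           " call without overlap; dropped")
    }
  }
  if (length(rows) == 0) return(call_events())
  onset <- vapply(rows, `[[`, 0, "onset")
  offset <- vapply(rows, `[[`, 0, "offset")
  type <- vapply(rows, `[[`, "", "type")
  syl <- mapply(function(on, off, ty) {
    syllable_times(on, off, ty, config)
  }, onset, offset, type, SIMPLIFY = FALSE)
  # the annotated offset is the acoustic end of the call: for twitter the
  # end of the last syllable sweep, not the nominal drawn duration
  tw <- type == "twitter"
  offset[tw] <- vapply(syl[tw], max, 0) + config$twitter_syllable_duty_s
  ord <- order(onset)
  call_events(onset[ord], offset[ord], type[ord], syl[ord], is_target = TRUE)
}

# Syllable onset times for one call (absolute seconds).  The first syllable
# defines the vocal onset and is never jittered.
syllable_times <- function(onset, offset, type, config) {
  dur <- offset - onset
  if (type == "twitter") {
    rate <- config$twitter_syllable_rate_hz
    k <- max(3, round(dur * rate))
    t <- onset + (seq_len(k) - 1) / rate
    if (config$twitter_syllable_jitter_s > 0 && k > 1) {
      t[-1] <- t[-1] + stats::rnorm(k - 1, 0, config$twitter_syllable_jitter_s)
      t <- c(t[1], sort(pmin(pmax(t[-1], onset), offset - 1e-3)))
    }
    t[t <= offset]
  } else if (type == "compound") {
    # heterogeneous elements of >= ~0.3 s each, always 3+
    k <- max(3, min(3 + stats::rpois(1, 0.7), floor(dur / 0.3)))
    gap <- dur / k
    onset + (seq_len(k) - 1) * gap
  } else {
    onset
  }
}

#' Synthesize the waveform of one call
#'
#' Phase-accumulation FM synthesis.  Per type: phee = slow linear FM; trill
#' = sinusoidal FM; trillphee = sinusoidal FM decaying to a phee-like second
#' half; twitter = short upward sweeps at the syllable onsets separated by
#' silence; compound = alternating trill-like and phee-like elements at the
#' syllable onsets.  All fundamentals sit above 5 kHz.
#'
#' @param event One-row `call_events` slice (or list with `onset_s`,
#'   `offset_s`, `call_type`, `syllable_onsets_s`).
#' @param sample_rate_hz Output rate; must exceed twice the maximum
#'   instantaneous frequency.
#' @param config A [synth_config()].
#' @return Numeric waveform of length `round(duration * sample_rate_hz)`.
#' @export
synthesize_call_waveform <- function(event, sample_rate_hz, config) {
  ty <- as.character(event$call_type)
  dur <- event$offset_s - event$onset_s
  fs <- sample_rate_hz
  n <- round(dur * fs)
  if (n < 1) stop("call duration shorter than one sample")
  fmax <- max(config$phee_carrier_hz + config$phee_fm_slope_hz_per_s * dur,
              config$trill_carrier_hz + config$trill_fm_depth_hz,
              config$twitter_sweep_hz[2])
  if (fs < 2 * fmax) {
    stop("sample rate ", fs, " Hz below twice the maximum instantaneous ",
         "frequency (", fmax, " Hz): aliasing")
  }
  t <- (seq_len(n) - 1) / fs
  amp <- config$call_peak_amp[[ty]]
  syl <- event$syllable_onsets_s[[1]] %||% event$onset_s
  if (is.list(syl)) syl <- syl[[1]]
  syl_rel <- syl - event$onset_s
  w <- switch(ty,
    phee = {
      f <- config$phee_carrier_hz + config$phee_fm_slope_hz_per_s * t
      tone(f, fs) * trapezoid(n, fs, 0.02)
    },
    trill = {
      f <- config$trill_carrier_hz +
        config$trill_fm_depth_hz * sin(2 * pi * config$trill_fm_rate_hz * t)
      tone(f, fs) * trapezoid(n, fs, 0.01)
    },
    trillphee = {
      # FM depth full over the first half, smoothly off over ~100 ms
      dep <- config$trill_fm_depth_hz *
        (1 / (1 + exp((t - dur / 2) / 0.025)))
      f <- config$trill_carrier_hz +
        dep * sin(2 * pi * config$trill_fm_rate_hz * t)
      tone(f, fs) * trapezoid(n, fs, 0.02)
    },
    twitter = {
      x <- numeric(n)
      duty <- config$twitter_syllable_duty_s
      for (s0 in syl_rel) {
        i0 <- round(s0 * fs) + 1
        m <- min(round(duty * fs), n - i0 + 1)
        if (m < 8) next
        ts <- (seq_len(m) - 1) / fs
        f <- config$twitter_sweep_hz[1] +
          diff(config$twitter_sweep_hz) * ts / duty
        x[i0:(i0 + m - 1)] <- tone(f, fs) * hann(m)
      }
      x
    },
    compound = {
      x <- numeric(n)
      bounds <- c(syl_rel, dur)
      for (k in seq_along(syl_rel)) {
        i0 <- round(syl_rel[k] * fs) + 1
        # elements fill their slot up to a 30 ms articulatory gap; the last
        # element runs to the annotated call end
        slot <- bounds[k + 1] - syl_rel[k] -
          if (k < length(syl_rel)) 0.03 else 0
        m <- min(round(slot * fs), n - i0 + 1)
        if (m < 8) next
        ts <- (seq_len(m) - 1) / fs
        f <- if (k %% 2 == 1) {
          config$trill_carrier_hz +
            config$trill_fm_depth_hz * sin(2 * pi * config$trill_fm_rate_hz * ts)
        } else {
          config$phee_carrier_hz + config$phee_fm_slope_hz_per_s * ts
        }
        x[i0:(i0 + m - 1)] <- tone(f, fs) * trapezoid(m, fs, 0.01)
      }
      x
    },
    stop("cannot synthesize call type: ", ty)
  )
  amp * w
}

tone <- function(f_inst, fs) sin(2 * pi * cumsum(f_inst) / fs)

trapezoid <- function(n, fs, ramp_s) {
  r <- min(round(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[n - r + seq_len(r)] <- rev(ramp)
  }
  env
}

hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' Render a two-channel acoustic scene
#'
#' Target calls enter the parabolic channel with the configured front gain
#' (default +20 dB) and the reference channel at unit gain; non-target calls
#' and background noise enter both channels at equal level, so the
#' channel-difference map cancels everything but the target.
#'
#' @param targets,nontargets `call_events` tables (targets must not overlap
#'   each other).
#' @param config A [synth_config()].
#' @param seed Integer seed (noise substream).
#' @param duration_s Optional scene length; defaults to the last offset
#'   plus 0.5 s.
#' @return An `acoustic_scene`: list with `parabolic`, `reference`,
#'   `sample_rate_hz`, `truth_target`, `truth_nontarget`.
#' @export
generate_acoustic_scene <- function(targets, nontargets = call_events(),
                                    config = synth_config(),
                                    seed = config$seed, duration_s = NULL) {
  fs <- config$sample_rate_hz
  if (nrow(targets) > 1) {
    o <- order(targets$onset_s)
    if (any(targets$onset_s[o][-1] < targets$offset_s[o][-nrow(targets)])) {
      stop("target events overlap")
    }
  }
  all_off <- c(targets$offset_s, nontargets$offset_s, 1)
  duration_s <- duration_s %||% (max(all_off) + 0.5)
  n <- round(duration_s * fs)
  set.seed(substream_seed(seed, "noise"))
  par <- stats::rnorm(n, 0, config$noise_rms)
  ref <- stats::rnorm(n, 0, config$noise_rms)
  gain <- 10^(config$target_gain_db / 20)
  add_call <- function(chan, ev_row, g) {
    w <- synthesize_call_waveform(ev_row, fs, config) * g
    i0 <- round(ev_row$onset_s * fs) + 1
    idx <- i0:(i0 + length(w) - 1)
    keep <- idx >= 1 & idx <= n
    chan[idx[keep]] <- chan[idx[keep]] + w[keep]
    chan
  }
  for (i in seq_len(nrow(targets))) {
    par <- add_call(par, targets[i, ], gain)
    ref <- add_call(ref, targets[i, ], 1)
  }
  for (i in seq_len(nrow(nontargets))) {
    par <- add_call(par, nontargets[i, ], 1)
    ref <- add_call(ref, nontargets[i, ], 1)
  }
  structure(list(parabolic = par, reference = ref, sample_rate_hz = fs,
                 truth_target = targets, truth_nontarget = nontargets),
            class = "acoustic_scene")
}
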