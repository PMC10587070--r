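# Synthetic LFP: 1/f background whose beta- and theta-band content is
# replaced by controlled components -- a beta envelope multiplicatively
# suppressed around each call and a theta oscillation whose phase is
# anchored to the trough (plus von Mises jitter) at every syllable onset.

#' Generate a multi-channel synthetic LFP
#'
#' Background is pink (1/f) noise at `lfp_bg_rms_uv`.  Its beta-band
#' (12-30 Hz) content is rescaled to `beta_rms_uv` and multiplied, for each
#' call of type `ty`, by `sqrt(1 - depth[ty])` from `onset + start[ty]` to
#' the call end (50 ms raised-cosine ramps).  Because the suppression is an
#' amplitude factor `sqrt(1 - d)`, the *relative band power* inside a fully
#' suppressed window has the closed-form expectation `1 - d`.
#'
#' The theta component is an amplitude-enveloped oscillator at
#' `theta_freq_hz` whose unwrapped phase is linearly interpolated between
#' anchors placed at every syllable onset, where the target phase is the
#' trough (`pi` under the cosine convention) plus von Mises(`theta_kappa`)
#' jitter.  Anchoring the phase directly (rather than adding per-syllable
#' wave packets) keeps the generated onset phase exact: packets repeating at
#' the syllable rate interfere coherently and would bias vector strength.
#'
#' @param calls `call_events`, sorted; events should sit at least ~4 s from
#'   the recording edges for downstream baselines.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param duration_s Recording length; default last offset + 4 s.
#' @param n_channels Number of channels (default `config$n_channels`).
#' @return An `lfp_channels` object: `samples` (channels x time, uV),
#'   `sample_rate_hz`, `site_xy_mm`.
#' @export
generate_lfp <- function(calls, config = synth_config(), seed = config$seed,
                         duration_s = NULL, n_channels = config$n_channels) {
  validate_synth_config(config)
  if (nrow(calls) > 1 && is.unsorted(calls$onset_s)) stop("calls must be sorted")
  fs <- config$lfp_rate_hz
  duration_s <- duration_s %||% (max(c(calls$offset_s, 1)) + 4)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  env_mod <- beta_mod_envelope(calls, config, n, fs)
  samples <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    set.seed(substream_seed(seed, paste0("lfp", ch)))
    bg <- pink_noise(n, config$lfp_bg_rms_uv)
    bg_beta <- bandpass(bg, fs, config$beta_band)
    bg_theta <- bandpass(bg, fs, config$theta_band)
    rest <- bg - bg_beta - bg_theta
    beta <- bg_beta / rms(bg_beta) * config$beta_rms_uv * env_mod
    theta_bg <- bg_theta / rms(bg_theta) * config$theta_bg_rms_uv
    theta <- theta_component(calls, config, n, fs)
    # confine the oscillator to below the beta band: envelope ramps and
    # phase jitter spray weak sidebands upward; the zero-phase low-pass
    # removes them without touching the onset phases
    if (any(theta != 0)) {
      lp <- signal::butter(4, (config$beta_band[1] - 0.5) / (fs / 2),
                           type = "low")
      theta <- signal::filtfilt(lp, theta)
    }
    samples[ch, ] <- rest + beta + theta_bg + theta
  }
  grid <- expand.grid(x = seq_len(ceiling(sqrt(n_channels))),
                      y = seq_len(ceiling(sqrt(n_channels))))[seq_len(n_channels), ]
  structure(list(samples = samples, sample_rate_hz = fs,
                 site_xy_mm = as.matrix(grid) * 0.5,
                 duration_s = duration_s),
            class = "lfp_channels")
}

# Multiplicative amplitude envelope for the beta component: sqrt(1 - depth)
# inside [onset + start, offset] per call, raised-cosine ramps.
beta_mod_envelope <- function(calls, config, n, fs) {
  env <- rep(1, n)
  if (nrow(calls) == 0) return(env)
  ramp <- round(config$mod_ramp_s * fs)
  for (i in seq_len(nrow(calls))) {
    ty <- calls$call_type[i]
    m <- config$beta_mod[[ty]]
    if (is.null(m) || m$depth <= 0) next
    a <- sqrt(1 - m$depth)
    i0 <- round((calls$onset_s[i] + m$start) * fs) + 1
    i1 <- round(calls$offset_s[i] * fs)
    if (i1 <= i0) next
    i0 <- max(1, i0); i1 <- min(n, i1)
    seg <- rep(a, i1 - i0 + 1)
    r <- min(ramp, floor(length(seg) / 2))
    if (r > 0) {
      up <- a + (1 - a) * 0.5 * (1 + cos(pi * seq_len(r) / r))
      seg[seq_len(r)] <- up
      seg[length(seg) - r + seq_len(r)] <- rev(up)
    }
    env[i0:i1] <- pmin(env[i0:i1], seg)
  }
  env
}

# Phase-anchored theta oscillation: amplitude envelope spans each call
# (+/- 0.3 s shoulders).  The oscillator runs at theta_freq_hz with a
# slowly varying phase deviation that equals pi + vonMises jitter at every
# syllable onset.  The deviation is held constant on a plateau around each
# onset and moves only in the middle of inter-syllable gaps, so the
# narrowband analysis filter (whose kernel averages over ~0.2 s) sees a
# locally constant phase at every onset and recovers the generated jitter
# without shrinkage -- provided syllable gaps are a few theta cycles.
theta_component <- function(calls, config, n, fs) {
  out <- numeric(n)
  if (nrow(calls) == 0) return(out)
  f0 <- config$theta_freq_hz
  # the envelope reaches full amplitude 0.3 s before the first syllable
  # so the analysis filter's kernel sees constant amplitude at every onset
  pad <- 0.6
  ramp_s <- 0.3
  for (i in seq_len(nrow(calls))) {
    syl <- calls$syllable_onsets_s[[i]]
    jit <- rvonmises(length(syl), 0, config$theta_kappa)
    t0 <- calls$onset_s[i] - pad
    t1 <- calls$offset_s[i] + pad
    i0 <- max(1, round(t0 * fs) + 1)
    i1 <- min(n, round(t1 * fs))
    if (i1 <= i0) next
    tt <- (i0:i1 - 1) / fs
    # unwrapped phase deviation d(t): phi(t) = pi + 2 pi f0 (t - syl[1]) +
    # d(t), with d(syl_k) congruent to jit_k - 2 pi f0 (syl_k - syl[1])
    K <- length(syl)
    d <- numeric(K)
    d[1] <- jit[1]
    if (K > 1) {
      for (k in 2:K) {
        want <- jit[k] - 2 * pi * f0 * (syl[k] - syl[1])
        d[k] <- d[k - 1] + wrap_phase(want - d[k - 1])
      }
    }
    gap_min <- if (K > 1) min(diff(syl)) else Inf
    p <- min(0.25, 0.35 * gap_min)
    # raised-cosine steps between plateaus keep the deviation spectrum low
    knots_x <- c(syl[1] - p, syl[1] + p)
    knots_y <- c(d[1], d[1])
    if (K > 1) {
      frac <- (1 - cos(pi * seq(0, 1, length.out = 9))) / 2
      for (k in 2:K) {
        x0 <- syl[k - 1] + p
        x1 <- syl[k] - p
        knots_x <- c(knots_x, x0 + (x1 - x0) * frac[-c(1, 9)],
                     x1, syl[k] + p)
        knots_y <- c(knots_y, d[k - 1] + (d[k] - d[k - 1]) * frac[-c(1, 9)],
                     d[k], d[k])
      }
    }
    dev <- stats::approx(x = knots_x, y = knots_y, xout = tt, rule = 2)$y
    phi <- pi + 2 * pi * f0 * (tt - syl[1]) + dev
    env <- rep(1, length(tt))
    r <- min(round(ramp_s * fs), floor(length(tt) / 2))
    if (r > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
      env[seq_len(r)] <- ramp
      env[length(tt) - r + seq_len(r)] <- rev(ramp)
    }
    out[i0:i1] <- out[i0:i1] + config$theta_amp_uv * env * cos(phi)
  }
  out
}
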