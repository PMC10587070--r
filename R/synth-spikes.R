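# Synthetic spike trains (inhomogeneous Poisson with window-specific rate
# gains around each call) and sync-pulse trains on two drifting clocks.

#' Peri-call analysis windows
#'
#' The four windows used throughout the spike analyses, relative to the
#' vocal onset of a call of duration `dur`: early `(-2, -0.5)`, pre
#' `(-0.5, 0)`, during `(0, 0.8 * dur)`, post `(0.8 * dur, dur + 0.5)`.
#'
#' @param dur Call duration (s).
#' @return 4 x 2 matrix with rownames `early`, `pre`, `during`, `post`.
#' @export
spike_windows <- function(dur) {
  m <- rbind(early = c(-2, -0.5),
             pre = c(-0.5, 0),
             during = c(0, 0.8 * dur),
             post = c(0.8 * dur, dur + 0.5))
  colnames(m) <- c("lo", "hi")
  m
}

#' Generate spike trains around a call sequence
#'
#' Each unit is an inhomogeneous Poisson process: rate equals the unit's
#' baseline everywhere except inside the four peri-call windows, where it is
#' multiplied by the call type's configured gain.  Sampling is by thinning
#' against the maximum rate, so identical `(config, seed)` give identical
#' trains.
#'
#' @param calls `call_events`, sorted; callers should space calls so
#'   windows of adjacent calls do not overlap.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param duration_s Recording span; default last offset + 11 s.
#' @return A `spike_trains` object: list `times` (per-unit sorted vectors),
#'   `unit_channel`, `duration_s`.
#' @export
generate_spike_trains <- function(calls, config = synth_config(),
                                  seed = config$seed, duration_s = NULL) {
  validate_synth_config(config)
  duration_s <- duration_s %||% (max(c(calls$offset_s, 1)) + 11)
  gains <- config$spike_gains
  # piecewise-constant gain lookup over call windows
  edges <- numeric(0); gvals <- numeric(0)
  for (i in seq_len(nrow(calls))) {
    w <- spike_windows(calls$offset_s[i] - calls$onset_s[i])
    g <- gains[[calls$call_type[i]]]
    edges <- c(edges, calls$onset_s[i] + as.vector(t(w)))
    gvals <- c(gvals, as.vector(rbind(g, NA)))
  }
  gain_at <- function(t) {
    if (length(edges) == 0) return(rep(1, length(t)))
    idx <- findInterval(t, edges)
    out <- rep(1, length(t))
    inside <- idx >= 1 & idx <= length(gvals)
    gv <- gvals[pmax(idx, 1)]
    hit <- inside & !is.na(gv)
    out[hit] <- gv[hit]
    out
  }
  times <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    set.seed(substream_seed(seed, paste0("spikes", u)))
    base <- config$unit_baseline_hz[u]
    rmax <- base * max(1, unlist(gains))
    ncand <- stats::rpois(1, rmax * duration_s)
    cand <- sort(stats::runif(ncand, 0, duration_s))
    keep <- stats::runif(ncand) < base * gain_at(cand) / rmax
    times[[u]] <- cand[keep]
  }
  structure(list(times = times,
                 unit_channel = rep_len(seq_len(max(1, config$n_channels)),
                                        config$n_units),
                 duration_s = duration_s),
            class = "spike_trains")
}

#' Generate matched sync-pulse trains on two clocks
#'
#' A pulse train with a 2 s period is emitted on the audio clock; the same
#' physical pulses are observed on the neural clock through an offset and a
#' linear drift, emulating independent device clocks.
#'
#' @param duration_s Recording span (>= one period).
#' @param drift_ppm Clock drift of the neural clock in parts per million.
#' @param seed Integer seed (draws the offset when `offset_s` is NULL).
#' @param offset_s Fixed clock offset (s); default drawn uniform on [0, 5].
#' @param period_s Nominal pulse period (default 2 s).
#' @return List with `audio` and `neural` `sync_pulses` objects.
#' @export
generate_sync <- function(duration_s, drift_ppm = 0, seed = 1,
                          offset_s = NULL, period_s = 2) {
  if (duration_s < period_s) stop("duration must cover at least one period")
  if (is.null(offset_s)) {
    set.seed(substream_seed(seed, "sync"))
    offset_s <- stats::runif(1, 0, 5)
  }
  t_audio <- seq(0, duration_s, by = period_s)
  t_neural <- offset_s + t_audio * (1 + drift_ppm * 1e-6)
  list(audio = structure(list(times = t_audio, period_s = period_s),
                         class = "sync_pulses"),
       neural = structure(list(times = t_neural, period_s = period_s),
                          class = "sync_pulses"))
}
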