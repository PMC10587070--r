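# Shared data model: call events, generator configuration, and their
# validation.  All times are seconds on the recording clock, 0-based, with
# half-open intervals [onset, offset).

CALL_TYPES <- c("phee", "trill", "twitter", "trillphee", "compound")

#' Construct a table of call events
#'
#' The central annotation container used by every module: one row per
#' vocalization, with the ordered syllable onsets stored as a list column.
#'
#' @param onset_s,offset_s Numeric vectors, `offset_s > onset_s`.
#' @param call_type Character vector in
#'   `c("phee","trill","twitter","trillphee","compound")` (or `"unknown"` for
#'   detector output).
#' @param syllable_onsets_s List of numeric vectors; each must be sorted,
#'   start at the call onset, and lie within the call.  Defaults to one
#'   syllable at the onset.
#' @param is_target Logical; ground-truth flag for synthetic scenes.
#' @return A `call_events` data frame.
#' @export
call_events <- function(onset_s = numeric(0), offset_s = numeric(0),
                        call_type = character(0),
                        syllable_onsets_s = NULL,
                        is_target = TRUE) {
  n <- length(onset_s)
  stopifnot(length(offset_s) == n, length(call_type) == n)
  if (is.null(syllable_onsets_s)) syllable_onsets_s <- as.list(onset_s)
  stopifnot(length(syllable_onsets_s) == n)
  is_target <- rep_len(is_target, n)
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   call_type = as.character(call_type),
                   is_target = is_target,
                   stringsAsFactors = FALSE)
  ev$syllable_onsets_s <- lapply(syllable_onsets_s, as.numeric)
  class(ev) <- c("call_events", "data.frame")
  validate_call_events(ev)
}

#' Validate a call-event table
#'
#' Checks the invariants: positive durations, sorted in-call syllable
#' onsets whose first element equals the call onset, and at least 3
#' syllables for twitter calls.
#'
#' @param ev A `call_events` object.
#' @return `ev`, invisibly unchanged, or an error.
#' @export
validate_call_events <- function(ev) {
  if (nrow(ev) == 0) return(ev)
  if (any(ev$offset_s <= ev$onset_s)) stop("call offset must exceed onset")
  bad <- !(ev$call_type %in% c(CALL_TYPES, "unknown"))
  if (any(bad)) stop("unknown call type: ", paste(unique(ev$call_type[bad]),
                                                  collapse = ", "))
  for (i in seq_len(nrow(ev))) {
    s <- ev$syllable_onsets_s[[i]]
    if (length(s) < 1 || is.unsorted(s, strictly = FALSE)) {
      stop("syllable onsets must be non-empty and sorted (event ", i, ")")
    }
    if (abs(s[1] - ev$onset_s[i]) > 1e-9) {
      stop("first syllable onset must equal the call onset (event ", i, ")")
    }
    if (s[length(s)] > ev$offset_s[i] + 1e-9) {
      stop("syllable onsets must lie within the call (event ", i, ")")
    }
    if (ev$call_type[i] == "twitter" && length(s) < 3) {
      stop("twitter calls must have at least 3 syllables (event ", i, ")")
    }
  }
  ev
}

#' Sort and concatenate call-event tables
#' @param ... `call_events` objects.
#' @return A single sorted `call_events` object.
#' @export
bind_call_events <- function(...) {
  evs <- list(...)
  evs <- evs[vapply(evs, nrow, 0L) > 0]
  if (length(evs) == 0) return(call_events())
  out <- do.call(rbind, lapply(evs, function(e) { class(e) <- "data.frame"; e }))
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("call_events", "data.frame")
  out
}

#' Generator configuration
#'
#' Bundles every free parameter of the synthetic recordings.  Defaults are
#' the package's standing description of a colony session: trill-heavy call
#' rates, phee-loudest / trill-softest amplitudes, a 20 dB parabolic front
#' gain, 1/f LFP background with band-limited beta and theta components,
#' trough-locked theta with von Mises jitter, and per-type spike-rate gains
#' in the four peri-call windows.
#'
#' @param ... Named overrides of any default component (nested lists are
#'   merged shallowly at the top level, i.e. a supplied component replaces
#'   the default component wholesale).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    sample_rate_hz = 48000,
    lfp_rate_hz = 1000,
    # calls / minute, Poisson process per type
    call_rates_per_min = c(phee = 0.8, trill = 2.0, twitter = 1.0,
                           trillphee = 0.5, compound = 0.3),
    duration_range_s = list(phee = c(1.2, 2.5), trill = c(0.3, 0.6),
                            twitter = c(0.8, 1.6), trillphee = c(1.0, 2.0),
                            compound = c(1.0, 2.0)),
    twitter_syllable_rate_hz = 7,
    twitter_syllable_jitter_s = 0.004,
    # reference-channel peak amplitudes (arbitrary pressure units);
    # phee loudest, trill softest
    call_peak_amp = c(phee = 0.30, trill = 0.10, twitter = 0.20,
                      trillphee = 0.25, compound = 0.22),
    target_gain_db = 20,
    noise_rms = 0.004,
    min_call_gap_s = 0.35,
    # acoustic carriers: fundamentals above 5 kHz
    phee_carrier_hz = 7000, phee_fm_slope_hz_per_s = 500,
    trill_carrier_hz = 7500, trill_fm_rate_hz = 30, trill_fm_depth_hz = 600,
    twitter_sweep_hz = c(6000, 10000), twitter_syllable_duty_s = 0.045,
    # LFP
    n_channels = 4,
    lfp_bg_rms_uv = 50,
    beta_band = c(12, 30), beta_rms_uv = 15,
    theta_band = c(5, 10), theta_freq_hz = 7,
    theta_amp_uv = 40, theta_bg_rms_uv = 5, theta_kappa = 2.5,
    # per-type beta suppression: fractional power depth in [0,1] and start
    # offset (s, relative to vocal onset); suppression lasts to call end
    beta_mod = list(phee = list(depth = 0.50, start = -0.60),
                    trill = list(depth = 0.30, start = -0.30),
                    twitter = list(depth = 0.40, start = -0.40),
                    trillphee = list(depth = 0.45, start = 0.30),
                    compound = list(depth = 0.40, start = -0.30)),
    mod_ramp_s = 0.05,
    # spikes: per-unit baseline rates and per-type gains in the four
    # windows (early, pre, during, post)
    n_units = 8,
    unit_baseline_hz = NULL, # filled as seq(3, 8, length.out = n_units)
    spike_gains = list(phee = c(early = 1.2, pre = 1.5, during = 0.8, post = 1.0),
                       trill = c(early = 1.3, pre = 2.0, during = 0.7, post = 1.0),
                       twitter = c(early = 1.0, pre = 1.2, during = 0.5, post = 2.0),
                       trillphee = c(early = 1.0, pre = 1.2, during = 1.8, post = 1.2),
                       compound = c(early = 1.0, pre = 1.2, during = 1.5, post = 1.2)),
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(names(over) != ""))
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown synth_config fields: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (is.null(cfg$unit_baseline_hz)) {
    cfg$unit_baseline_hz <- seq(3, 8, length.out = cfg$n_units)
  }
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' Validate generator configuration
#' @param cfg A `synth_config`.
#' @return `cfg` or an error.
#' @export
validate_synth_config <- function(cfg) {
  if (any(cfg$call_rates_per_min < 0)) stop("call rates must be >= 0")
  if (cfg$twitter_syllable_rate_hz <= 0) stop("syllable rate must be > 0")
  for (ty in names(cfg$beta_mod)) {
    d <- cfg$beta_mod[[ty]]$depth
    if (d < 0 || d > 1) stop("beta depth must lie in [0,1] (", ty, ")")
  }
  if (cfg$theta_kappa < 0) stop("theta_kappa must be >= 0")
  if (any(unlist(cfg$spike_gains) < 0)) stop("spike gains must be >= 0")
  if (any(cfg$unit_baseline_hz <= 0)) stop("baseline rates must be > 0")
  if (length(cfg$unit_baseline_hz) != cfg$n_units) {
    stop("unit_baseline_hz must have n_units entries")
  }
  invisible(cfg)
}
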