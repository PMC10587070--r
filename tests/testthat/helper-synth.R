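# Shared fixture builders: regularly spaced call schedules and small
# synthetic populations, all generated in code at test time.

# n calls of one type, evenly spaced, with optional syllable grid
spaced_events <- function(n, type = "trill", dur = 0.5, spacing = 8,
                          start = 6, syl_spacing = NULL, n_syl = NULL) {
  on <- start + (seq_len(n) - 1) * spacing
  if (is.null(syl_spacing)) {
    call_events(on, on + dur, rep(type, n))
  } else {
    syl <- lapply(on, function(o) o + (seq_len(n_syl) - 1) * syl_spacing)
    off <- on + (n_syl - 1) * syl_spacing + 0.1
    call_events(on, off, rep(type, n), syl)
  }
}

# interleaved two-type schedule for spike/decoding tests
two_type_events <- function(n_each, types = c("trill", "trillphee"),
                            dur = 0.8, spacing = 22, start = 12) {
  n <- 2 * n_each
  on <- start + (seq_len(n) - 1) * spacing
  call_events(on, on + dur, rep(types, n_each))
}

# per-neuron trial rates for the decoder, via the spike generator; gains_a
# applies to trill, gains_b to trillphee
decoder_population <- function(n_neurons, n_calls, gains_a, gains_b,
                               seed, baseline = 5, center = 0) {
  flat <- c(early = 1, pre = 1, during = 1, post = 1)
  ev <- two_type_events(n_calls)
  lapply(seq_len(n_neurons), function(u) {
    cfg <- synth_config(n_units = 1, unit_baseline_hz = baseline,
                        spike_gains = list(phee = flat, trill = gains_a,
                                           twitter = flat,
                                           trillphee = gains_b,
                                           compound = flat))
    spk <- generate_spike_trains(ev, cfg, seed = seed * 1000 + u)
    list(a = neuron_window_rates(spk, ev[ev$call_type == "trill", ],
                                 1, center),
         b = neuron_window_rates(spk, ev[ev$call_type == "trillphee", ],
                                 1, center))
  })
}

flat_gains <- function() c(early = 1, pre = 1, during = 1, post = 1)

# uniform-across-types spike gains
uniform_spike_gains <- function(g = flat_gains()) {
  list(phee = g, trill = g, twitter = g, trillphee = g, compound = g)
}

# theta-band phase-locking fixture: multi-syllable calls whose syllable
# grid is an integer number of theta cycles apart (4 cycles), so the
# 5-10 Hz filter transmits the generated jitter unshrunk
phase_lock_events <- function(n_calls, n_syl = 10, f0 = 7, cycles = 4,
                              spacing = 7, start = 4) {
  sp <- cycles / f0
  spaced_events(n_calls, "compound", spacing = spacing, start = start,
                syl_spacing = sp, n_syl = n_syl)
}
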