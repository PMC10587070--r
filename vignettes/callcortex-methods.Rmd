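---
title: "Methods: synthetic colony recordings and the call-production pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic colony recordings and the call-production pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind `callcortex`: what the synthetic-data generator
emulates, how each analysis stage is defined, and what passing tests do
and do not establish about real recordings.

## The recording model

A session consists of four jointly simulated data streams tied together
by a shared call schedule:

* **Two-channel audio** (48 kHz). Target calls enter the parabolic
  channel with a configurable front gain (default **20 dB**, the nominal
  on-axis advantage of a parabolic reflector over a reference microphone)
  and the reference channel at unit gain. Non-target calls and Gaussian
  background noise enter both channels at equal level. This is the
  premise of channel-difference source separation: everything symmetric
  cancels, the target's calls remain.
* **Multi-channel LFP** (1 kHz, µV). 1/f background (50 µV RMS) whose
  beta-band and theta-band content is replaced by controlled components
  (below), so band-limited modulations have closed-form expectations.
* **Spike trains.** Inhomogeneous Poisson per unit: baseline rate
  (defaults 3–8 Hz across units) multiplied by a per-call-type gain
  inside each of the four peri-call windows, sampled by thinning.
* **Sync pulses.** A 2 s pulse train observed on two clocks related by
  offset + linear drift; `align_clocks()` inverts the relation by least
  squares.

Call types follow independent Poisson processes at configured rates
(trill most frequent), with per-type uniform duration ranges, phee the
loudest and trill the softest call. Twitter syllables repeat at 7 Hz
with small Gaussian timing jitter; compound calls carry three or more
heterogeneous elements. Event counts are drawn first and onsets placed
by rejection, so counts remain exactly Poisson while target calls never
overlap. The annotated offset of a twitter is the acoustic end of its
last syllable sweep, not the nominal drawn duration, so detector
boundaries and annotations refer to the same physical extent.

### Beta suppression

The generator rescales the background's 12–30 Hz content to a 15 µV RMS
beta component and multiplies its amplitude by `sqrt(1 - depth)` from
`onset + start` to the call end (50 ms raised-cosine ramps), per call
type. Because the suppression acts on amplitude as `sqrt(1 - d)`, the
*relative band power* inside a fully suppressed window has expectation
`1 - d` — the exact mapping the recovery tests use. Default depths/starts
(phee 0.50 from −0.6 s; trill 0.30 from −0.3 s; twitter 0.40 from
−0.4 s; trillphee 0.45 from +0.3 s; compound 0.40 from −0.3 s) encode
early pre-vocal suppression for phee-like calls and late, mid-call
suppression for trillphee, the qualitative pattern the cross-type
analyses are designed to resolve. Effect sizes are free parameters of the
simulation, not claims about any animal.

### Trough-locked theta

The theta component is an amplitude-enveloped oscillator at 7 Hz whose
unwrapped phase deviation is **held constant on a plateau around every
syllable onset** (±0.25 s, shrunk for tightly spaced syllables) and moves
between plateaus along raised-cosine steps; at each onset the phase
equals the trough (π under the cosine convention) plus von Mises jitter
of concentration κ (default 2.5). Two design points matter:

* *Why not additive wave packets?* Packets repeating at the syllable
  rate interfere coherently and bias the measured vector strength
  upward; the phase-anchored oscillator makes the generated onset phase
  exact by construction.
* *Why plateaus?* The 5–10 Hz analysis filter has an impulse response
  several hundred milliseconds wide. If the phase moved linearly between
  anchors, the filter would average the anchor value with its
  neighbours and shrink the jitter (inflating VS). With the deviation
  locally constant, the filter sees a stationary phase at every sampling
  point. For the same reason the amplitude envelope reaches full level
  0.3 s before the first syllable.

A physical limit remains: when syllables repeat at the theta rate itself
(twitter at 7 Hz), per-syllable independent jitter is phase modulation at
up to 3.5 Hz, partially outside what any 5–10 Hz filter can transmit
around a 7 Hz carrier — measured VS is then biased toward 1 regardless of
generator design. The quantitative vector-strength recovery checks
therefore use syllable grids an integer number of theta cycles apart
(8 cycles = 1.14 s), for which the jitter spectrum lies inside the band;
recovery at n = 10⁴ syllables reproduces I₁(κ)/I₀(κ) within 0.02 at
κ = 2. Twitter-rate locking is still generated and detected, but its VS
should be read as a lower-variance, upward-shrunken estimate.

## Analysis definitions

* **Detection.** STFT with a 512-sample Hann window, 50% hop, 4–20 kHz
  analysis band (marmoset call band; fundamentals sit above 5 kHz).
  Frames whose band-summed parabolic/reference power ratio exceeds
  **10 dB** (half the nominal front gain) are marked; runs are merged
  across gaps ≤ 0.15 s (bridging 7 Hz syllable gaps) and dropped under
  0.1 s. Boundaries carry ±half-hop (≈2.7 ms) quantization.
* **Classification** is a deterministic cascade: ≥3 envelope bursts →
  twitter vs compound by element duration (any burst > 0.25 s, or a
  duration CV > 0.5, → compound); two long bursts → compound; otherwise
  the 20–45 Hz sinusoidal-FM power of the instantaneous-frequency track
  (decimated to 1 kHz for filter stability) separates trill (sustained),
  trillphee (first half only) and phee (absent, duration ≥ 0.5 s);
  anything else is labelled `unknown`, never silently guessed.
* **Band power.** 4th-order Butterworth run forward–backward (zero
  phase), 1 s reflected padding against end transients, analytic
  amplitude by FFT Hilbert transform, squared, block-averaged to 200 Hz,
  epoched to [−3.5, 3.5] s, divided per trial by the [−3, −1] s baseline
  mean. Calls shorter than 200 ms are excluded.
* **Modulation criterion.** Significant ⇔ two-sided signed-rank p < 0.05
  *and* |trial-averaged window mean − baseline mean| > 2 bootstrap SDs.
  The bootstrap draws 200 trials (without replacement when that many
  exist, with replacement otherwise — the procedure is only fully defined
  for abundant trial counts), averages them, segments the baseline into
  200 ms windows and takes the SD of segment means, averaged over 1000
  repetitions. The combined criterion is conservative by construction;
  its empirical per-window false-positive rate on null data is checked
  to stay ≤ 7% at α = 0.05. Start times search 100 ms windows in 5 ms
  steps over [−0.5 s, max(0.9 s, median duration)]. Identical
  window/baseline comparisons return p = 1; constant input is flagged
  degenerate with p undefined. Multiple testing across sites is *not*
  corrected (per-site α = 0.05), deliberately.
* **Spikes.** 50 ms bins over [−10, 10] s, z-scored per trial (zero-
  variance trials get z = 0 and stay in the count); the same combined
  criterion with 500 ms bootstrap segments and draws capped at the trial
  count; the 2 SD rule is applied in z units. Shuffle controls
  circularly shift each trial by an independent uniform offset and rerun
  the whole test. "Responding differently" to two call types means a
  different direction in any window or a different set of significant
  windows.
* **Decoding.** Neurons qualify with ≥20 calls of each type. Per
  repetition: 70/30 split per neuron and class, `n_redraw` bootstrap
  pseudo-trials per class and pool (pseudo-trials pair trials at random
  across neurons — the central modeling assumption for units recorded in
  different sessions), PCA fit on training draws only (≤10 components,
  capped at the feature dimension), `MASS::lda`, accuracy on test draws;
  mean and 2.5–97.5 percentile CI over repetitions. Degenerate redraws
  (a collapsed pool) are resampled. Choosing to redraw the 70/30 split
  every repetition (rather than once) makes the CI reflect both split
  and resampling variability.

## Numerical choices

* All FFTs run on 2-3-5-smooth lengths (reflected or zero padding,
  trimmed afterwards): R's mixed-radix FFT degrades to quadratic cost on
  lengths with large prime factors, which recording durations routinely
  produce.
* The Morlet transform (width 7, σ_t = width/2πf) is evaluated by linear
  FFT convolution with zero padding past the longest wavelet, then
  center-aligned.
* The Rayleigh p-value uses the standard series correction in Z = nVS²;
  the statistic 2nVS² is compared to χ²(2) quantiles (13.8 at 0.001).
  This is the only convention under which a printed threshold of 13.8
  corresponds to p = 0.001.
* A master seed spawns named substreams (calls, noise, per-channel LFP,
  per-unit spikes, bootstraps, decoder), so stages can be regenerated
  independently and a full run is bit-reproducible from `(config, seed)`.
  No output file embeds a timestamp.

## Problem sizes

The default demo session simulates a 120 s acoustic scene, 24 calls per
social call type for the neural analyses (2 LFP channels, 6 units), and
a 3-center decoding curve at reduced resampling (200 redraws, 50
repetitions); it completes in minutes on one core. The statistical
checks use the sizes their targets require: 200 null units for type-I
control, 300 trials for change-point recovery, 10⁴ syllables for
vector-strength convergence, 50 + 50 calls for detection scores. These
are simulation-design choices balancing statistical resolution against
routine re-runs of the whole suite.

## What passing tests do not show

The generator reproduces the *statistical structure* the analyses assume
— stationary 1/f background, band-limited modulations with sharp onsets,
Poisson spiking with window gains, noise-free annotations of non-target
calls. Real colony recordings add movement and chewing artifacts,
overlapping target calls, non-stationary backgrounds, acoustic
reverberation, spike-sorting errors and drifting electrodes, none of
which are modeled; detection scores and error rates measured here are
upper bounds on real-data performance. Call-type classification is a
rule cascade adequate for the synthetic repertoire, standing in for the
human-corrected learned classifier used on real data; its error profile
is not expected to transfer. Sites are abstract array coordinates — no
anatomical claims attach to them.
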