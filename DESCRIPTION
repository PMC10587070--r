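Package: callcortex
Title: Frontal-Cortex Neural Dynamics During Marmoset Call Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for frontal-cortex electrophysiology
    recorded while marmosets produce social calls in a colony setting.
    Covers targeted two-channel (parabolic/reference) acoustic call
    detection and classification, trial-aligned baseline-normalized LFP
    band-power analysis with a bootstrap standard-deviation criterion and
    modulation start-time estimation, theta-band phase locking of call
    syllables quantified by vector strength and the Rayleigh test,
    single-neuron peri-call firing-rate modulation with circular-shift
    shuffle controls, and Monte-Carlo linear-discriminant population
    decoding of call type.  A synthetic-data generator emulates the
    paired-microphone audio, multi-channel LFP, spike trains, and sync
    pulses with known ground truth so every stage of the pipeline is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
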