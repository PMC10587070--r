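#!/usr/bin/env Rscript
# Simulate one synthetic colony session: two-channel targeted audio with
# ground-truth annotations, multi-channel LFP, spike trains and sync
# pulses.  Writes everything under results/session/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(callcortex)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

config <- default_run_config(seed = seed, outdir = "results/session")
config$stages[c("detect", "lfp", "phase", "spikes", "decode",
                "report")] <- FALSE
bundle <- run_pipeline(config)

truth <- read_annotations(bundle$paths$scene_truth)
neural <- read_annotations(bundle$paths$neural_truth)
cat("Scene:", config$synth$scene_duration_s, "s with", nrow(truth),
    "target calls (", paste(names(table(truth$call_type)),
                            table(truth$call_type), collapse = ", "),
    ")\n")
cat("Neural session:", nrow(neural), "calls,",
    config$synth$n_channels, "LFP channels,",
    config$synth$n_units, "units\n")
write_run_config(config, "results/session/config.json")
cat("Config written to results/session/config.json\n")
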