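#!/usr/bin/env Rscript
# Detect, segment and classify the target animal's calls from the
# parabolic/reference pair simulated by 01_simulate.R, and score the
# detections against the generator's ground truth.
#
# Usage: Rscript analysis/02_detect_calls.R

library(callcortex)

config <- read_run_config("results/session/config.json")
config$stages[c("synth", "detect")] <- TRUE
config$stages[c("lfp", "phase", "spikes", "decode", "report")] <- FALSE
bundle <- run_pipeline(config)

metrics <- read.csv(bundle$paths$detect_metrics)
det <- read_annotations(bundle$paths$detected)
cat("Detected", nrow(det), "target segments\n")
for (i in seq_len(nrow(metrics))) {
  cat(sprintf("  %-14s %.3f\n", metrics$metric[i], metrics$value[i]))
}
cat("Detections written to", bundle$paths$detected, "\n")
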