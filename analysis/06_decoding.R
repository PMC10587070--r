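#!/usr/bin/env Rscript
# Population decoding of call type (trill vs twitter) from pooled
# single-neuron rates with the Monte-Carlo resampled PCA + LDA decoder in
# sliding 1 s windows.
#
# Usage: Rscript analysis/06_decoding.R

library(callcortex)

config <- read_run_config("results/session/config.json")
config$stages[c("synth", "decode")] <- TRUE
config$stages[c("detect", "lfp", "phase", "spikes", "report")] <- FALSE
bundle <- run_pipeline(config)

curve <- read.csv(bundle$paths$decode_curve)
cat("Decoding curve (chance = 0.5):\n")
for (i in seq_len(nrow(curve))) {
  cat(sprintf("  t = %+5.1f s: accuracy %.3f [%.3f, %.3f]%s\n",
              curve$center_s[i], curve$mean_acc[i], curve$ci_lo[i],
              curve$ci_hi[i],
              if (curve$significant[i]) " *" else ""))
}
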