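#!/usr/bin/env Rscript
# Single-neuron modulation: per unit and call type, test the four
# peri-call windows (early / pre / during / post) against the [-8, -4] s
# baseline, and tally cross-type differences.
#
# Usage: Rscript analysis/05_spike_modulation.R

library(callcortex)

config <- read_run_config("results/session/config.json")
config$stages[c("synth", "spikes")] <- TRUE
config$stages[c("detect", "lfp", "phase", "decode", "report")] <- FALSE
bundle <- run_pipeline(config)

res <- read.csv(bundle$paths$spike_results)
for (ty in unique(res$call_type)) {
  s <- res[res$call_type == ty, ]
  mod <- tapply(s$significant, s$unit, any)
  cat(sprintf("%-10s %d of %d tested units modulated\n", ty,
              sum(mod), length(mod)))
}
tally <- read.csv(bundle$paths$spike_tally)
for (i in seq_len(nrow(tally))) {
  cat(sprintf("%s vs %s: %d modulated, %d differ (%.0f%%)\n",
              tally$type_a[i], tally$type_b[i], tally$modulated[i],
              tally$modulated[i] * tally$diff_proportion[i],
              100 * tally$diff_proportion[i]))
}
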