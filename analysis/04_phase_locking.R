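#!/usr/bin/env Rscript
# Theta-band (5-10 Hz) phase locking of syllable onsets for multi-syllable
# calls: vector strength and Rayleigh test per recording site.
#
# Usage: Rscript analysis/04_phase_locking.R

library(callcortex)

config <- read_run_config("results/session/config.json")
config$stages[c("synth", "phase")] <- TRUE
config$stages[c("detect", "lfp", "spikes", "decode", "report")] <- FALSE
bundle <- run_pipeline(config)

res <- read.csv(bundle$paths$phase_results)
crit <- rayleigh_critical(0.001)
cat(sprintf("Rayleigh 0.001 critical value: %.1f\n", crit))
for (i in seq_len(nrow(res))) {
  cat(sprintf("  site %d: n = %d syllables, VS = %.2f, Rayleigh = %.1f%s\n",
              res$site[i], res$n[i], res$vs[i], res$rayleigh[i],
              if (res$rayleigh[i] > crit) " (p < 0.001)" else ""))
}
cat("Circular mean phase across sites:",
    round(mean_phase(res$mean_phase), 2), "rad (+/-pi = trough)\n")
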