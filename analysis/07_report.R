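#!/usr/bin/env Rscript
# Aggregate every stage into the summary tables and plain-text report.
#
# Usage: Rscript analysis/07_report.R

library(callcortex)

config <- read_run_config("results/session/config.json")
config$stages[] <- TRUE
bundle <- run_pipeline(config)
cat(readLines(bundle$paths$report_txt), sep = "\n")
cat("\nFull tables under", config$outdir, "\n")
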