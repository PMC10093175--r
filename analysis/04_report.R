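#!/usr/bin/env Rscript
# Collate the analysis products into one human-readable markdown report.

library(turtledrift)

txt <- run_report("results/analysis")
cat(txt, "\n")
cat("\nReport written to results/analysis/report.md\n")
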