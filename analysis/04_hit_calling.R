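#!/usr/bin/env Rscript
# Full screen: viability gating, per-plate Dunnett hit calling against the
# stress controls, >=30%-reduction flagging and selectivity classification.
# Writes the per-extract results table, the correlation table and a summary
# report under results/screen/.

library(antioxscreen)

run <- run_screen(campaign_paths("results/campaign"), outdir = "results/screen")

writeLines(readLines("results/screen/report.txt"))

r <- run$results
best <- r[order(r$ros_pct + r$no_pct)[1:3], c("extract_id", "ros_pct", "no_pct",
                                              "selectivity")]
cat("strongest dual reducers:\n"); print(best, row.names = FALSE, digits = 4)
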