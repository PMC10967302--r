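#!/usr/bin/env Rscript
# Calibrate the cell-free chemistry: fit per-plate gallic-acid and Trolox
# standard curves, convert extract absorbances to TPC (mg GAE/L) and FRAP
# (umol TE/L) on the undiluted scale, and correlate the two endpoints.

library(antioxscreen)

files <- campaign_paths("results/campaign")
cfg <- screen_config()

tpc <- quantify_cellfree(
  read_measurements(files$tpc_meas, read_plate_map(files$tpc_map)),
  dilution_factor = cfg$tpc_dilution)
frap <- quantify_cellfree(
  read_measurements(files$frap_meas, read_plate_map(files$frap_map)),
  dilution_factor = cfg$frap_dilution, delta_tol = cfg$frap_delta_tol)

r2 <- vapply(tpc$curves, function(cv) cv$r_squared, numeric(1))
cat(sprintf("TPC standard curves: %d plates, r^2 %.4f - %.4f\n",
            length(r2), min(r2), max(r2)))
print(tpc$curves[[1]])

cellfree <- merge(
  setNames(tpc$per_extract[, c("extract_id", "conc", "sd")],
           c("extract_id", "tpc_gae_mg_L", "tpc_sd")),
  setNames(frap$per_extract[, c("extract_id", "conc", "sd")],
           c("extract_id", "frap_te_umol_L", "frap_sd")))
dir.create("results", showWarnings = FALSE)
write.csv(cellfree, "results/cellfree.csv", row.names = FALSE)

top <- cellfree[order(-cellfree$tpc_gae_mg_L)[1:3], ]
cat("highest-TPC extracts:\n"); print(top, row.names = FALSE, digits = 6)
ct <- spearman_cor(cellfree$tpc_gae_mg_L, cellfree$frap_te_umol_L)
cat(sprintf("TPC-FRAP Spearman r_s = %.4f (p = %.3g, n = %d)\n",
            ct$r_s, ct$p_value, ct$n))
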