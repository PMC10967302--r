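#!/usr/bin/env Rscript
# Normalize the cellular endpoints: DCF ROS time courses to percent of the
# AAPH stress control (trapezoidal AUC of the start-value-normalized trace,
# two-anchor rescaling), Griess NO absorbances to percent of the LPS stress
# control, and resazurin viability to percent of the untreated control with
# the 80% cytotoxicity gate.

library(antioxscreen)

files <- campaign_paths("results/campaign")
cfg <- screen_config()

ros <- process_ros(read_measurements(files$ros_dcf_meas,
                                     read_plate_map(files$ros_dcf_map),
                                     read_schedule = cfg$ros_schedule))
no <- process_no(read_measurements(files$no_griess_meas,
                                   read_plate_map(files$no_griess_map)))
vc <- process_viability(read_measurements(files$viability_caco2_meas,
                                          read_plate_map(files$viability_caco2_map)),
                        threshold = cfg$viability_threshold)
vr <- process_viability(read_measurements(files$viability_raw_meas,
                                          read_plate_map(files$viability_raw_map)),
                        threshold = cfg$viability_threshold)

cellular <- Reduce(function(a, b) merge(a, b, all = TRUE), list(
  setNames(ros$per_sample[, c("sample_id", "ros_pct", "sd")],
           c("extract_id", "ros_pct", "ros_sd")),
  setNames(no$per_sample[, c("sample_id", "no_pct", "sd")],
           c("extract_id", "no_pct", "no_sd")),
  setNames(vc[, c("sample_id", "viability_pct", "excluded")],
           c("extract_id", "viability_caco2_pct", "excluded_ros")),
  setNames(vr[, c("sample_id", "viability_pct", "excluded")],
           c("extract_id", "viability_raw_pct", "excluded_no"))))
write.csv(cellular, "results/cellular.csv", row.names = FALSE)

q <- cellular[cellular$extract_id == "QUERCETIN", ]
cat(sprintf("positive control (quercetin): ROS %.2f%% +- %.2f, NO %.2f%% +- %.2f of stress\n",
            q$ros_pct, q$ros_sd, q$no_pct, q$no_sd))
cat(sprintf("viability gate: %d excluded on Caco-2, %d on RAW264.7\n",
            sum(vc$excluded), sum(vr$excluded)))
if (!is.null(ros$excluded_wells))
  cat(sprintf("%d ROS wells dropped for invalid baselines\n",
              nrow(ros$excluded_wells)))
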