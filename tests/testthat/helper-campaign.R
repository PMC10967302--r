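# Small synthetic campaign used across test files: 24 extracts fit on a
# single cell plate (and a single cell-free plate), keeping whole-pipeline
# tests fast while exercising every stage.
tiny_config <- function(seed = 11, n_extracts = 24, ...) {
  sim_config(n_extracts = n_extracts, seed = seed, ...)
}

make_campaign <- function(config = tiny_config()) {
  truth <- simulate_truth(config)
  dir <- tempfile("campaign")
  emit_raw_plates(truth, config, dir)
  list(truth = truth, dir = dir, files = campaign_paths(dir), config = config)
}

# expected class label under the selectivity rule for generator truth classes
truth_rule_class <- function(truth) {
  ifelse(truth$selectivity_truth %in% c("inactive", "no_increasing"),
         "unclassified", truth$selectivity_truth)
}

# distance of the true levels from every decision boundary of the
# selectivity rule (60/90 thresholds and the 100% direction anchor)
truth_margin <- function(truth) {
  pmin(abs(truth$no_level - 60), abs(truth$ros_level - 60),
       abs(truth$no_level - 90), abs(truth$ros_level - 90),
       abs(truth$no_level - 100), abs(truth$ros_level - 100))
}

write_lines_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
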