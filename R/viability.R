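## Resazurin viability, normalized to the untreated-control mean, and the
## cytotoxicity gate: extracts whose mean viability falls below 80% are
## excluded from the ROS (Caco-2) or NO (RAW264.7) endpoint of that cell
## line. Exclusion is per cell line: an extract cytotoxic to macrophages can
## still be scored on the ROS endpoint, and vice versa.

#' Viability as percent of the untreated control
#'
#' @param f_sample Resorufin fluorescence of the treated well(s), RFU.
#' @param f_control_mean Mean fluorescence of the untreated-control wells.
#' @return `100 * f_sample / f_control_mean`.
#' @export
viability_percent <- function(f_sample, f_control_mean) {
  if (!is.finite(f_control_mean) || f_control_mean <= 0) {
    stop("degenerate control: untreated-control fluorescence mean must be ",
         "positive", call. = FALSE)
  }
  100 * f_sample / f_control_mean
}

#' Cytotoxicity gate
#'
#' Flags extracts whose mean viability is strictly below the threshold
#' (default 80%): a mean of exactly 80.0% is retained. The gate operates on
#' the triplicate mean, not on single wells, and is idempotent.
#'
#' @param viability_pct Named vector of per-extract mean viabilities (%).
#' @param threshold Cytotoxicity threshold in percent (default 80).
#' @return Named logical vector: `TRUE` = excluded (cytotoxic).
#' @export
gate_cytotoxic <- function(viability_pct, threshold = 80) {
  stats::setNames(viability_pct < threshold, names(viability_pct))
}

#' Process a resazurin viability measurement table
#'
#' Per plate, treated wells are normalized to that plate's untreated-control
#' mean; replicate wells are averaged per extract and the cytotoxicity gate
#' applied.
#'
#' @param measurements Measurement table from [read_measurements()] for the
#'   `viability` assay of one cell line.
#' @param threshold Gate threshold in percent (default 80).
#' @return Data frame `sample_id, viability_pct, sd, n, excluded`.
#' @export
process_viability <- function(measurements, threshold = 80) {
  stopifnot(attr(measurements, "assay") == "viability")
  rows <- list()
  for (p in unique(measurements$plate_id)) {
    pm <- measurements[measurements$plate_id == p, , drop = FALSE]
    ctrl <- pm$value[pm$role == "untreated_control"]
    if (!length(ctrl)) {
      stop("anchor error: plate ", p, " lacks an untreated control", call. = FALSE)
    }
    trt <- pm[pm$role %in% c("treatment", "positive_control"), , drop = FALSE]
    trt$pct <- viability_percent(trt$value, mean(ctrl))
    rows[[p]] <- trt[, c("sample_id", "pct")]
  }
  all_trt <- do.call(rbind, rows)
  out <- summarize_by_sample(all_trt$sample_id, all_trt$pct, "viability_pct")
  names(out)[1] <- "sample_id"
  out$excluded <- unname(gate_cytotoxic(out$viability_pct, threshold))
  out
}
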