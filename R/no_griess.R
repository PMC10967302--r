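## Griess nitrite absorbances (548 nm) -> NO level as percent of the LPS
## stress control. The medium-only (DMEM) untreated control serves as the
## zero/blank anchor so reagent background does not inflate the percentages;
## the construction deliberately parallels the two-anchor ROS normalization.

#' Nitrite level as percent of the LPS stress control
#'
#' `100 * (A_sample - A_blank) / (A_stress - A_blank)`. Values above 100
#' indicate NO production beyond the LPS stress control (NO increasers).
#'
#' @param a_sample Sample absorbance(s), AU.
#' @param a_stress_mean Mean absorbance of the LPS stress-control wells.
#' @param a_blank_mean Mean absorbance of the medium-only control wells
#'   (the zero anchor).
#' @return Percent of the stress control.
#' @export
nitrite_percent <- function(a_sample, a_stress_mean, a_blank_mean) {
  span <- a_stress_mean - a_blank_mean
  if (!is.finite(span) || span <= 0) {
    stop("degenerate anchors: stress-control absorbance does not exceed the ",
         "blank (no LPS induction)", call. = FALSE)
  }
  100 * (a_sample - a_blank_mean) / span
}

#' Summarize replicate NO percentages for one extract
#'
#' @param percents Replicate normalized NO percentages (n >= 1).
#' @return List with `mean`, `sd` (sample SD; 0 when n = 1), `n` and the
#'   replicate values (kept for the Dunnett test).
#' @export
summarize_no <- function(percents) {
  n <- length(percents)
  if (n < 1L) stop("need at least one replicate", call. = FALSE)
  list(mean = mean(percents),
       sd = if (n > 1L) stats::sd(percents) else 0,
       n = n,
       replicates = percents)
}

#' Process a Griess NO measurement table
#'
#' Per plate, the untreated (DMEM-only) control mean anchors 0% and the LPS
#' stress-control mean anchors 100%; every treated and positive-control well
#' is rescaled between them and replicates are summarized per sample.
#'
#' @param measurements Measurement table from [read_measurements()] for the
#'   `no_griess` assay.
#' @return Same structure as [process_ros()]: `per_sample` (with column
#'   `no_pct`), `per_well`, `replicates`, `control_replicates`,
#'   `sample_plate`, `excluded_wells` (always `NULL` here).
#' @export
process_no <- function(measurements) {
  stopifnot(attr(measurements, "assay") == "no_griess")
  key <- well_key(measurements)
  per_well <- data.frame(
    plate_id = measurements$plate_id, well = key, role = measurements$role,
    sample_id = measurements$sample_id, value = measurements$value,
    stringsAsFactors = FALSE
  )
  out <- list()
  for (p in unique(per_well$plate_id)) {
    pw <- per_well[per_well$plate_id == p, , drop = FALSE]
    u <- pw$value[pw$role == "untreated_control"]
    s <- pw$value[pw$role == "stress_control"]
    if (!length(s) || !length(u)) {
      stop("anchor error: plate ", p, " lacks a stress or untreated control",
           call. = FALSE)
    }
    pw$pct <- nitrite_percent(pw$value, mean(s), mean(u))
    out[[p]] <- pw
  }
  build_cellular_result(do.call(rbind, out), value_name = "no_pct")
}
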