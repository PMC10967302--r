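## DCF fluorescence time courses (0/15/30/60/90 min) -> normalized ROS
## percentage: background correction, start-value-ratio AUC, and two-anchor
## rescaling (AAPH stress control = 100%, untreated control = 0%).

#' Background-correct a fluorescence trace
#'
#' Subtracts the per-time-point mean of the cell-free blank wells from a raw
#' DCF trace, elementwise. A corrected baseline `f_corrected(0) <= 0` leaves
#' no valid start value to normalize by, so the well must be excluded; this
#' is signalled with an error of class `invalid_baseline` that table-level
#' processing catches and logs.
#'
#' @param time_min Read times (minutes), strictly increasing, starting at 0.
#' @param f_raw Raw fluorescence (RFU) at those times.
#' @param blank_mean Mean blank fluorescence at the same times (RFU). A scalar
#'   is recycled.
#' @return Corrected trace `f_raw - blank_mean`.
#' @export
background_correct <- function(time_min, f_raw, blank_mean) {
  n <- length(time_min)
  if (length(f_raw) != n) {
    stop("trace and time vectors must have the same length", call. = FALSE)
  }
  if (length(blank_mean) == 1L) blank_mean <- rep(blank_mean, n)
  if (length(blank_mean) != n) {
    stop("schedule error: blank series does not cover the trace's time points",
         call. = FALSE)
  }
  f_corr <- f_raw - blank_mean
  if (f_corr[1] <= 0) {
    stop(structure(
      class = c("invalid_baseline", "error", "condition"),
      list(message = sprintf(
        "invalid baseline: corrected fluorescence at t=%g is %g <= 0",
        time_min[1], f_corr[1]), call = NULL)
    ))
  }
  f_corr
}

#' Start-value-normalized area under a fluorescence trace
#'
#' Divides the corrected trace by its starting value (`f_rel(0) = 1`, making
#' the trace dimensionless and insensitive to well-to-well loading) and
#' integrates by the trapezoidal rule over the actual read times.
#'
#' @param time_min Read times (minutes), strictly increasing, length >= 2.
#' @param f_corrected Background-corrected fluorescence, `f_corrected[1] > 0`.
#' @return The relative AUC (unitless x minutes).
#' @export
auc_normalized <- function(time_min, f_corrected) {
  if (length(time_min) < 2L) {
    stop("insufficient data: AUC needs >= 2 time points", call. = FALSE)
  }
  if (length(f_corrected) != length(time_min)) {
    stop("trace and time vectors must have the same length", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("read times must be strictly increasing", call. = FALSE)
  }
  if (f_corrected[1] <= 0) {
    stop("invalid baseline: f_corrected(0) must be positive", call. = FALSE)
  }
  f_rel <- f_corrected / f_corrected[1]
  pracma::trapz(time_min, f_rel)
}

#' Two-anchor percent-of-stress normalization
#'
#' Linearly rescales a sample's relative AUC so the untreated-control mean
#' maps to 0% and the stress-control mean to 100%. Values below 0% (stronger
#' suppression than the untreated baseline) and above 100% (pro-oxidant
#' effect) are permitted.
#'
#' @param auc_sample Sample AUC(s).
#' @param auc_untreated_mean Mean AUC of the untreated-control wells.
#' @param auc_stress_mean Mean AUC of the stress-control wells.
#' @return Percent of the stress-induced increase.
#' @export
normalize_two_anchor <- function(auc_sample, auc_untreated_mean, auc_stress_mean) {
  span <- auc_stress_mean - auc_untreated_mean
  if (!is.finite(span) || span == 0) {
    stop("degenerate anchors: stress and untreated AUC means coincide ",
         "(stress induction failed)", call. = FALSE)
  }
  100 * (auc_sample - auc_untreated_mean) / span
}

#' Summarize replicate ROS percentages for one extract
#'
#' @param percents Replicate normalized ROS percentages (n >= 1).
#' @return List with `mean`, `sd` (sample SD; 0 when n = 1), `n` and the
#'   replicate values (kept for the Dunnett test).
#' @export
summarize_ros <- function(percents) {
  n <- length(percents)
  if (n < 1L) stop("need at least one replicate", call. = FALSE)
  list(mean = mean(percents),
       sd = if (n > 1L) stats::sd(percents) else 0,
       n = n,
       replicates = percents)
}

#' Process a DCF ROS measurement table
#'
#' Runs the full chain per plate: per-time blank means, background correction,
#' start-value-normalized trapezoidal AUC per well, two-anchor normalization
#' against that plate's untreated and AAPH stress controls, and triplicate
#' summaries per sample. Wells whose corrected baseline is not positive are
#' excluded and logged, reducing the replicate count rather than being
#' imputed. Plates without blank wells are processed without background
#' correction, with a warning.
#'
#' @param measurements Measurement table from [read_measurements()] for the
#'   `ros_dcf` assay.
#' @return List with `per_sample` (data frame `sample_id, ros_pct, sd, n, role`),
#'   `per_well` (well-level AUCs and percents, incl. controls),
#'   `replicates` (named list of replicate percent vectors, treatments and
#'   positive controls), `control_replicates` (named list per plate: stress
#'   well percents) and `excluded_wells` (log of dropped wells).
#' @export
process_ros <- function(measurements) {
  stopifnot(attr(measurements, "assay") == "ros_dcf")
  key <- well_key(measurements)
  wells <- list(); dropped <- list()
  for (p in unique(measurements$plate_id)) {
    pm <- measurements[measurements$plate_id == p, , drop = FALSE]
    pk <- key[measurements$plate_id == p]
    times <- sort(unique(pm$time_min))
    blanks <- pm[pm$role == "blank", , drop = FALSE]
    if (nrow(blanks)) {
      blank_mean <- vapply(times, function(t) mean(blanks$value[blanks$time_min == t]),
                           numeric(1))
    } else {
      warning("plate ", p, ": no blank wells; skipping background correction ",
              "(two-anchor normalization cancels shared offsets only approximately)",
              call. = FALSE)
      blank_mean <- rep(0, length(times))
    }
    for (k in unique(pk[pm$role != "blank"])) {
      w <- pm[pk == k, , drop = FALSE]
      w <- w[order(w$time_min), , drop = FALSE]
      auc <- tryCatch({
        f_corr <- background_correct(w$time_min, w$value,
                                     blank_mean[match(w$time_min, times)])
        auc_normalized(w$time_min, f_corr)
      }, invalid_baseline = function(e) {
        dropped[[length(dropped) + 1L]] <<- data.frame(
          plate_id = p, well = k, reason = conditionMessage(e),
          stringsAsFactors = FALSE)
        NA_real_
      })
      if (!is.na(auc)) {
        wells[[length(wells) + 1L]] <- data.frame(
          plate_id = p, well = k, role = w$role[1],
          sample_id = if (is.na(w$sample_id[1])) NA_character_ else w$sample_id[1],
          auc_rel = auc, stringsAsFactors = FALSE)
      }
    }
  }
  per_well <- do.call(rbind, wells)
  anchored <- anchor_normalize_wells(per_well, value_col = "auc_rel")
  build_cellular_result(anchored, value_name = "ros_pct",
                        excluded_wells = if (length(dropped)) do.call(rbind, dropped)
                        else NULL)
}

## Per plate, rescale a well-level statistic to percent of stress control
## (untreated mean -> 0, stress mean -> 100).
anchor_normalize_wells <- function(per_well, value_col) {
  out <- list()
  for (p in unique(per_well$plate_id)) {
    pw <- per_well[per_well$plate_id == p, , drop = FALSE]
    u <- pw[[value_col]][pw$role == "untreated_control"]
    s <- pw[[value_col]][pw$role == "stress_control"]
    if (!length(s) || !length(u)) {
      stop("anchor error: plate ", p, " lacks a stress or untreated control",
           call. = FALSE)
    }
    pw$pct <- normalize_two_anchor(pw[[value_col]], mean(u), mean(s))
    out[[p]] <- pw
  }
  do.call(rbind, out)
}

## Shared tail of process_ros()/process_no(): per-sample summaries plus
## replicate bookkeeping for the Dunnett test.
build_cellular_result <- function(per_well, value_name, excluded_wells = NULL) {
  trt <- per_well[per_well$role %in% c("treatment", "positive_control"), , drop = FALSE]
  smry <- summarize_by_sample(trt$sample_id, trt$pct, value_name)
  names(smry)[1] <- "sample_id"
  smry$role <- vapply(smry$sample_id, function(i)
    trt$role[trt$sample_id == i][1], character(1))
  replicates <- split(trt$pct, trt$sample_id)
  ctrl <- per_well[per_well$role == "stress_control", , drop = FALSE]
  control_replicates <- split(ctrl$pct, ctrl$plate_id)
  sample_plate <- vapply(split(trt$plate_id, trt$sample_id), `[`, character(1), 1)
  rownames(smry) <- NULL
  list(per_sample = smry, per_well = per_well, replicates = replicates,
       control_replicates = control_replicates, sample_plate = sample_plate,
       excluded_wells = excluded_wells)
}
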