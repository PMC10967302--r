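## End-to-end orchestration of one screening campaign:
## calibrate (TPC, FRAP) -> normalize (ROS, NO) -> gate (viability) ->
## call (Dunnett) -> classify (selectivity) -> correlate (Spearman).

#' Analysis configuration for a screening run
#'
#' @param alpha Two-sided significance level for the Dunnett hit calls.
#' @param viability_threshold Cytotoxicity gate in percent (strictly below
#'   excludes).
#' @param tpc_dilution,frap_dilution,cell_dilution Fold dilutions of the
#'   extracts in the respective reactions.
#' @param frap_delta_tol FRAP kinetic plateau tolerance (AU).
#' @param ros_schedule Required DCF read schedule in minutes.
#' @return A `screen_config` list.
#' @export
screen_config <- function(alpha = 0.05, viability_threshold = 80,
                          tpc_dilution = 17, frap_dilution = 31,
                          cell_dilution = 200, frap_delta_tol = 0.005,
                          ros_schedule = c(0, 15, 30, 60, 90)) {
  structure(list(alpha = alpha, viability_threshold = viability_threshold,
                 tpc_dilution = tpc_dilution, frap_dilution = frap_dilution,
                 cell_dilution = cell_dilution, frap_delta_tol = frap_delta_tol,
                 ros_schedule = ros_schedule),
            class = "screen_config")
}

#' Standard file layout of an emitted campaign directory
#'
#' @param dir Directory written by [emit_raw_plates()].
#' @return Named list of paths (`<assay>_map` / `<assay>_meas`), with entries
#'   for files that exist.
#' @export
campaign_paths <- function(dir) {
  assays <- c("tpc", "frap", "ros_dcf", "no_griess",
              "viability_caco2", "viability_raw")
  out <- list()
  for (a in assays) {
    mp <- file.path(dir, paste0("plate_map_", a, ".csv"))
    ms <- file.path(dir, paste0("measurements_", a, ".csv"))
    if (file.exists(mp) && file.exists(ms)) {
      out[[paste0(a, "_map")]] <- mp
      out[[paste0(a, "_meas")]] <- ms
    }
  }
  out
}

#' Run the full screening analysis
#'
#' Reads every available assay's plate map and measurements, quantifies TPC
#' (mg GAE/L) and FRAP (umol TE/L) through per-plate standard curves,
#' normalizes the DCF ROS and Griess NO endpoints to percent of stress
#' control, applies the per-cell-line viability gate, calls hits with the
#' per-plate Dunnett test, classifies selectivity, and computes Spearman
#' correlations across all available endpoint pairs on pairwise-complete,
#' non-excluded extracts. Assays may be omitted; downstream outputs degrade
#' gracefully (empty columns, fewer correlation pairs).
#'
#' @param files Named list of file paths as produced by [campaign_paths()]:
#'   entries `tpc_map`, `tpc_meas`, `frap_map`, `frap_meas`, `ros_dcf_map`,
#'   `ros_dcf_meas`, `no_griess_map`, `no_griess_meas`, `viability_caco2_*`,
#'   `viability_raw_*`. Any assay pair may be missing.
#' @param config A [screen_config()].
#' @param outdir Optional output directory; when given, writes `results.csv`
#'   (fixed column order, see [write_results()]), `correlations.csv` and
#'   `report.txt`.
#' @return List with `results` (per-extract table), `correlations`,
#'   `report` (named list of counts), and the intermediate stage outputs
#'   (`tpc`, `frap`, `ros`, `no`, `viability_caco2`, `viability_raw`,
#'   `hits_ros`, `hits_no`).
#' @export
run_screen <- function(files, config = screen_config(), outdir = NULL) {
  have <- function(a) !is.null(files[[paste0(a, "_map")]])
  load_assay <- function(a, schedule = NULL, dilution = 1) {
    map <- read_plate_map(files[[paste0(a, "_map")]])
    read_measurements(files[[paste0(a, "_meas")]], map,
                      read_schedule = schedule, dilution_factor = dilution)
  }

  tpc <- frap <- ros <- no <- viab_c <- viab_r <- NULL
  hits_ros <- hits_no <- NULL

  if (have("tpc")) {
    tpc <- quantify_cellfree(load_assay("tpc", dilution = config$tpc_dilution),
                             dilution_factor = config$tpc_dilution)
  }
  if (have("frap")) {
    frap <- quantify_cellfree(load_assay("frap", dilution = config$frap_dilution),
                              dilution_factor = config$frap_dilution,
                              delta_tol = config$frap_delta_tol)
  }
  if (have("viability_caco2")) {
    viab_c <- process_viability(load_assay("viability_caco2",
                                           dilution = config$cell_dilution),
                                threshold = config$viability_threshold)
  }
  if (have("viability_raw")) {
    viab_r <- process_viability(load_assay("viability_raw",
                                           dilution = config$cell_dilution),
                                threshold = config$viability_threshold)
  }
  if (have("ros_dcf")) {
    ros <- process_ros(load_assay("ros_dcf", schedule = config$ros_schedule,
                                  dilution = config$cell_dilution))
    hits_ros <- call_hits(ros, "ros", alpha = config$alpha)
  }
  if (have("no_griess")) {
    no <- process_no(load_assay("no_griess", dilution = config$cell_dilution))
    hits_no <- call_hits(no, "no", alpha = config$alpha)
  }

  ids <- sort(unique(c(
    if (!is.null(tpc)) tpc$per_extract$extract_id,
    if (!is.null(frap)) frap$per_extract$extract_id,
    if (!is.null(hits_ros)) hits_ros$sample_id,
    if (!is.null(hits_no)) hits_no$sample_id
  )))

  pull <- function(df, key, col, default = NA_real_) {
    if (is.null(df)) return(rep(default, length(ids)))
    df[[col]][match(ids, df[[key]])]
  }

  excluded_ros <- pull(viab_c, "sample_id", "excluded", NA)
  excluded_no <- pull(viab_r, "sample_id", "excluded", NA)
  gate_ros <- !is.na(excluded_ros) & excluded_ros
  gate_no <- !is.na(excluded_no) & excluded_no

  results <- data.frame(
    extract_id = ids,
    tpc_gae_mg_L = pull(tpc$per_extract, "extract_id", "conc"),
    frap_te_umol_L = pull(frap$per_extract, "extract_id", "conc"),
    ros_pct = pull(hits_ros, "sample_id", "mean_pct"),
    ros_sd = if (is.null(ros)) NA_real_ else
      ros$per_sample$sd[match(ids, ros$per_sample$sample_id)],
    no_pct = pull(hits_no, "sample_id", "mean_pct"),
    no_sd = if (is.null(no)) NA_real_ else
      no$per_sample$sd[match(ids, no$per_sample$sample_id)],
    viability_caco2_pct = pull(viab_c, "sample_id", "viability_pct"),
    viability_raw_pct = pull(viab_r, "sample_id", "viability_pct"),
    excluded_ros = excluded_ros,
    excluded_no = excluded_no,
    stringsAsFactors = FALSE
  )
  dir_of <- function(hits) if (is.null(hits)) rep(NA_character_, length(ids)) else
    hits$direction[match(ids, hits$sample_id)]
  ros_dir <- dir_of(hits_ros); no_dir <- dir_of(hits_no)
  results$sig_ros <- ifelse(gate_ros, NA, ros_dir != "none")
  results$sig_no <- ifelse(gate_no, NA, no_dir != "none")
  results$reduction30_ros <- ifelse(gate_ros, NA, results$ros_pct <= 70)
  results$reduction30_no <- ifelse(gate_no, NA, results$no_pct <= 70)
  # gated extracts carry no usable cellular endpoint
  results$ros_pct[gate_ros] <- NA
  results$ros_sd[gate_ros] <- NA
  results$no_pct[gate_no] <- NA
  results$no_sd[gate_no] <- NA
  results$selectivity <- classify_selectivity(
    no_pct = results$no_pct, ros_pct = results$ros_pct,
    no_sig_decrease = !is.na(no_dir) & no_dir == "decrease" & !gate_no,
    ros_sig_decrease = !is.na(ros_dir) & ros_dir == "decrease" & !gate_ros,
    excluded = gate_ros | gate_no
  )
  if (is.null(hits_ros) || is.null(hits_no)) {
    results$selectivity <- NA_character_
  }

  correlations <- screen_correlations(results)
  report <- screen_report(results, ros = ros, no = no)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(outdir, "results.csv"))
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    writeLines(format_report(report), file.path(outdir, "report.txt"))
  }

  list(results = results, correlations = correlations, report = report,
       tpc = tpc, frap = frap, ros = ros, no = no,
       viability_caco2 = viab_c, viability_raw = viab_r,
       hits_ros = hits_ros, hits_no = hits_no)
}

#' Cross-assay Spearman correlations
#'
#' Correlates every available pair of per-extract endpoint means on
#' pairwise-complete, non-excluded extracts (gated extracts carry `NA` on
#' their cellular endpoints and drop out of any pair involving them).
#'
#' @param results Per-extract results table from [run_screen()].
#' @return Data frame `pair, r_s, p_value, n`.
#' @export
screen_correlations <- function(results) {
  endpoints <- c(tpc = "tpc_gae_mg_L", frap = "frap_te_umol_L",
                 ros = "ros_pct", no = "no_pct")
  avail <- names(endpoints)[vapply(endpoints, function(cn)
    sum(is.finite(results[[cn]])) >= 3, logical(1))]
  rows <- list()
  if (length(avail) >= 2) {
    combos <- utils::combn(avail, 2)
    for (j in seq_len(ncol(combos))) {
      a <- combos[1, j]; b <- combos[2, j]
      ct <- spearman_cor(results[[endpoints[a]]], results[[endpoints[b]]])
      rows[[j]] <- data.frame(pair = paste(a, b, sep = "_"),
                              r_s = ct$r_s, p_value = ct$p_value, n = ct$n,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pair = character(), r_s = numeric(),
                      p_value = numeric(), n = integer()))
  }
  do.call(rbind, rows)
}

#' Summary counts of a screening run
#'
#' @param results Per-extract results table from [run_screen()].
#' @param ros,no Optional stage outputs of [process_ros()]/[process_no()]
#'   (used to report the positive-control level).
#' @return Named list of counts mirroring the screen's reporting structure:
#'   exclusions, significant decreases/increases, >=30% reductions,
#'   selectivity class sizes, positive-control means.
#' @export
screen_report <- function(results, ros = NULL, no = NULL) {
  cnt <- function(x) sum(x, na.rm = TRUE)
  pos_level <- function(stage) {
    if (is.null(stage)) return(NA_real_)
    ps <- stage$per_sample
    v <- ps[[setdiff(names(ps), c("sample_id", "sd", "n", "role"))[1]]]
    v[ps$role == "positive_control"][1]
  }
  ros_dir <- ifelse(is.na(results$sig_ros), "none",
                    ifelse(results$sig_ros & results$ros_pct < 100, "decrease",
                           ifelse(results$sig_ros & results$ros_pct > 100,
                                  "increase", "none")))
  no_dir <- ifelse(is.na(results$sig_no), "none",
                   ifelse(results$sig_no & results$no_pct < 100, "decrease",
                          ifelse(results$sig_no & results$no_pct > 100,
                                 "increase", "none")))
  list(
    n_extracts = nrow(results),
    n_excluded_caco2 = cnt(results$excluded_ros),
    n_excluded_raw = cnt(results$excluded_no),
    n_sig_ros_decrease = cnt(ros_dir == "decrease"),
    n_sig_ros_increase = cnt(ros_dir == "increase"),
    n_reduction30_ros = cnt(results$reduction30_ros),
    n_sig_no_decrease = cnt(no_dir == "decrease"),
    n_sig_no_increase = cnt(no_dir == "increase"),
    n_reduction30_no = cnt(results$reduction30_no),
    selectivity_counts = table(factor(results$selectivity,
                                      levels = SELECTIVITY_CLASSES)),
    quercetin_ros_pct = pos_level(ros),
    quercetin_no_pct = pos_level(no)
  )
}

format_report <- function(report) {
  sel <- report$selectivity_counts
  c(
    sprintf("extracts screened: %d", report$n_extracts),
    sprintf("excluded by viability gate: Caco-2 %d, RAW264.7 %d",
            report$n_excluded_caco2, report$n_excluded_raw),
    sprintf("ROS: %d significant decreases, %d increases, %d with >=30%% reduction",
            report$n_sig_ros_decrease, report$n_sig_ros_increase,
            report$n_reduction30_ros),
    sprintf("NO: %d significant decreases, %d increases, %d with >=30%% reduction",
            report$n_sig_no_decrease, report$n_sig_no_increase,
            report$n_reduction30_no),
    sprintf("selectivity: %s",
            paste(sprintf("%s=%d", names(sel), as.integer(sel)), collapse = ", ")),
    sprintf("positive control (quercetin): ROS %.2f%%, NO %.2f%% of stress",
            report$quercetin_ros_pct, report$quercetin_no_pct)
  )
}
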