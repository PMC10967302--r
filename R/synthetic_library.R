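## Synthetic screening campaign: a ground-truth extract library with the
## statistical structure the analysis assumes (rank-correlated TPC/FRAP,
## selectivity classes with calibrated frequencies, a small cytotoxic
## fraction), plus raw plate files for all five assays obtained by inverting
## each assay's measurement model. Everything is deterministic given the
## config seed, so the campaign doubles as a reproducible end-to-end fixture.

#' Configuration of a synthetic screening campaign
#'
#' Defaults emulate the study conditions of a 375-extract library screened in
#' triplicate: class counts calibrated so that roughly 34 extracts reduce ROS
#' to <= 70% and 57 reduce NO to <= 70% of the stress control, about 40
#' increase NO, and 3 (Caco-2) / 15 (RAW264.7) extracts are cytotoxic;
#' TPC-FRAP rank correlation targeted at 0.857 and the cell-free vs cellular
#' rank correlations at about -0.44 (ROS) and -0.46 (NO); 2% measurement
#' noise CV; published positive-control levels (quercetin: ROS 3.6% of
#' stress, NO 66.5% of stress) reused as generator constants.
#'
#' @param n_extracts Library size (default 375).
#' @param seed Mandatory RNG seed.
#' @param n_reps Replicate wells per sample (default 3).
#' @param noise_cv Multiplicative measurement noise CV (default 0.02).
#' @param target_rs Named rank-correlation targets
#'   (`tpc_frap`, `tpc_ros`, `tpc_no`).
#' @param class_props Named proportions of the selectivity classes
#'   `dual`, `ros_selective`, `no_selective`, `no_increasing` (the remainder
#'   is inactive).
#' @param cytotox_props Named proportions of cytotoxic extracts per cell line
#'   (`caco2`, `raw`).
#' @param ... Overrides for any other generator constant (see the function
#'   body for the full list: latent-phenolic scale, standard-curve and
#'   kinetic parameters, anchors, plate capacities).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_extracts = 375, seed = 1, n_reps = 3,
                       noise_cv = 0.02,
                       target_rs = c(tpc_frap = 0.857, tpc_ros = -0.44,
                                     tpc_no = -0.46),
                       class_props = c(dual = 20 / 375, ros_selective = 16 / 375,
                                       no_selective = 38 / 375,
                                       no_increasing = 40 / 375),
                       cytotox_props = c(caco2 = 3 / 375, raw = 15 / 375),
                       ...) {
  if (any(abs(target_rs) > 1)) {
    stop("infeasible correlation target: |r_s| > 1", call. = FALSE)
  }
  if (any(class_props < 0) || sum(class_props) > 1 || any(cytotox_props < 0)) {
    stop("class proportions must be in [0,1] and sum to at most 1", call. = FALSE)
  }
  cfg <- list(
    n_extracts = n_extracts, seed = as.integer(seed), n_reps = n_reps,
    noise_cv = noise_cv, target_rs = target_rs,
    class_props = class_props, cytotox_props = cytotox_props,
    # latent phenolic content P ~ lognormal; TPC = tpc_scale * P * noise,
    # FRAP = frap_scale * P^frap_gamma * noise
    p_sdlog = 0.8, tpc_scale = 800, frap_scale = 4000, frap_gamma = 1.1,
    # monotone link of cellular levels to P: copula strength within class,
    # and the tilt with which active classes are drawn from high-P extracts
    rho_within = c(ros = 0.65, no = 0.48), kappa_active = 1.6,
    kappa_increase = 0.9, rho_inactive = c(ros = 0.55, no = 0.38),
    # class-conditional level distributions (% of stress control)
    class_levels = list(
      dual          = list(ros = c(48, 10), no = c(45, 10)),
      ros_selective = list(ros = c(55, 10), no = c(100, 5)),
      no_selective  = list(ros = c(98, 4),  no = c(40, 15)),
      no_increasing = list(ros = c(96, 4),  no = c(125, 12)),
      inactive      = list(ros = c(95, 4),  no = c(96, 4))
    ),
    # positive control (quercetin) generator constants
    quercetin_ros_level = 3.6, quercetin_no_level = 66.5,
    # standard curves (blank-corrected absorbance = slope * conc + intercept)
    tpc_standards = seq(0, 500, by = 100), tpc_slope = 9e-4,
    tpc_intercept = 0.005, tpc_blank_au = 0.05, tpc_noise_au = 0.002,
    frap_standards = seq(0, 1000, by = 200), frap_slope = 6e-4,
    frap_intercept = 0.005, frap_blank_au = 0.04, frap_noise_au = 3e-4,
    frap_read_times = 0:12, frap_tau_range = c(0.8, 1.5),
    # dilution of the extracts in each reaction
    tpc_dilution = 17, frap_dilution = 31, cell_dilution = 200,
    # DCF kinetics: f(t) = blank + F0 * (1 + r * t), r = basal + stress*(level/100)
    ros_schedule = c(0, 15, 30, 60, 90), ros_f0 = 5000, ros_blank_rfu = 200,
    ros_r_basal = 0.002, ros_r_stress = 0.02, ros_f0_jitter = 0.1,
    ros_read_cv = 0.005,
    # biological replicate-to-replicate spread of the cellular response
    # (percent-of-stress units per well)
    rep_sd_ros = 3, rep_sd_no = 2.5,
    # Griess: A = dmem + span * (level/100)
    griess_dmem_au = 0.07, griess_span_au = 0.5, griess_noise_au = 0.002,
    # resazurin viability
    viab_control_rfu = 20000, viab_mean = 100, viab_sd = 3,
    viab_cytotoxic_mean = 60, viab_cytotoxic_sd = 5, viab_threshold = 80,
    # plate capacities (treatments per 96-well plate after controls)
    cellfree_per_plate = 25, cell_per_plate = 28
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "sim_config"
  cfg
}

## Multiplicative log-noise SD that dilutes a shared lognormal latent to a
## target Spearman correlation (via the bivariate-normal identity
## rho = 2 sin(pi * r_s / 6)).
solve_link_noise <- function(r_s, sigma, gamma) {
  if (r_s >= 1) return(0)
  rho <- 2 * sin(pi * r_s / 6)
  f <- function(s2) gamma * sigma^2 /
    sqrt((sigma^2 + s2) * (gamma^2 * sigma^2 + s2)) - rho
  sqrt(stats::uniroot(f, c(1e-9, 100))$root)
}

#' Simulate the ground truth of a synthetic extract library
#'
#' Draws a positive log-normal phenolic latent `P` per extract; TPC and FRAP
#' are noisy monotone functions of `P` with the multiplicative noise solved
#' analytically so the configured TPC-FRAP rank correlation is hit in
#' expectation. Selectivity classes are assigned with configured frequencies,
#' active (decreaser) classes drawn preferentially from high-`P` extracts and
#' NO increasers from low-`P` extracts; within each class the cellular levels
#' follow a Gaussian-copula monotone link to `P`, so the configured TPC-ROS
#' and TPC-NO rank correlations are approached. A small cytotoxic fraction is
#' drawn (from the inactive class, keeping the calibrated active-class counts
#' interpretable). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per extract: `extract_id`,
#'   `phenolic_latent`, `true_tpc` (mg GAE/L), `true_frap` (umol TE/L),
#'   `ros_level` / `no_level` (true normalized % of stress control),
#'   `ros_inhibition` / `no_inhibition` (1 - level/100), `selectivity_truth`,
#'   `cytotoxic_caco2`, `cytotoxic_raw`.
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_extracts
  sigma <- config$p_sdlog
  P <- stats::rlnorm(n, 0, sigma)
  z <- log(P) / sigma

  s_link <- solve_link_noise(config$target_rs[["tpc_frap"]], sigma,
                             config$frap_gamma)
  true_tpc <- config$tpc_scale * P * exp(stats::rnorm(n, 0, s_link))
  true_frap <- config$frap_scale * P^config$frap_gamma *
    exp(stats::rnorm(n, 0, s_link))

  counts <- round(config$class_props * n)
  n_active <- sum(counts[c("dual", "ros_selective", "no_selective")])
  if (n_active + counts[["no_increasing"]] > n) {
    stop("class proportions exceed the library size", call. = FALSE)
  }
  cls <- rep("inactive", n)
  active_idx <- sample.int(n, n_active, prob = exp(config$kappa_active * z))
  cls[active_idx] <- sample(rep(c("dual", "ros_selective", "no_selective"),
                                counts[c("dual", "ros_selective", "no_selective")]))
  rest <- which(cls == "inactive")
  inc_idx <- rest[sample.int(length(rest), counts[["no_increasing"]],
                             prob = exp(-config$kappa_increase * z[rest]))]
  cls[inc_idx] <- "no_increasing"

  draw_level <- function(endpoint) {
    rho_w <- ifelse(cls %in% c("inactive", "no_increasing"),
                    config$rho_inactive[[endpoint]],
                    config$rho_within[[endpoint]])
    u <- stats::pnorm(rho_w * z + sqrt(1 - rho_w^2) * stats::rnorm(n))
    vapply(seq_len(n), function(i) {
      par <- config$class_levels[[cls[i]]][[endpoint]]
      stats::qnorm(1 - u[i], mean = par[1], sd = par[2])
    }, numeric(1))
  }
  ros_level <- draw_level("ros")
  no_level <- draw_level("no")

  inact <- which(cls == "inactive")
  cyt_c <- inact[sample.int(length(inact),
                            round(config$cytotox_props[["caco2"]] * n))]
  cyt_r <- inact[sample.int(length(inact),
                            round(config$cytotox_props[["raw"]] * n))]

  data.frame(
    extract_id = sprintf("EXT%04d", seq_len(n)),
    phenolic_latent = P,
    true_tpc = true_tpc,
    true_frap = true_frap,
    ros_level = ros_level,
    no_level = no_level,
    ros_inhibition = 1 - ros_level / 100,
    no_inhibition = 1 - no_level / 100,
    selectivity_truth = cls,
    cytotoxic_caco2 = seq_len(n) %in% cyt_c,
    cytotoxic_raw = seq_len(n) %in% cyt_r,
    stringsAsFactors = FALSE
  )
}

## ---- plate layout -----------------------------------------------------

## Column-major well sequence A1, B1, ..., H1, A2, ...
well_sequence <- function(n) {
  stopifnot(n <= 96)
  idx <- seq_len(n) - 1L
  data.frame(row = WELL_ROWS[idx %% 8L + 1L], col = idx %/% 8L + 1L,
             stringsAsFactors = FALSE)
}

## One plate map block: fixed-role wells first, then n_reps consecutive
## treatment wells per extract.
plate_block <- function(plate_id, fixed_roles, extract_ids, n_reps,
                        standard_concs = NULL) {
  roles <- character(); concs <- numeric(); ids <- character()
  for (r in fixed_roles) {
    if (r == "standard") {
      for (cc in standard_concs) {
        roles <- c(roles, rep("standard", n_reps))
        concs <- c(concs, rep(cc, n_reps))
        ids <- c(ids, rep(NA_character_, n_reps))
      }
    } else {
      roles <- c(roles, rep(r, n_reps))
      concs <- c(concs, rep(NA_real_, n_reps))
      ids <- c(ids, rep(if (r == "positive_control") "QUERCETIN"
                        else NA_character_, n_reps))
    }
  }
  for (e in extract_ids) {
    roles <- c(roles, rep("treatment", n_reps))
    concs <- c(concs, rep(NA_real_, n_reps))
    ids <- c(ids, rep(e, n_reps))
  }
  wells <- well_sequence(length(roles))
  data.frame(plate_id = plate_id, row = wells$row, col = wells$col,
             role = roles, standard_conc = concs, sample_id = ids,
             stringsAsFactors = FALSE)
}

build_plate_map <- function(prefix, extract_ids, per_plate, fixed_roles,
                            n_reps, standard_concs = NULL) {
  chunks <- split(extract_ids, ceiling(seq_along(extract_ids) / per_plate))
  do.call(rbind, lapply(seq_along(chunks), function(i) {
    plate_block(sprintf("%s%02d", prefix, i), fixed_roles, chunks[[i]],
                n_reps, standard_concs)
  }))
}

## ---- raw-signal emission ----------------------------------------------

#' Emit raw plate files for a synthetic campaign
#'
#' Inverts each assay's measurement model to turn the ground truth into raw
#' plate-reader signals with multiplicative measurement noise: standards from
#' the configured curves, extract TPC/FRAP absorbances from inverse
#' calibration at the assay dilution (FRAP as saturating kinetic traces),
#' DCF time courses with linear-in-time fluorescence growth, Griess
#' absorbances proportional to the NO level, and resazurin signals centred at
#' 100% (or 60% for cytotoxic extracts) of the control. Writes one plate-map
#' and one measurement CSV per assay (viability once per cell line) plus
#' `truth.csv`; identical config and seed produce byte-identical files.
#'
#' @param truth Ground truth from [simulate_truth()].
#' @param config The same [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Named list of file paths (invisibly): `<assay>_map` and
#'   `<assay>_meas` for assays `tpc`, `frap`, `ros_dcf`, `no_griess`,
#'   `viability_caco2`, `viability_raw`, plus `truth`.
#' @export
emit_raw_plates <- function(truth, config = sim_config(), outdir) {
  tables <- build_campaign_tables(truth, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (a in names(tables$maps)) {
    mp <- file.path(outdir, paste0("plate_map_", a, ".csv"))
    ms <- file.path(outdir, paste0("measurements_", a, ".csv"))
    map_out <- tables$maps[[a]]
    map_out$standard_conc[is.na(map_out$standard_conc)] <- ""
    map_out$sample_id[is.na(map_out$sample_id)] <- ""
    utils::write.csv(map_out, mp, row.names = FALSE, quote = FALSE)
    meas_out <- tables$meas[[a]]
    meas_out$time_min[is.na(meas_out$time_min)] <- ""
    meas_out$value <- vapply(meas_out$value, format, character(1),
                             digits = 15, scientific = FALSE, trim = TRUE)
    utils::write.csv(meas_out, ms, row.names = FALSE, quote = FALSE)
    paths[[paste0(a, "_map")]] <- mp
    paths[[paste0(a, "_meas")]] <- ms
  }
  tp <- file.path(outdir, "truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE, quote = FALSE)
  paths$truth <- tp
  invisible(paths)
}

#' @rdname emit_raw_plates
#' @return `build_campaign_tables()` returns the same content in memory:
#'   list with `maps` and `meas`, each a named list of data frames.
#' @export
build_campaign_tables <- function(truth, config = sim_config()) {
  set.seed(config$seed + 1L)
  n_reps <- config$n_reps
  cv <- config$noise_cv
  ids <- truth$extract_id
  mnoise <- function(k) 1 + stats::rnorm(k, 0, cv)

  maps <- list(); meas <- list()

  ## -- TPC: endpoint absorbance at 750 nm -------------------------------
  maps$tpc <- build_plate_map("TPC", ids, config$cellfree_per_plate,
                              c("blank", "standard"), n_reps,
                              standard_concs = config$tpc_standards)
  tpc_signal <- function(conc) config$tpc_blank_au + config$tpc_intercept +
    config$tpc_slope * conc
  conc_of <- function(map) ifelse(
    map$role == "blank", 0,
    ifelse(map$role == "standard", map$standard_conc,
           truth$true_tpc[match(map$sample_id, ids)] / config$tpc_dilution))
  m <- maps$tpc
  value <- ifelse(m$role == "blank", config$tpc_blank_au,
                  tpc_signal(conc_of(m))) * mnoise(nrow(m)) +
    stats::rnorm(nrow(m), 0, config$tpc_noise_au)
  meas$tpc <- data.frame(plate_id = m$plate_id, row = m$row, col = m$col,
                         assay = "tpc", time_min = NA_real_, value = value,
                         stringsAsFactors = FALSE)

  ## -- FRAP: kinetic absorbance at 593 nm, saturating to the endpoint ----
  maps$frap <- build_plate_map("FRP", ids, config$cellfree_per_plate,
                               c("blank", "standard"), n_reps,
                               standard_concs = config$frap_standards)
  m <- maps$frap
  conc <- ifelse(
    m$role == "blank", NA_real_,
    ifelse(m$role == "standard", m$standard_conc,
           truth$true_frap[match(m$sample_id, ids)] / config$frap_dilution))
  amp <- ifelse(m$role == "blank", 0,
                (config$frap_intercept + config$frap_slope * conc) *
                  mnoise(nrow(m)))
  tau <- stats::runif(nrow(m), config$frap_tau_range[1], config$frap_tau_range[2])
  tt <- config$frap_read_times
  frap_rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- config$frap_blank_au + amp[i] * (1 - exp(-tt / tau[i])) +
      stats::rnorm(length(tt), 0, config$frap_noise_au)
    data.frame(plate_id = m$plate_id[i], row = m$row[i], col = m$col[i],
               assay = "frap", time_min = tt, value = v,
               stringsAsFactors = FALSE)
  })
  meas$frap <- do.call(rbind, frap_rows)

  ## -- DCF ROS: fluorescence time course in stressed Caco-2 cells --------
  # cytotoxic extracts are measured too; the viability gate excludes them later
  maps$ros_dcf <- build_plate_map(
    "ROS", ids, config$cell_per_plate,
    c("blank", "untreated_control", "stress_control", "positive_control"),
    n_reps)
  m <- maps$ros_dcf
  level <- ifelse(m$role == "treatment",
                  truth$ros_level[match(m$sample_id, ids)],
                  ifelse(m$role == "stress_control", 100,
                         ifelse(m$role == "positive_control",
                                config$quercetin_ros_level, 0)))
  # biological well-to-well spread of the cellular response (not in blanks)
  level <- level + ifelse(m$role == "blank", 0,
                          stats::rnorm(nrow(m), 0, config$rep_sd_ros))
  rate <- config$ros_r_basal + config$ros_r_stress * level / 100
  f0 <- config$ros_f0 *
    stats::runif(nrow(m), 1 - config$ros_f0_jitter, 1 + config$ros_f0_jitter)
  tt <- config$ros_schedule
  ## well-level noise (loading, probe uptake) multiplies the whole trace and
  ## cancels in the start-value ratio; per-read instrument noise does not
  well_factor <- 1 + stats::rnorm(nrow(m), 0, cv)
  ros_rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- if (m$role[i] == "blank") {
      config$ros_blank_rfu * (1 + stats::rnorm(length(tt), 0, config$ros_read_cv))
    } else {
      config$ros_blank_rfu +
        f0[i] * well_factor[i] * (1 + rate[i] * tt) *
          (1 + stats::rnorm(length(tt), 0, config$ros_read_cv))
    }
    data.frame(plate_id = m$plate_id[i], row = m$row[i], col = m$col[i],
               assay = "ros_dcf", time_min = tt, value = v,
               stringsAsFactors = FALSE)
  })
  meas$ros_dcf <- do.call(rbind, ros_rows)

  ## -- Griess NO: endpoint absorbance at 548 nm --------------------------
  maps$no_griess <- build_plate_map(
    "NOG", ids, config$cell_per_plate,
    c("untreated_control", "stress_control", "positive_control"), n_reps)
  m <- maps$no_griess
  level <- ifelse(m$role == "treatment",
                  truth$no_level[match(m$sample_id, ids)],
                  ifelse(m$role == "stress_control", 100,
                         ifelse(m$role == "positive_control",
                                config$quercetin_no_level, 0)))
  level <- level + ifelse(m$role == "untreated_control", 0,
                          stats::rnorm(nrow(m), 0, config$rep_sd_no))
  value <- config$griess_dmem_au +
    config$griess_span_au * (level / 100) * mnoise(nrow(m)) +
    stats::rnorm(nrow(m), 0, config$griess_noise_au)
  meas$no_griess <- data.frame(plate_id = m$plate_id, row = m$row, col = m$col,
                               assay = "no_griess", time_min = NA_real_,
                               value = value, stringsAsFactors = FALSE)

  ## -- resazurin viability, one file per cell line ------------------------
  for (line in c("caco2", "raw")) {
    cyt <- if (line == "caco2") truth$cytotoxic_caco2 else truth$cytotoxic_raw
    viab_true <- stats::setNames(ifelse(
      cyt,
      stats::rnorm(nrow(truth), config$viab_cytotoxic_mean, config$viab_cytotoxic_sd),
      stats::rnorm(nrow(truth), config$viab_mean, config$viab_sd)), ids)
    nm <- paste0("viability_", line)
    maps[[nm]] <- build_plate_map(
      toupper(substr(paste0("V", line), 1, 3)), ids, config$cell_per_plate,
      c("untreated_control", "positive_control"), n_reps)
    m <- maps[[nm]]
    v_pct <- ifelse(m$role == "treatment", viab_true[m$sample_id],
                    ifelse(m$role == "positive_control", config$viab_mean, 100))
    value <- config$viab_control_rfu * (v_pct / 100) * mnoise(nrow(m))
    meas[[nm]] <- data.frame(plate_id = m$plate_id, row = m$row, col = m$col,
                             assay = "viability", time_min = NA_real_,
                             value = value, stringsAsFactors = FALSE)
  }

  list(maps = maps, meas = meas)
}
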