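#' Fit a standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration + intercept`
#' through blank-corrected standard absorbances. Used for the gallic-acid
#' (total phenolic content, mg GAE/L) and Trolox (FRAP, umol TE/L) series.
#' The intercept is left free: it absorbs any residual blank signal that the
#' blank-mean subtraction did not remove.
#'
#' @param concentration Standard concentrations (mg/L gallic acid or umol/L
#'   Trolox). At least two distinct values.
#' @param absorbance Blank-corrected absorbances (AU), same length.
#' @param analyte `"gallic_acid"` or `"trolox"`.
#' @param blank_mean Mean blank absorbance (AU) that was subtracted from the
#'   standards; stored so samples can be corrected identically.
#' @return An object of class `standard_curve`: list with `analyte`, `slope`
#'   (AU per concentration unit), `intercept` (AU), `r_squared`, `blank_mean`,
#'   `n_points`.
#' @export
fit_standard_curve <- function(concentration, absorbance,
                               analyte = c("gallic_acid", "trolox"),
                               blank_mean = 0) {
  analyte <- match.arg(analyte)
  if (length(concentration) != length(absorbance)) {
    stop("concentration and absorbance must have the same length", call. = FALSE)
  }
  if (!all(is.finite(concentration)) || !all(is.finite(absorbance))) {
    stop("standard-curve inputs must be finite", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("degenerate calibration design: need >= 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failure: fitted slope is not positive (", format(slope),
         ")", call. = FALSE)
  }
  fitted_vals <- stats::fitted(fit)
  r2 <- if (stats::var(absorbance) == 0) 1 else stats::cor(fitted_vals, absorbance)^2
  structure(
    list(analyte = analyte, slope = slope, intercept = intercept,
         r_squared = r2, blank_mean = blank_mean,
         n_points = length(unique(concentration))),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  unit <- if (x$analyte == "gallic_acid") "mg/L" else "umol/L"
  cat(sprintf("Standard curve (%s): A = %.6g * C + %.6g  [C in %s]\n",
              x$analyte, x$slope, x$intercept, unit))
  cat(sprintf("  r^2 = %.5f, n = %d concentration levels, blank = %.4g AU\n",
              x$r_squared, x$n_points, x$blank_mean))
  invisible(x)
}

#' Invert a standard curve
#'
#' Converts a blank-corrected sample absorbance to a concentration on the
#' undiluted-extract scale: `dilution_factor * (A - intercept) / slope`.
#' Sub-blank signals yield negative concentrations; they are returned as-is
#' (not clipped) so downstream statistics see unbiased values, and can be
#' flagged by the caller.
#'
#' @param curve A `standard_curve`.
#' @param a_sample Blank-corrected sample absorbance(s), AU.
#' @param dilution_factor Fold dilution of the extract in the reaction
#'   (>= 1); the result is scaled back to the undiluted extract.
#' @return Concentration(s) in the curve's units (mg GAE/L or umol TE/L).
#' @export
absorbance_to_concentration <- function(curve, a_sample, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(a_sample))) {
    stop("sample absorbance must be finite", call. = FALSE)
  }
  if (dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  dilution_factor * (a_sample - curve$intercept) / curve$slope
}

#' Locate the FRAP kinetic endpoint
#'
#' The FRAP reaction is read every minute until the absorbance stops changing.
#' The plateau time is the first read from which every consecutive
#' absorbance difference stays below `delta_tol`; if the trace is flat from
#' the very first pair, the plateau is the first read. If the last pair still
#' changes by `delta_tol` or more, the reaction has not converged and the last
#' read is returned with `converged = FALSE`.
#'
#' @param time_min Read times in minutes, strictly increasing, length >= 2.
#' @param absorbance_au Absorbances at those times (AU).
#' @param delta_tol Plateau tolerance in AU (default 0.005).
#' @return List with `endpoint_au`, `t_plateau` (minutes) and `converged`.
#' @export
frap_endpoint <- function(time_min, absorbance_au, delta_tol = 0.005) {
  n <- length(time_min)
  if (n < 2L) {
    stop("insufficient data: FRAP endpoint needs >= 2 reads", call. = FALSE)
  }
  if (length(absorbance_au) != n) {
    stop("time and absorbance vectors must have the same length", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("read times must be strictly increasing", call. = FALSE)
  }
  quiet <- abs(diff(absorbance_au)) < delta_tol          # pair (i, i+1)
  # first pair index from which all later pairs are quiet
  stable_from <- if (!quiet[n - 1L]) NA_integer_ else {
    run <- rev(cumprod(rev(quiet)))                      # 1 where tail all quiet
    which(run == 1)[1]
  }
  if (is.na(stable_from)) {
    return(list(endpoint_au = absorbance_au[n], t_plateau = time_min[n],
                converged = FALSE))
  }
  idx <- if (stable_from == 1L) 1L else stable_from + 1L
  list(endpoint_au = absorbance_au[idx], t_plateau = time_min[idx],
       converged = TRUE)
}

#' Quantify a cell-free assay from a measurement table
#'
#' Full calibration chain for one campaign's TPC or FRAP files: per plate,
#' the blank mean is computed, a standard curve is fitted on blank-corrected
#' standard absorbances (FRAP standards are first reduced to their kinetic
#' endpoints), and every treatment well is converted to a concentration on
#' the undiluted-extract scale. Replicate wells are averaged per extract.
#'
#' @param measurements Measurement table from [read_measurements()] for the
#'   `tpc` or `frap` assay.
#' @param dilution_factor Fold dilution of the extracts in the reaction
#'   (defaults: 17 for TPC, 31 for FRAP, from the assay volumetrics).
#' @param delta_tol FRAP plateau tolerance in AU (ignored for TPC).
#' @return List with `per_extract` (data frame `extract_id`, `conc`, `sd`,
#'   `n`, `sub_blank` flag for negative concentrations) and `curves` (one
#'   `standard_curve` per plate).
#' @export
quantify_cellfree <- function(measurements, dilution_factor = NULL,
                              delta_tol = 0.005) {
  assay <- attr(measurements, "assay")
  if (!assay %in% c("tpc", "frap")) {
    stop("quantify_cellfree() handles the tpc and frap assays only", call. = FALSE)
  }
  if (is.null(dilution_factor)) {
    dilution_factor <- if (assay == "tpc") 17 else 31
  }
  analyte <- if (assay == "tpc") "gallic_acid" else "trolox"

  well_values <- cellfree_well_values(measurements, assay, delta_tol)

  curves <- list()
  rows <- list()
  for (p in unique(well_values$plate_id)) {
    pw <- well_values[well_values$plate_id == p, , drop = FALSE]
    blank_mean <- mean(pw$value[pw$role == "blank"])
    if (!is.finite(blank_mean)) blank_mean <- 0
    std <- pw[pw$role == "standard", , drop = FALSE]
    if (nrow(std) < 2L) {
      stop("plate ", p, " carries fewer than 2 standard wells", call. = FALSE)
    }
    std_means <- stats::aggregate(value ~ standard_conc, data = std, FUN = mean)
    curve <- fit_standard_curve(std_means$standard_conc,
                                std_means$value - blank_mean,
                                analyte = analyte, blank_mean = blank_mean)
    curves[[p]] <- curve
    trt <- pw[pw$role == "treatment", , drop = FALSE]
    if (nrow(trt)) {
      trt$conc <- absorbance_to_concentration(curve, trt$value - blank_mean,
                                              dilution_factor)
      rows[[p]] <- trt[, c("sample_id", "conc")]
    }
  }
  all_trt <- do.call(rbind, rows)
  per_extract <- summarize_by_sample(all_trt$sample_id, all_trt$conc, "conc")
  per_extract$sub_blank <- per_extract$conc < 0
  list(per_extract = per_extract, curves = curves)
}

## One value per well: raw endpoint absorbance for TPC, kinetic plateau for FRAP.
cellfree_well_values <- function(measurements, assay, delta_tol) {
  if (assay == "tpc") {
    out <- measurements[, c("plate_id", "row", "col", "role",
                            "standard_conc", "sample_id", "value")]
    return(out)
  }
  key <- well_key(measurements)
  first <- !duplicated(key)
  out <- measurements[first, c("plate_id", "row", "col", "role",
                               "standard_conc", "sample_id", "value")]
  out$value <- vapply(key[first], function(k) {
    w <- measurements[key == k, , drop = FALSE]
    frap_endpoint(w$time_min, w$value, delta_tol)$endpoint_au
  }, numeric(1))
  out
}

summarize_by_sample <- function(sample_id, value, value_name = "value") {
  ids <- unique(sample_id)
  out <- data.frame(
    extract_id = ids,
    value = vapply(ids, function(i) mean(value[sample_id == i]), numeric(1)),
    sd = vapply(ids, function(i) {
      v <- value[sample_id == i]
      if (length(v) > 1L) stats::sd(v) else 0
    }, numeric(1)),
    n = vapply(ids, function(i) sum(sample_id == i), integer(1)),
    stringsAsFactors = FALSE
  )
  names(out)[2] <- value_name
  rownames(out) <- NULL
  out
}
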