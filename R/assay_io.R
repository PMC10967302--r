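#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the plate model. A 96-well plate is addressed
## by row letter A-H and column 1-12; every well carries exactly one role.

WELL_ROWS <- LETTERS[1:8]
WELL_COLS <- 1:12

WELL_ROLES <- c(
  "blank", "standard", "untreated_control", "stress_control",
  "positive_control", "treatment"
)

ASSAYS <- c("tpc", "frap", "ros_dcf", "no_griess", "viability")

## Assays whose wells are read repeatedly over time.
KINETIC_ASSAYS <- c("frap", "ros_dcf")

SELECTIVITY_CLASSES <- c(
  "dual", "no_selective", "ros_selective", "unclassified", "excluded"
)

## Fixed column order of the per-extract results table.
RESULT_COLUMNS <- c(
  "extract_id", "tpc_gae_mg_L", "frap_te_umol_L",
  "ros_pct", "ros_sd", "no_pct", "no_sd",
  "viability_caco2_pct", "viability_raw_pct",
  "excluded_ros", "excluded_no", "sig_ros", "sig_no",
  "reduction30_ros", "reduction30_no", "selectivity"
)

#' Read a plate map
#'
#' Parses a plate-map CSV describing the role of every well on one or more
#' 96-well plates. The file must have the header
#' `plate_id,row,col,role,standard_conc,sample_id`. `standard_conc` (mg/L for
#' gallic acid, umol/L for Trolox) must be present exactly when
#' `role == "standard"`; `sample_id` exactly when the role is `treatment` or
#' `positive_control`. Missing optional fields are empty strings, never
#' sentinel numbers.
#'
#' @param path Path to the plate-map CSV (UTF-8, comma separated, dot decimal).
#' @return A data frame with columns `plate_id`, `row`, `col`, `role`,
#'   `standard_conc` (numeric, `NA` where absent) and `sample_id` (`NA_character_`
#'   where absent), canonically sorted by plate, row, column.
#' @export
read_plate_map <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  required <- c("plate_id", "row", "col", "role", "standard_conc", "sample_id")
  if (!all(required %in% names(raw))) {
    stop("plate map '", path, "' must have columns ",
         paste(required, collapse = ","), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_plate_map())
  }
  map <- data.frame(
    plate_id = trimws(raw$plate_id),
    row = trimws(raw$row),
    col = suppressWarnings(as.integer(trimws(raw$col))),
    role = trimws(raw$role),
    standard_conc = suppressWarnings(as.numeric(ifelse(trimws(raw$standard_conc) == "",
                                                       NA, trimws(raw$standard_conc)))),
    sample_id = ifelse(trimws(raw$sample_id) == "", NA_character_, trimws(raw$sample_id)),
    stringsAsFactors = FALSE
  )
  validate_plate_map(map, path)
  canonical_map_order(map)
}

empty_plate_map <- function() {
  data.frame(
    plate_id = character(), row = character(), col = integer(),
    role = character(), standard_conc = numeric(), sample_id = character(),
    stringsAsFactors = FALSE
  )
}

validate_plate_map <- function(map, path = "<plate map>") {
  bad_role <- which(!(map$role %in% WELL_ROLES))
  if (length(bad_role)) {
    stop("unknown role '", map$role[bad_role[1]], "' in ", path,
         " (data row ", bad_role[1], ")", call. = FALSE)
  }
  bad_row <- which(!(map$row %in% WELL_ROWS))
  if (length(bad_row)) {
    stop("well row must be a letter A-H; got '", map$row[bad_row[1]],
         "' in ", path, " (data row ", bad_row[1], ")", call. = FALSE)
  }
  bad_col <- which(is.na(map$col) | map$col < 1L | map$col > 12L)
  if (length(bad_col)) {
    stop("well column must be an integer 1-12 in ", path,
         " (data row ", bad_col[1], ")", call. = FALSE)
  }
  key <- well_key(map)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate well address ", key[dup[1]], " in ", path, call. = FALSE)
  }
  is_std <- map$role == "standard"
  if (any(is_std & is.na(map$standard_conc))) {
    stop("standard wells must carry standard_conc in ", path, call. = FALSE)
  }
  if (any(!is_std & !is.na(map$standard_conc))) {
    stop("standard_conc given for a non-standard well in ", path, call. = FALSE)
  }
  if (any(map$standard_conc[is_std] < 0, na.rm = TRUE)) {
    stop("standard_conc must be non-negative in ", path, call. = FALSE)
  }
  needs_id <- map$role %in% c("treatment", "positive_control")
  if (any(needs_id & is.na(map$sample_id))) {
    stop("treatment/positive_control wells must carry sample_id in ", path,
         call. = FALSE)
  }
  if (any(!needs_id & !is.na(map$sample_id))) {
    stop("sample_id given for a well that takes none in ", path, call. = FALSE)
  }
  invisible(map)
}

well_key <- function(df) paste(df$plate_id, df$row, df$col, sep = ":")

canonical_map_order <- function(df) {
  ord <- order(df$plate_id, match(df$row, WELL_ROWS), df$col)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read long-format plate-reader measurements
#'
#' Parses a measurement CSV with header `plate_id,row,col,assay,time_min,value`
#' and joins every reading to its role through the plate map. All rows of one
#' file must belong to a single assay. For kinetic assays a read schedule can
#' be enforced: every well must then have been read at exactly the scheduled
#' times.
#'
#' @param path Path to the measurements CSV.
#' @param plate_map Plate map as returned by [read_plate_map()], covering every
#'   address in the file.
#' @param read_schedule Optional numeric vector of required read times in
#'   minutes (e.g. `c(0, 15, 30, 60, 90)` for the DCF assay). When given, a
#'   missing scheduled time point is an error naming the well and time.
#' @param dilution_factor Dilution applied to the extracts before the assay
#'   (stored as metadata; default 200, the 1:200 dilution of the cell assays).
#' @return A data frame (one row per reading) with columns `plate_id`, `row`,
#'   `col`, `assay`, `time_min`, `value`, `role`, `standard_conc`, `sample_id`,
#'   canonically sorted by plate, well and time, with attributes `assay`,
#'   `dilution_factor` and `read_schedule`.
#' @export
read_measurements <- function(path, plate_map, read_schedule = NULL,
                              dilution_factor = 200) {
  raw <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  required <- c("plate_id", "row", "col", "assay", "time_min", "value")
  if (!all(required %in% names(raw))) {
    stop("measurement file '", path, "' must have columns ",
         paste(required, collapse = ","), call. = FALSE)
  }
  meas <- data.frame(
    plate_id = trimws(raw$plate_id),
    row = trimws(raw$row),
    col = suppressWarnings(as.integer(trimws(raw$col))),
    assay = trimws(raw$assay),
    time_min = suppressWarnings(as.numeric(ifelse(trimws(raw$time_min) == "",
                                                  NA, trimws(raw$time_min)))),
    value = suppressWarnings(as.numeric(trimws(raw$value))),
    stringsAsFactors = FALSE
  )
  if (nrow(meas)) {
    bad_assay <- which(!(meas$assay %in% ASSAYS))
    if (length(bad_assay)) {
      stop("unknown assay '", meas$assay[bad_assay[1]], "' in ", path,
           " (data row ", bad_assay[1], ")", call. = FALSE)
    }
    if (length(unique(meas$assay)) > 1L) {
      stop("all rows of ", path, " must belong to one assay; found ",
           paste(unique(meas$assay), collapse = ", "), call. = FALSE)
    }
    bad_value <- which(!is.finite(meas$value))
    if (length(bad_value)) {
      stop("non-numeric or non-finite value in ", path, " (data row ",
           bad_value[1], ")", call. = FALSE)
    }
    neg_t <- which(!is.na(meas$time_min) & meas$time_min < 0)
    if (length(neg_t)) {
      stop("negative time_min in ", path, " (data row ", neg_t[1], ")",
           call. = FALSE)
    }
  }
  mk <- well_key(meas)
  pk <- well_key(plate_map)
  orphan <- which(!(mk %in% pk))
  if (length(orphan)) {
    stop("well ", mk[orphan[1]], " in ", path, " is absent from the plate map",
         call. = FALSE)
  }
  idx <- match(mk, pk)
  meas$role <- plate_map$role[idx]
  meas$standard_conc <- plate_map$standard_conc[idx]
  meas$sample_id <- plate_map$sample_id[idx]

  if (!is.null(read_schedule) && nrow(meas)) {
    sched <- sort(unique(read_schedule))
    for (k in unique(mk)) {
      got <- sort(meas$time_min[mk == k])
      if (length(got) != length(sched) || any(got != sched)) {
        missing_t <- setdiff(sched, got)
        stop("well ", k, " in ", path, " does not follow the read schedule; ",
             if (length(missing_t)) paste("missing t =", paste(missing_t, collapse = ", "), "min")
             else "has extra or duplicated reads",
             call. = FALSE)
      }
    }
  }

  ord <- order(meas$plate_id, match(meas$row, WELL_ROWS), meas$col, meas$time_min)
  meas <- meas[ord, , drop = FALSE]
  rownames(meas) <- NULL
  attr(meas, "assay") <- if (nrow(meas)) meas$assay[1] else NA_character_
  attr(meas, "dilution_factor") <- dilution_factor
  attr(meas, "read_schedule") <- read_schedule
  meas
}

#' Write and re-read the per-extract results table
#'
#' `write_results()` writes one row per extract in a fixed, documented column
#' order; `read_results()` reads such a file back with the same types.
#' Numeric fields survive the round trip at full double precision (15
#' significant digits), logical flags as TRUE/FALSE, missing values as empty
#' fields.
#'
#' @param results Data frame with the columns listed in the package's results
#'   contract: `extract_id, tpc_gae_mg_L, frap_te_umol_L, ros_pct, ros_sd,
#'   no_pct, no_sd, viability_caco2_pct, viability_raw_pct, excluded_ros,
#'   excluded_no, sig_ros, sig_no, reduction30_ros, reduction30_no,
#'   selectivity`.
#' @param path Output (input) CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()` the
#'   results data frame.
#' @export
write_results <- function(results, path) {
  missing_cols <- setdiff(RESULT_COLUMNS, names(results))
  if (length(missing_cols)) {
    stop("results table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- results[, RESULT_COLUMNS, drop = FALSE]
  bad <- setdiff(unique(out$selectivity[!is.na(out$selectivity)]), SELECTIVITY_CLASSES)
  if (length(bad)) {
    stop("invalid selectivity class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(format_results_for_csv(out), path, row.names = FALSE,
                     quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write results to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

format_results_for_csv <- function(out) {
  num_cols <- vapply(out, is.numeric, logical(1))
  for (nm in names(out)[num_cols]) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), "", vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1)))
  }
  out
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  num_cols <- c("tpc_gae_mg_L", "frap_te_umol_L", "ros_pct", "ros_sd",
                "no_pct", "no_sd", "viability_caco2_pct", "viability_raw_pct")
  for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
  lgl_cols <- c("excluded_ros", "excluded_no", "sig_ros", "sig_no",
                "reduction30_ros", "reduction30_no")
  for (nm in lgl_cols) df[[nm]] <- as.logical(df[[nm]])
  df$extract_id <- as.character(df$extract_id)
  df$selectivity <- as.character(df$selectivity)
  df[, RESULT_COLUMNS, drop = FALSE]
}
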