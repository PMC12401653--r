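#' @importFrom utils read.csv write.csv
NULL

## Canonical weighting labels and tie-break simplicity order.
.weightingLabels <- c("equal", "1/x", "1/x2", "1/y", "1/y2")

#' Normalize a calibration weighting label
#'
#' Accepts the spellings used on instrument printouts ("Equal", "1/x^2",
#' "1/y^2", case-insensitive) and returns the canonical label.
#'
#' @param label character vector of weighting labels.
#' @return character vector with values among
#'   `c("equal", "1/x", "1/x2", "1/y", "1/y2")`.
#' @examples
#' normalizeWeighting(c("Equal", "1/x^2"))
#' @export
normalizeWeighting <- function(label) {
  out <- gsub("^", "", tolower(trimws(label)), fixed = TRUE)
  out <- gsub("\u00b2", "2", out)
  bad <- !(out %in% .weightingLabels)
  if (any(bad)) {
    stop("unknown weighting label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  out
}

.metabolitePattern <- "-M ("

#' Metabolite flags of a panel
#'
#' An analyte is flagged as an (active) metabolite when its name carries the
#' "-M (" designation, which also covers the two dual parent/metabolite
#' entries (nordiazepam, paliperidone); those additionally carry
#' `dual_status = TRUE`.
#'
#' @param panel an [AnalytePanel-class].
#' @return logical vector, one flag per analyte.
#' @export
isMetabolite <- function(panel) {
  grepl(.metabolitePattern, panel@entries$analyte, fixed = TRUE)
}

#' Read an analyte panel CSV
#'
#' Reads the panel definition (one analyte per row: weighting label, five
#' calibrator levels, LLOQ/ULOQ, QC low/high, therapeutic and toxic ranges,
#' sum-group and dual-status bookkeeping) and validates its invariants:
#' strictly increasing calibrator levels, LLOQ = calibrator 1,
#' ULOQ = calibrator 5, and `lloq <= qc_low < qc_high <= uloq`.
#' The one-point calibrator concentration is calibrator 3.
#'
#' Printed panels occasionally violate the QC-range invariant (a transcribed
#' typo); by default such rows raise a warning naming the analyte rather
#' than an error.
#'
#' @param path CSV file path.
#' @param strict if `TRUE`, QC-range violations are errors.
#' @return An [AnalytePanel-class].
#' @examples
#' panel <- readPanel(system.file("extdata", "panel.csv", package = "etquant"))
#' length(panel)
#' @export
readPanel <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 check.names = FALSE)
  if (nrow(df) == 0L) stop("no analytes in panel file: ", path)
  missing <- setdiff(.panelRequiredCols, names(df))
  if (length(missing)) {
    stop("missing mandatory panel column(s): ", paste(missing, collapse = ", "))
  }
  df$weighting <- normalizeWeighting(df$weighting)
  numcols <- c(paste0("cal", 1:5), "lloq", "uloq", "qc_low", "qc_high",
               "therapeutic_low", "therapeutic_high", "toxic_above", "rt_min")
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.na(df[[cc]]) & df[[cc]] != "" & is.na(v))
    if (length(bad)) {
      stop(sprintf("panel row %d (%s): non-numeric value in column '%s'",
                   bad[1L], df$analyte[bad[1L]], cc))
    }
    df[[cc]] <- v
  }
  df$range_is_sum <- as.logical(df$range_is_sum) %in% TRUE
  df$dual_status <- as.logical(df$dual_status) %in% TRUE
  df$sum_group[is.na(df$sum_group) | df$sum_group == ""] <- NA_character_
  cal <- as.matrix(df[paste0("cal", 1:5)])
  for (i in seq_len(nrow(df))) {
    if (any(is.na(cal[i, ]))) {
      stop(sprintf("panel row %d (%s): missing calibrator level", i, df$analyte[i]))
    }
    if (any(diff(cal[i, ]) <= 0)) {
      stop(sprintf("panel row %d (%s): calibrator levels not strictly increasing",
                   i, df$analyte[i]))
    }
    if (df$lloq[i] != cal[i, 1L] || df$uloq[i] != cal[i, 5L]) {
      stop(sprintf("panel row %d (%s): lloq/uloq must equal calibrators 1 and 5",
                   i, df$analyte[i]))
    }
    qcOk <- df$lloq[i] <= df$qc_low[i] && df$qc_low[i] < df$qc_high[i] &&
      df$qc_high[i] <= df$uloq[i]
    if (!qcOk) {
      msg <- sprintf(
        "panel row %d (%s): QC levels outside lloq <= qc_low < qc_high <= uloq",
        i, df$analyte[i])
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  new("AnalytePanel", entries = df)
}

#' Write an analyte panel CSV
#'
#' @param panel an [AnalytePanel-class].
#' @param path output CSV path.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path, force = FALSE) {
  stopifnot(is(panel, "AnalytePanel"))
  .checkOverwrite(path, force)
  write.csv(panel@entries[.panelRequiredCols], path, row.names = FALSE,
            na = "", quote = TRUE)
  invisible(path)
}

#' Extract one analyte's panel entry
#'
#' @param panel an [AnalytePanel-class].
#' @param analyte analyte name.
#' @return A named list with the entry's fields, including the numeric
#'   vector `cal_levels`, `one_point_conc` (calibrator 3) and the
#'   `is_metabolite` flag.
#' @examples
#' panel <- readPanel(system.file("extdata", "panel.csv", package = "etquant"))
#' panelEntry(panel, "Alprazolam")$cal_levels
#' @export
panelEntry <- function(panel, analyte) {
  stopifnot(is(panel, "AnalytePanel"))
  i <- match(analyte, panel@entries$analyte)
  if (is.na(i)) stop("unknown analyte: ", analyte)
  row <- panel@entries[i, ]
  lev <- as.numeric(row[paste0("cal", 1:5)])
  list(
    analyte = row$analyte,
    weighting = row$weighting,
    cal_levels = lev,
    lloq = row$lloq,
    uloq = row$uloq,
    qc_low = row$qc_low,
    qc_high = row$qc_high,
    one_point_conc = lev[3L],
    therapeutic_low = row$therapeutic_low,
    therapeutic_high = row$therapeutic_high,
    toxic_above = row$toxic_above,
    range_is_sum = row$range_is_sum,
    sum_group = row$sum_group,
    dual_status = row$dual_status,
    is_metabolite = grepl(.metabolitePattern, row$analyte, fixed = TRUE),
    working_solution = row$working_solution,
    rt_min = row$rt_min
  )
}

.checkOverwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop("output exists (use force = TRUE to overwrite): ", path)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  invisible(TRUE)
}

#' Construct a calibration store
#'
#' @param records `data.frame` with columns `analyte`, `slope`, `intercept`,
#'   `lloq`, `uloq`, `one_point_conc`, and optionally `istd` (default
#'   "Trimipramine-d3"), `unit` (default "ng/mL"), `quant_mz`,
#'   `created_date`, `archived`.
#' @param onePointSlopes optional list of numeric one-point slope histories,
#'   one per record (default: all empty).
#' @return A [CalibrationStore-class].
#' @export
calibrationStore <- function(records, onePointSlopes = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$istd)) records$istd <- "Trimipramine-d3"
  if (is.null(records$unit)) records$unit <- "ng/mL"
  if (is.null(records$quant_mz)) records$quant_mz <- NA_real_
  if (is.null(records$created_date)) {
    records$created_date <- format(Sys.Date())
  }
  if (is.null(records$archived)) records$archived <- FALSE
  if (is.null(onePointSlopes)) {
    onePointSlopes <- rep(list(numeric()), nrow(records))
  }
  new("CalibrationStore", records = records[.storeRequiredCols],
      onePointSlopes = onePointSlopes)
}

#' Extract one analyte's calibration record
#'
#' @param store a [CalibrationStore-class].
#' @param analyte analyte name.
#' @return A named list with the record fields plus `one_point_slopes`
#'   (numeric history) and `working_slope`, the mean of the stored
#'   five-point slope and all one-point slopes.
#' @export
calibRecord <- function(store, analyte) {
  stopifnot(is(store, "CalibrationStore"))
  i <- match(analyte, store@records$analyte)
  if (is.na(i)) stop("missing calibration record for analyte: ", analyte)
  rec <- as.list(store@records[i, ])
  rec$one_point_slopes <- store@onePointSlopes[[i]]
  rec$working_slope <- mean(c(rec$slope, rec$one_point_slopes))
  rec
}

#' Write the electronically stored calibration to CSV
#'
#' One row per analyte, mirroring the stored-calibration schema: analyte,
#' internal standard, slope, intercept, LLOQ, ULOQ, unit, one-point
#' calibrator concentration, quantifier m/z, then the one-point slope
#' history as columns `cal_slope_1 ... cal_slope_n`.
#'
#' @param store a [CalibrationStore-class].
#' @param path output CSV path.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @seealso [readCalibrationStore()], [renewCalibrationStore()]
#' @export
writeCalibrationStore <- function(store, path, force = FALSE) {
  stopifnot(is(store, "CalibrationStore"))
  validObject(store)
  .checkOverwrite(path, force)
  df <- store@records[.storeRequiredCols]
  nmax <- max(0L, vapply(store@onePointSlopes, length, integer(1)))
  if (nmax > 0L) {
    for (k in seq_len(nmax)) {
      df[[paste0("cal_slope_", k)]] <- vapply(
        store@onePointSlopes,
        function(s) if (length(s) >= k) s[k] else NA_real_, numeric(1))
    }
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read an electronically stored calibration CSV
#'
#' @param path CSV file path written by [writeCalibrationStore()].
#' @return A [CalibrationStore-class]; `cal_slope_*` columns are collected
#'   back into the per-analyte one-point slope history, in order.
#' @export
readCalibrationStore <- function(path) {
  if (!file.exists(path)) stop("calibration store not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 check.names = FALSE)
  missing <- setdiff(.storeRequiredCols, names(df))
  if (length(missing)) {
    stop("missing store column(s): ", paste(missing, collapse = ", "))
  }
  slopeCols <- grep("^cal_slope_[0-9]+$", names(df), value = TRUE)
  slopeCols <- slopeCols[order(as.integer(sub("cal_slope_", "", slopeCols)))]
  hist <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(df[i, slopeCols, drop = FALSE])))
    as.numeric(v[!is.na(v)])
  })
  df$archived <- as.logical(df$archived) %in% TRUE
  df$quant_mz <- suppressWarnings(as.numeric(df$quant_mz))
  new("CalibrationStore", records = df[.storeRequiredCols],
      onePointSlopes = hist)
}

#' Renew the stored calibration, archiving the previous file
#'
#' When a fresh five-point calibration replaces the stored one, the previous
#' store file is moved to an archive file (its records flagged as archived)
#' and a new store file with empty one-point slope histories is initiated.
#'
#' @param store the new [CalibrationStore-class] (fresh five-point slopes).
#' @param path store CSV path; an existing file at `path` is archived.
#' @param archivePath archive destination; default appends a timestamp
#'   suffix to `path`.
#' @return A list with elements `path` and `archivePath` (`NA` when there
#'   was nothing to archive), invisibly.
#' @export
renewCalibrationStore <- function(store, path, archivePath = NULL) {
  stopifnot(is(store, "CalibrationStore"))
  archived <- NA_character_
  if (file.exists(path)) {
    old <- readCalibrationStore(path)
    old@records$archived <- TRUE
    if (is.null(archivePath)) {
      archivePath <- sub("(\\.csv)?$",
                         format(Sys.time(), "_archived_%Y%m%d%H%M%S.csv"),
                         path)
    }
    writeCalibrationStore(old, archivePath, force = TRUE)
    archived <- archivePath
    file.remove(path)
  }
  writeCalibrationStore(store, path)
  invisible(list(path = path, archivePath = archived))
}

.sampleRoles <- c("calibrator", "qc_low", "qc_high", "blank", "case", "pt",
                  "neat", "postextraction_spike", "single_solution", "mixture")

#' Read a measurement table CSV
#'
#' One peak-area observation per row: sample id, analyte, analyte area
#' (empty = not detected), internal-standard area, nominal concentration
#' (required for calibrator/QC roles), sample role, run/day indices and
#' timestamp.
#'
#' @param path CSV file path.
#' @return A `data.frame` of measurements.
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 check.names = FALSE)
  req <- c("sample_id", "analyte", "analyte_area", "is_area", "nominal_conc",
           "sample_role", "run_index", "day_index", "timestamp")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("missing measurement column(s): ", paste(missing, collapse = ", "))
  }
  for (cc in c("analyte_area", "is_area", "nominal_conc")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  bad <- !(df$sample_role %in% .sampleRoles)
  if (any(bad)) {
    stop("unknown sample_role: ", paste(unique(df$sample_role[bad]),
                                        collapse = ", "))
  }
  quantRoles <- c("calibrator", "qc_low", "qc_high", "case", "pt")
  if (any(df$sample_role %in% quantRoles &
            (!is.finite(df$is_area) | df$is_area <= 0))) {
    stop("is_area must be positive for quantifiable samples")
  }
  needNom <- df$sample_role %in% c("calibrator", "qc_low", "qc_high")
  if (any(needNom & !is.finite(df$nominal_conc))) {
    stop("nominal_conc required for calibrator/QC roles")
  }
  df
}

#' Write a measurement table CSV
#'
#' Optionally serializes a generator/configuration block as a JSON sidecar
#' (`<path>.config.json`) so simulated sets remain reproducible.
#'
#' @param measurements measurement `data.frame` (see [readMeasurements()]).
#' @param path output CSV path.
#' @param config optional named list serialized alongside the CSV.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(measurements, path, config = NULL,
                              force = FALSE) {
  .checkOverwrite(path, force)
  write.csv(measurements, path, row.names = FALSE, na = "", quote = TRUE)
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a proficiency-test table CSV
#'
#' The `calculated` column may hold a number, the token `"nd"` (no analyte
#' peak detected) or a censored token `"< X"` (detected, below the
#' quantification limit `X`). Censored tokens are parsed losslessly into a
#' `status` column (`value`, `censored_lt`, `nd`) plus a numeric
#' `censor_limit`. The acceptance range is read from `accepted_low` /
#' `accepted_high` columns or split from a single `range` column
#' ("26.6-79.4").
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `analyte`, `calculated` (numeric, NA
#'   when censored), `status`, `censor_limit`, `target`, `accepted_low`,
#'   `accepted_high`, plus any of `case_type`, `lloq`, `comment` present in
#'   the file.
#' @examples
#' pt <- readPTTable(system.file("extdata", "pt_results.csv",
#'                               package = "etquant"))
#' table(pt$status)
#' @export
readPTTable <- function(path) {
  if (!file.exists(path)) stop("PT file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 check.names = FALSE)
  if (!"analyte" %in% names(df)) stop("missing mandatory column: analyte")
  if (!"calculated" %in% names(df)) stop("missing mandatory column: calculated")
  if (!"target" %in% names(df)) stop("missing mandatory column: target")
  if (!all(c("accepted_low", "accepted_high") %in% names(df))) {
    if (!"range" %in% names(df)) {
      stop("need either accepted_low/accepted_high or a range column")
    }
    parts <- strsplit(trimws(df$range), "\\s*[-\u2010\u2013\u2014]\\s*")
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad)) {
      stop(sprintf("row %d (%s): malformed range string '%s'",
                   bad[1L], df$analyte[bad[1L]], df$range[bad[1L]]))
    }
    df$accepted_low <- as.numeric(vapply(parts, `[`, "", 1L))
    df$accepted_high <- as.numeric(vapply(parts, `[`, "", 2L))
  }
  tok <- trimws(as.character(df$calculated))
  status <- ifelse(tolower(tok) == "nd", "nd",
                   ifelse(grepl("^<", tok), "censored_lt", "value"))
  censor <- rep(NA_real_, nrow(df))
  censor[status == "censored_lt"] <-
    as.numeric(sub("^<\\s*", "", tok[status == "censored_lt"]))
  calc <- rep(NA_real_, nrow(df))
  calc[status == "value"] <- suppressWarnings(as.numeric(tok[status == "value"]))
  if (any(status == "value" & is.na(calc))) {
    i <- which(status == "value" & is.na(calc))[1L]
    stop(sprintf("row %d (%s): cannot parse calculated value '%s'",
                 i, df$analyte[i], tok[i]))
  }
  num <- cbind(calc, censor, df$target, df$accepted_low, df$accepted_high)
  if (any(num < 0, na.rm = TRUE)) stop("negative concentration in PT table")
  inv <- which(df$accepted_low >= df$accepted_high)
  if (length(inv)) {
    stop(sprintf("row %d (%s): inverted range %g-%g", inv[1L],
                 df$analyte[inv[1L]], df$accepted_low[inv[1L]],
                 df$accepted_high[inv[1L]]))
  }
  out <- data.frame(
    analyte = df$analyte, calculated = calc, status = status,
    censor_limit = censor, target = df$target,
    accepted_low = df$accepted_low, accepted_high = df$accepted_high,
    stringsAsFactors = FALSE
  )
  for (extra in c("case_type", "lloq", "comment")) {
    if (extra %in% names(df)) out[[extra]] <- df[[extra]]
  }
  out
}

#' Write a proficiency-test table CSV
#'
#' Censored results are emitted both as the literal token in `calculated`
#' ("nd", "< 500") and in the dedicated `status`/`censor_limit` columns, so
#' numeric columns stay purely numeric on read.
#'
#' @param pt PT `data.frame` as returned by [readPTTable()].
#' @param path output CSV path.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
writePTTable <- function(pt, path, force = FALSE) {
  .checkOverwrite(path, force)
  out <- pt
  tok <- as.character(out$calculated)
  tok[out$status == "nd"] <- "nd"
  cl <- out$status == "censored_lt"
  tok[cl] <- paste0("< ", format(out$censor_limit[cl], trim = TRUE,
                                 scientific = FALSE))
  out$calculated <- tok
  write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}
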