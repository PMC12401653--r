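#' Quantify one measurement against a stored calibration record
#'
#' Converts the analyte/IS peak-area ratio to a plasma concentration via the
#' stored calibration, `conc = (ratio - intercept) / slope`, using the
#' working slope (mean of the five-point slope and the one-point slope
#' history). Results are censored against the quantification range: `nd`
#' when no analyte peak was detected (absent/zero area), `below_lloq` when
#' the back-calculated concentration falls below the LLOQ, `above_uloq`
#' above the ULOQ, otherwise `value`. When a panel entry is supplied, a
#' reportable value is interpreted against the therapeutic/toxic ranges.
#'
#' @param measurement a list or one-row `data.frame` with `analyte_area`
#'   (NA or 0 means not detected) and `is_area` (> 0).
#' @param record calibration record list from [calibRecord()] (not
#'   archived).
#' @param entry optional panel entry from [panelEntry()] for
#'   interpretation.
#' @param sumPartnerConc optional partner concentration for sum-range
#'   entries, passed to [interpretConc()].
#' @return A list of class `quantResult`: `analyte`, `conc` (NA unless
#'   `status == "value"`), `status`, `band`, `used_slope`,
#'   `used_intercept`.
#' @examples
#' rec <- list(analyte = "Alprazolam", slope = 0.001, intercept = 0,
#'             lloq = 50, uloq = 500, one_point_slopes = numeric(),
#'             archived = FALSE)
#' quantifySample(list(analyte_area = 250, is_area = 1000), rec)
#' @export
quantifySample <- function(measurement, record, entry = NULL,
                           sumPartnerConc = NULL) {
  m <- as.list(measurement)
  if (isTRUE(record$archived)) stop("calibration record is archived")
  slope <- if (!is.null(record$working_slope)) record$working_slope
           else mean(c(record$slope, record$one_point_slopes))
  if (!is.finite(slope) || slope <= 0) stop("nonpositive calibration slope")
  if (is.null(m$is_area) || !is.finite(m$is_area) || m$is_area <= 0) {
    stop("is_area must be positive for a quantifiable sample")
  }
  detected <- !is.null(m$analyte_area) && is.finite(m$analyte_area) &&
    m$analyte_area > 0
  res <- list(analyte = record$analyte, conc = NA_real_, status = "nd",
              band = "not_interpretable", used_slope = slope,
              used_intercept = record$intercept)
  if (detected) {
    ratio <- m$analyte_area / m$is_area
    conc <- (ratio - record$intercept) / slope
    if (conc < record$lloq) {
      res$status <- "below_lloq"
    } else if (conc > record$uloq) {
      res$status <- "above_uloq"
    } else {
      res$status <- "value"
      res$conc <- conc
      if (!is.null(entry)) {
        res$band <- interpretConc(conc, entry, sumPartnerConc)
      }
    }
  }
  class(res) <- "quantResult"
  res
}

#' @export
print.quantResult <- function(x, ...) {
  lab <- switch(x$status,
                value = sprintf("%.4g ng/mL (%s)", x$conc, x$band),
                below_lloq = "below LLOQ",
                above_uloq = "above ULOQ",
                nd = "not detected")
  cat(sprintf("%s: %s\n", x$analyte, lab))
  invisible(x)
}

#' Interpret a concentration against therapeutic and toxic ranges
#'
#' Bands a plasma concentration: `subtherapeutic` below the therapeutic
#' range, `therapeutic` within it (bounds inclusive), `above_therapeutic`
#' between the range and the toxic threshold, `toxic` at or above the toxic
#' threshold. Overlapping ranges (e.g. a toxic threshold inside the
#' therapeutic range, as for carbamazepine) are resolved toxic-first: any
#' concentration at or above the toxic threshold is toxic. Entries without
#' any range (nor-metabolites) give `not_interpretable`. Entries whose
#' printed range refers to the drug + active-metabolite sum are only
#' interpreted when the partner concentration is explicitly supplied; the
#' summed concentration is then banded against the summed range.
#'
#' @param conc concentration, ng/mL.
#' @param entry panel entry list from [panelEntry()].
#' @param sumPartnerConc partner concentration for sum-range entries; no
#'   imputation is done when absent.
#' @return One of `"subtherapeutic"`, `"therapeutic"`,
#'   `"above_therapeutic"`, `"toxic"`, `"not_interpretable"`.
#' @examples
#' panel <- readPanel(system.file("extdata", "panel.csv", package = "etquant"))
#' interpretConc(67, panelEntry(panel, "Alprazolam"))
#' @export
interpretConc <- function(conc, entry, sumPartnerConc = NULL) {
  lo <- entry$therapeutic_low
  hi <- entry$therapeutic_high
  tox <- entry$toxic_above
  if ((is.na(lo) || is.na(hi)) && is.na(tox)) return("not_interpretable")
  if (isTRUE(entry$range_is_sum)) {
    if (is.null(sumPartnerConc) || is.na(sumPartnerConc)) {
      return("not_interpretable")
    }
    conc <- conc + sumPartnerConc
  }
  if (!is.na(tox) && conc >= tox) return("toxic")
  if (!is.na(lo) && conc < lo) return("subtherapeutic")
  if (!is.na(hi) && conc <= hi) return("therapeutic")
  "above_therapeutic"
}

#' One-point recalibration of a stored record
#'
#' A freshly prepared one-point calibrator (at the stored one-point
#' concentration, calibrator 3) analyzed in triplicate yields an observed
#' slope `(mean ratio - intercept) / conc`, which is appended to the
#' record's one-point slope history. The working slope becomes the
#' arithmetic mean of the stored five-point slope and the full history; the
#' intercept is kept fixed (set `refreshIntercept = FALSE` explicitly to
#' document the choice; refreshing is not supported by the stored schema).
#'
#' @param record calibration record list from [calibRecord()].
#' @param ratios numeric vector of replicate area ratios (typically 3).
#' @param conc one-point calibrator concentration; must equal the record's
#'   `one_point_conc`.
#' @return The updated record list (`one_point_slopes` grown by one,
#'   `working_slope` refreshed).
#' @examples
#' rec <- list(analyte = "X", slope = 0.0010, intercept = 0,
#'             one_point_conc = 1000, one_point_slopes = numeric())
#' onePointRecalibrate(rec, ratios = c(0.8, 0.8, 0.8))$working_slope
#' @export
onePointRecalibrate <- function(record, ratios,
                                conc = record$one_point_conc) {
  stopifnot(is.numeric(ratios), length(ratios) >= 1L)
  if (any(ratios <= 0)) stop("one-point calibrator ratios must be positive")
  if (!isTRUE(all.equal(conc, record$one_point_conc))) {
    stop("one-point calibrator concentration (", conc,
         ") does not match the stored level (", record$one_point_conc, ")")
  }
  observed <- (mean(ratios) - record$intercept) / conc
  if (observed <= 0) {
    stop("mean ratio at or below the intercept: nonpositive one-point slope")
  }
  record$one_point_slopes <- c(record$one_point_slopes, observed)
  record$working_slope <- mean(c(record$slope, record$one_point_slopes))
  record
}

#' Apply a one-point recalibration inside a calibration store
#'
#' @param store a [CalibrationStore-class].
#' @param analyte analyte name.
#' @param ratios triplicate area ratios of the fresh one-point calibrator.
#' @return The updated [CalibrationStore-class].
#' @seealso [onePointRecalibrate()]
#' @export
storeOnePointRecalibration <- function(store, analyte, ratios) {
  rec <- calibRecord(store, analyte)
  rec <- onePointRecalibrate(rec, ratios)
  i <- match(analyte, store@records$analyte)
  store@onePointSlopes[[i]] <- rec$one_point_slopes
  store
}

#' QC-drift monitoring with recalibration triggers
#'
#' Replays the stored-calibration monitoring rule over a time-ordered QC
#' series of one analyte: when the deviation of the calculated from the
#' nominal concentration exceeds the acceptance limit (+/- 30%) in two
#' consecutive measurements, a one-point recalibration is triggered; if the
#' first measurement after that adjustment still fails, a fresh five-point
#' calibration is triggered. After a five-point recalibration the episode
#' resets.
#'
#' @param series `data.frame` with columns `nominal` and `calculated`
#'   (plus optionally `timestamp`, `analyte`), time-ordered, single
#'   analyte; or with a precomputed `deviation_pct` column.
#' @param thresholds an [AcceptanceThresholds-class]; `qcDriftPct` is the
#'   limit.
#' @return `data.frame` with one row per fired action: `index` (series row
#'   that triggered it), `action` (`one_point_recalibration` or
#'   `five_point_recalibration`); the per-point deviations are attached as
#'   attribute `"deviation_pct"`.
#' @examples
#' s <- data.frame(nominal = 100, calculated = c(110, 135, 132, 133))
#' qcMonitor(s)
#' @export
qcMonitor <- function(series, thresholds = defaultThresholds()) {
  stopifnot(is.data.frame(series))
  if (!is.null(series$analyte) && length(unique(series$analyte)) > 1L) {
    stop("qcMonitor expects a single-analyte series")
  }
  if (!is.null(series$timestamp) && is.unsorted(series$timestamp)) {
    stop("series timestamps must be ordered")
  }
  dev <- if (!is.null(series$deviation_pct)) series$deviation_pct
         else 100 * (series$calculated - series$nominal) / series$nominal
  limit <- thresholds@qcDriftPct
  fail <- abs(dev) > limit
  actions <- data.frame(index = integer(), action = character(),
                        stringsAsFactors = FALSE)
  prevFail <- FALSE
  afterOnePoint <- FALSE
  for (i in seq_along(fail)) {
    if (afterOnePoint) {
      if (fail[i]) {
        actions <- rbind(actions, data.frame(
          index = i, action = "five_point_recalibration"))
        prevFail <- FALSE
        afterOnePoint <- FALSE
        next
      }
      afterOnePoint <- FALSE
    }
    if (fail[i] && prevFail) {
      actions <- rbind(actions, data.frame(
        index = i, action = "one_point_recalibration"))
      afterOnePoint <- TRUE
      prevFail <- FALSE
    } else {
      prevFail <- fail[i]
    }
  }
  attr(actions, "deviation_pct") <- dev
  actions
}

#' Batch quantification of case samples
#'
#' Quantifies every non-calibrator, non-blank measurement against the
#' stored calibration and, when a panel is given, interprets reportable
#' concentrations. Sum-range entries are interpreted against the summed
#' range when `sumGroups = TRUE` and the partner was quantified in the same
#' sample.
#'
#' @param measurements measurement `data.frame` (see [readMeasurements()]).
#' @param store a [CalibrationStore-class].
#' @param panel optional [AnalytePanel-class].
#' @param sumGroups interpret drug + active-metabolite sum ranges when both
#'   partners are quantified (opt-in).
#' @return `data.frame`: `sample_id`, `analyte`, `conc`, `status`, `band`,
#'   `used_slope`, `used_intercept`.
#' @export
quantifyBatch <- function(measurements, store, panel = NULL,
                          sumGroups = FALSE) {
  rows <- measurements[measurements$sample_role %in% c("case", "pt"), ]
  if (nrow(rows) == 0L) stop("no case/pt measurements to quantify")
  res <- lapply(seq_len(nrow(rows)), function(i) {
    m <- rows[i, ]
    rec <- calibRecord(store, m$analyte)
    entry <- if (!is.null(panel) && m$analyte %in% names(panel)) {
      panelEntry(panel, m$analyte)
    }
    q <- quantifySample(m, rec, entry)
    data.frame(sample_id = m$sample_id, analyte = m$analyte,
               conc = q$conc, status = q$status, band = q$band,
               used_slope = q$used_slope, used_intercept = q$used_intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (sumGroups && !is.null(panel)) {
    for (i in seq_len(nrow(out))) {
      if (out$status[i] != "value") next
      entry <- panelEntry(panel, out$analyte[i])
      if (!isTRUE(entry$range_is_sum)) next
      partners <- names(panel)[!is.na(panel@entries$sum_group) &
                                 panel@entries$sum_group == entry$sum_group &
                                 names(panel) != entry$analyte]
      p <- out[out$sample_id == out$sample_id[i] &
                 out$analyte %in% partners & out$status == "value", ]
      if (nrow(p) >= 1L) {
        out$band[i] <- interpretConc(out$conc[i], entry,
                                     sumPartnerConc = sum(p$conc))
      }
    }
  }
  out
}

#' Plain-text case report
#'
#' Renders batch quantification results as the "push and print" style case
#' summary: analyte, concentration with censoring, interpretation band and
#' the therapeutic/toxic reference range.
#'
#' @param results `data.frame` from [quantifyBatch()].
#' @param panel optional [AnalytePanel-class] for reference ranges.
#' @param file optional path; when given the report is written there.
#' @return The report lines, invisibly when written to `file`.
#' @export
caseReport <- function(results, panel = NULL, file = NULL) {
  fmtRange <- function(a) {
    if (is.null(panel) || !(a %in% names(panel))) return("")
    e <- panelEntry(panel, a)
    rng <- if (!is.na(e$therapeutic_low) && !is.na(e$therapeutic_high)) {
      sprintf("therapeutic %g-%g%s", e$therapeutic_low, e$therapeutic_high,
              if (isTRUE(e$range_is_sum)) " (sum)" else "")
    } else ""
    tox <- if (!is.na(e$toxic_above)) sprintf("toxic >= %g", e$toxic_above)
           else ""
    paste(Filter(nzchar, c(rng, tox)), collapse = ", ")
  }
  lines <- c("Quantification report (ng/mL)",
             strrep("-", 64))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    val <- switch(r$status,
                  value = sprintf("%.4g", r$conc),
                  below_lloq = "< LLOQ",
                  above_uloq = "> ULOQ",
                  nd = "nd")
    ref <- fmtRange(r$analyte)
    lines <- c(lines, sprintf(
      "%-12s %-40s %10s  %-18s %s",
      r$sample_id, r$analyte, val,
      ifelse(r$band == "not_interpretable", "", r$band), ref))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
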