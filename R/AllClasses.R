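#' @import methods
NULL

#' Acceptance thresholds for calibration, validation and monitoring
#'
#' Container for every acceptance criterion (AC) used across the package:
#' EMA back-calculation limits, GTFCh accuracy/precision and matrix-effect
#' limits, co-elution ionization limits, carry-over limits, the QC-drift
#' limit driving recalibration, the retention-time identification window and
#' the significance level of the Mandel linearity test.
#'
#' @slot backcalcPct calibrator back-calculation limit, percent (non-LLOQ levels)
#' @slot backcalcLloqPct back-calculation limit at the LLOQ, percent
#' @slot backcalcPassFraction minimum fraction of calibrators that must pass
#' @slot accuracyPct accuracy (bias) limit, percent of nominal
#' @slot precisionCvPct precision limit, percent CV
#' @slot matrixPct matrix-effect limit, percent deviation from 100
#' @slot ionizationPct co-elution ion suppression/enhancement limit, percent
#' @slot carryoverAnalytePct analyte carry-over limit, percent of LLOQ response
#' @slot carryoverIsPct internal-standard carry-over limit, percent
#' @slot qcDriftPct QC deviation limit triggering recalibration, percent
#' @slot rtWindowMin retention-time identification window, minutes
#' @slot alphaMandel significance level of the Mandel F-test
#'
#' @seealso [defaultThresholds()]
#' @exportClass AcceptanceThresholds
setClass("AcceptanceThresholds",
  representation(
    backcalcPct = "numeric",
    backcalcLloqPct = "numeric",
    backcalcPassFraction = "numeric",
    accuracyPct = "numeric",
    precisionCvPct = "numeric",
    matrixPct = "numeric",
    ionizationPct = "numeric",
    carryoverAnalytePct = "numeric",
    carryoverIsPct = "numeric",
    qcDriftPct = "numeric",
    rtWindowMin = "numeric",
    alphaMandel = "numeric"
  )
)

setValidity("AcceptanceThresholds", function(object) {
  pct <- c(
    object@backcalcPct, object@backcalcLloqPct, object@accuracyPct,
    object@precisionCvPct, object@matrixPct, object@ionizationPct,
    object@carryoverAnalytePct, object@carryoverIsPct, object@qcDriftPct
  )
  msgs <- character()
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct > 100)) {
    msgs <- c(msgs, "all percentage limits must lie in (0, 100]")
  }
  if (!is.finite(object@backcalcPassFraction) ||
      object@backcalcPassFraction <= 0 || object@backcalcPassFraction > 1) {
    msgs <- c(msgs, "backcalcPassFraction must lie in (0, 1]")
  }
  if (!is.finite(object@alphaMandel) ||
      object@alphaMandel <= 0 || object@alphaMandel >= 1) {
    msgs <- c(msgs, "alphaMandel must lie in (0, 1)")
  }
  if (!is.finite(object@rtWindowMin) || object@rtWindowMin <= 0) {
    msgs <- c(msgs, "rtWindowMin must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Default acceptance thresholds
#'
#' Returns the acceptance thresholds used throughout: back-calculation within
#' +/- 15% (+/- 20% at the LLOQ) with at least 75% of calibrators passing
#' (four out of five for a five-point curve); accuracy within +/- 30% of
#' nominal and precision CV <= 30% (emergency-toxicology limits); matrix
#' effects within +/- 30%; co-elution ionization effects within +/- 25%;
#' carry-over below 20% of the LLOQ response for analytes and 5% for the
#' internal standard; QC drift limit +/- 30%; retention-time window
#' +/- 0.4 min; Mandel-test alpha 0.05.
#'
#' @param ... named overrides for individual slots, e.g.
#'   `defaultThresholds(qcDriftPct = 20)`.
#' @return An [AcceptanceThresholds-class] object.
#' @examples
#' defaultThresholds()
#' @export
defaultThresholds <- function(...) {
  args <- list(
    backcalcPct = 15, backcalcLloqPct = 20, backcalcPassFraction = 0.75,
    accuracyPct = 30, precisionCvPct = 30, matrixPct = 30,
    ionizationPct = 25, carryoverAnalytePct = 20, carryoverIsPct = 5,
    qcDriftPct = 30, rtWindowMin = 0.4, alphaMandel = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(args))
  if (length(unknown)) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  }
  args[names(dots)] <- dots
  do.call(new, c(list("AcceptanceThresholds"), args))
}

setMethod("show", "AcceptanceThresholds", function(object) {
  cat("AcceptanceThresholds\n")
  cat(sprintf("  back-calculation: +/-%g%% (+/-%g%% at LLOQ), >= %g%% of levels\n",
              object@backcalcPct, object@backcalcLloqPct,
              100 * object@backcalcPassFraction))
  cat(sprintf("  accuracy +/-%g%%, precision CV <= %g%%\n",
              object@accuracyPct, object@precisionCvPct))
  cat(sprintf("  matrix +/-%g%%, ionization +/-%g%%\n",
              object@matrixPct, object@ionizationPct))
  cat(sprintf("  carry-over: analyte < %g%%, IS < %g%%\n",
              object@carryoverAnalytePct, object@carryoverIsPct))
  cat(sprintf("  QC drift +/-%g%%, RT window +/-%g min, Mandel alpha %g\n",
              object@qcDriftPct, object@rtWindowMin, object@alphaMandel))
})

.panelRequiredCols <- c(
  "analyte", "weighting", paste0("cal", 1:5), "lloq", "uloq",
  "qc_low", "qc_high", "therapeutic_low", "therapeutic_high", "toxic_above",
  "range_is_sum", "sum_group", "dual_status", "working_solution", "rt_min"
)

#' Analyte panel: calibration design and interpretation ranges
#'
#' One row per analyte: the five calibrator concentrations (calibrator 1 and
#' 5 define the LLOQ and ULOQ), low/high QC levels, the weighting label of
#' the linear calibration model, therapeutic and toxic reference ranges, and
#' bookkeeping columns (sum groups for drug + active-metabolite ranges,
#' metabolite/dual-status flags, working solution, retention time). All
#' concentrations are in ng/mL.
#'
#' @slot entries `data.frame` with one row per analyte.
#' @seealso [readPanel()], [panelEntry()]
#' @exportClass AnalytePanel
setClass("AnalytePanel", representation(entries = "data.frame"))

setValidity("AnalytePanel", function(object) {
  df <- object@entries
  msgs <- character()
  missing <- setdiff(.panelRequiredCols, names(df))
  if (length(missing)) {
    return(paste("missing panel column(s):", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return("no analytes")
  if (anyDuplicated(df$analyte)) msgs <- c(msgs, "duplicate analyte names")
  cal <- as.matrix(df[paste0("cal", 1:5)])
  if (any(apply(cal, 1L, function(z) any(diff(z) <= 0)))) {
    msgs <- c(msgs, "calibrator levels must be strictly increasing")
  }
  if (any(df$lloq != cal[, 1L])) msgs <- c(msgs, "lloq must equal cal1")
  if (any(df$uloq != cal[, 5L])) msgs <- c(msgs, "uloq must equal cal5")
  both <- !is.na(df$therapeutic_low) & !is.na(df$therapeutic_high)
  if (any(df$therapeutic_low[both] > df$therapeutic_high[both])) {
    msgs <- c(msgs, "therapeutic_low must not exceed therapeutic_high")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AnalytePanel", function(object) {
  df <- object@entries
  cat(sprintf("AnalytePanel with %d analytes (%d metabolites)\n",
              nrow(df), sum(isMetabolite(object))))
  cat("  weightings:",
      paste(sprintf("%s (%d)", names(table(df$weighting)), table(df$weighting)),
            collapse = ", "), "\n")
  cat("  ULOQ range:", min(df$uloq), "-", max(df$uloq), "ng/mL\n")
})

setMethod("length", "AnalytePanel", function(x) nrow(x@entries))

#' @describeIn AnalytePanel-class analyte names in panel order
#' @param x,object an `AnalytePanel`
#' @export
setMethod("names", "AnalytePanel", function(x) x@entries$analyte)

#' Electronically stored calibration
#'
#' The persistent calibration store: for each analyte the slope and intercept
#' of the five-point calibration curve, the quantification limits, the unit,
#' the one-point calibrator concentration (calibrator 3), optionally the
#' quantifier m/z, and the growing history of one-point recalibration slopes.
#' The working slope used for quantification is the arithmetic mean of the
#' stored five-point slope and all one-point slopes.
#'
#' @slot records `data.frame` with columns `analyte`, `istd`, `slope`,
#'   `intercept`, `lloq`, `uloq`, `unit`, `one_point_conc`, `quant_mz`,
#'   `created_date`, `archived`.
#' @slot onePointSlopes list of numeric vectors, one per record, the ordered
#'   one-point slope history.
#' @seealso [readCalibrationStore()], [calibRecord()], [onePointRecalibrate()]
#' @exportClass CalibrationStore
setClass("CalibrationStore",
  representation(records = "data.frame", onePointSlopes = "list")
)

.storeRequiredCols <- c(
  "analyte", "istd", "slope", "intercept", "lloq", "uloq", "unit",
  "one_point_conc", "quant_mz", "created_date", "archived"
)

setValidity("CalibrationStore", function(object) {
  df <- object@records
  msgs <- character()
  missing <- setdiff(.storeRequiredCols, names(df))
  if (length(missing)) {
    return(paste("missing store column(s):", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$analyte)) msgs <- c(msgs, "duplicate analyte names")
  if (any(!is.finite(df$slope) | df$slope <= 0)) {
    msgs <- c(msgs, "slope must be positive")
  }
  if (any(df$lloq >= df$uloq)) msgs <- c(msgs, "lloq must be below uloq")
  if (length(object@onePointSlopes) != nrow(df)) {
    msgs <- c(msgs, "onePointSlopes must have one entry per record")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CalibrationStore", function(object) {
  df <- object@records
  nhist <- vapply(object@onePointSlopes, length, integer(1))
  cat(sprintf("CalibrationStore with %d analytes (IS: %s)\n",
              nrow(df), paste(unique(df$istd), collapse = ", ")))
  cat(sprintf("  one-point slope history: %d analytes with >= 1 entry (max %d)\n",
              sum(nhist > 0), if (length(nhist)) max(nhist) else 0L))
  if (any(df$archived)) cat(sprintf("  %d archived record(s)\n", sum(df$archived)))
})

setMethod("length", "CalibrationStore", function(x) nrow(x@records))

#' @describeIn CalibrationStore-class analyte names in store order
#' @param x,object a `CalibrationStore`
#' @export
setMethod("names", "CalibrationStore", function(x) x@records$analyte)

#' Weighted linear calibration fit
#'
#' @slot slope response-ratio per ng/mL
#' @slot intercept response-ratio
#' @slot weighting canonical weighting label ("equal", "1/x", "1/x2", "1/y",
#'   "1/y2")
#' @slot ssrRelative sum of squared relative back-calculation errors
#' @slot nPoints number of calibration points
#' @slot residuals per-point residuals on the ratio scale
#' @slot weights per-point weights used in the fit
#' @seealso [fitWeightedLinear()]
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(
    slope = "numeric", intercept = "numeric", weighting = "character",
    ssrRelative = "numeric", nPoints = "integer",
    residuals = "numeric", weights = "numeric"
  )
)

setValidity("CalibrationFit", function(object) {
  msgs <- character()
  if (object@nPoints < 3L) msgs <- c(msgs, "nPoints must be >= 3")
  if (!is.finite(object@ssrRelative) || object@ssrRelative < 0) {
    msgs <- c(msgs, "ssrRelative must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit (%s weighting, n = %d)\n",
              object@weighting, object@nPoints))
  cat(sprintf("  slope %.6g, intercept %.6g, relative SSR %.4g\n",
              object@slope, object@intercept, object@ssrRelative))
})

#' @describeIn CalibrationFit-class intercept and slope, as for `lm`
#' @param object a `CalibrationFit`
#' @param ... ignored
#' @export
setMethod("coef", "CalibrationFit", function(object, ...) {
  c(intercept = object@intercept, slope = object@slope)
})

#' Mandel linearity test result
#'
#' F-test comparing the residual sums of squares of linear and quadratic
#' calibration fits; the linear model is accepted when the quadratic term
#' does not significantly reduce the residual variance.
#'
#' @slot sseLinear residual sum of squares of the linear fit
#' @slot sseQuadratic residual sum of squares of the quadratic fit
#' @slot fStatistic Mandel F-statistic with (1, n - 3) degrees of freedom
#' @slot pValue upper-tail p-value
#' @slot linearAccepted `TRUE` when `pValue >= alpha`
#' @slot alpha significance level
#' @slot nPoints number of calibration points
#' @seealso [mandelTest()]
#' @exportClass MandelResult
setClass("MandelResult",
  representation(
    sseLinear = "numeric", sseQuadratic = "numeric",
    fStatistic = "numeric", pValue = "numeric",
    linearAccepted = "logical", alpha = "numeric", nPoints = "integer"
  )
)

setValidity("MandelResult", function(object) {
  msgs <- character()
  if (object@sseQuadratic > object@sseLinear + 1e-12 * max(1, object@sseLinear)) {
    msgs <- c(msgs, "sseQuadratic cannot exceed sseLinear")
  }
  if (is.finite(object@fStatistic) && object@fStatistic < 0) {
    msgs <- c(msgs, "fStatistic must be nonnegative")
  }
  if (object@pValue < 0 || object@pValue > 1) {
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MandelResult", function(object) {
  cat(sprintf("Mandel linearity test (n = %d): F = %.4g, p = %.4g -> %s\n",
              object@nPoints, object@fStatistic, object@pValue,
              if (object@linearAccepted) "linear accepted" else "linear rejected"))
})

#' Synthetic peak-area response model
#'
#' Parameters of the seeded generator used to emulate IS-normalized peak-area
#' data: a linear ratio response with constant plus proportional Gaussian
#' noise, per-injection internal-standard area variability, per-donor matrix
#' multipliers, a between-day variability component, carry-over and slow
#' multiplicative slope drift.
#'
#' @slot slope true response-ratio per ng/mL
#' @slot intercept true response-ratio intercept
#' @slot noiseConstantSd constant component of the ratio noise SD
#' @slot noiseProportionalSd proportional component (SD per ng/mL of
#'   concentration, as a fraction of `slope * conc`)
#' @slot isAreaMean mean internal-standard peak area (counts)
#' @slot isAreaCv CV of the internal-standard area (fraction)
#' @slot matrixFactorByDonor per-donor matrix-effect multipliers
#' @slot carryoverFraction fraction of the previous injection's response
#'   carried into the next
#' @slot slopeDriftPerDay fractional slope decay per day
#' @slot betweenDayCv CV of the multiplicative day effect (fraction)
#' @slot seed integer seed; identical seeds give identical output
#' @seealso [responseModel()], [simulateCalibrationRun()]
#' @exportClass ResponseModel
setClass("ResponseModel",
  representation(
    slope = "numeric", intercept = "numeric",
    noiseConstantSd = "numeric", noiseProportionalSd = "numeric",
    isAreaMean = "numeric", isAreaCv = "numeric",
    matrixFactorByDonor = "numeric", carryoverFraction = "numeric",
    slopeDriftPerDay = "numeric", betweenDayCv = "numeric",
    seed = "integer"
  )
)

setValidity("ResponseModel", function(object) {
  msgs <- character()
  if (object@slope <= 0) msgs <- c(msgs, "slope must be positive")
  nonneg <- c(object@noiseConstantSd, object@noiseProportionalSd,
              object@isAreaCv, object@carryoverFraction, object@betweenDayCv)
  if (any(nonneg < 0)) msgs <- c(msgs, "noise/CV parameters must be nonnegative")
  if (object@isAreaMean <= 0) msgs <- c(msgs, "isAreaMean must be positive")
  if (any(object@matrixFactorByDonor <= 0)) {
    msgs <- c(msgs, "matrix multipliers must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic response model
#'
#' @param slope,intercept true calibration line on the ratio scale.
#' @param noiseConstantSd,noiseProportionalSd Gaussian ratio-noise components;
#'   the SD at concentration `x` is
#'   `noiseConstantSd + noiseProportionalSd * slope * x`.
#' @param isAreaMean,isAreaCv internal-standard area distribution.
#' @param matrixFactorByDonor per-donor matrix multipliers (post-extraction
#'   spike sets are scaled by these).
#' @param carryoverFraction fraction of the previous response carried over.
#' @param slopeDriftPerDay fractional multiplicative slope decay per day.
#' @param betweenDayCv CV of the multiplicative between-day effect.
#' @param seed integer seed.
#' @return A [ResponseModel-class] object.
#' @examples
#' responseModel(slope = 0.002, noiseProportionalSd = 0.05, seed = 7)
#' @export
responseModel <- function(slope = 0.002, intercept = 0,
                          noiseConstantSd = 0, noiseProportionalSd = 0,
                          isAreaMean = 1e6, isAreaCv = 0,
                          matrixFactorByDonor = rep(1, 6),
                          carryoverFraction = 0, slopeDriftPerDay = 0,
                          betweenDayCv = 0, seed = 1L) {
  new("ResponseModel",
      slope = slope, intercept = intercept,
      noiseConstantSd = noiseConstantSd,
      noiseProportionalSd = noiseProportionalSd,
      isAreaMean = isAreaMean, isAreaCv = isAreaCv,
      matrixFactorByDonor = matrixFactorByDonor,
      carryoverFraction = carryoverFraction,
      slopeDriftPerDay = slopeDriftPerDay,
      betweenDayCv = betweenDayCv, seed = as.integer(seed))
}

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf("ResponseModel: ratio = %.4g * conc + %.4g\n",
              object@slope, object@intercept))
  cat(sprintf("  noise sd = %.3g + %.3g * slope * conc; IS ~ %g (CV %.3g)\n",
              object@noiseConstantSd, object@noiseProportionalSd,
              object@isAreaMean, object@isAreaCv))
  cat(sprintf("  drift %.3g/day, between-day CV %.3g, seed %d\n",
              object@slopeDriftPerDay, object@betweenDayCv, object@seed))
})
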