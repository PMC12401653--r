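#' @importFrom stats rnorm residuals
NULL

.ratioNoiseSd <- function(model, conc, slope = model@slope) {
  model@noiseConstantSd + model@noiseProportionalSd * slope * conc
}

.sampleIsAreas <- function(model, n) {
  if (model@isAreaCv == 0) return(rep(model@isAreaMean, n))
  pmax(rnorm(n, model@isAreaMean, model@isAreaCv * model@isAreaMean),
       0.01 * model@isAreaMean)
}

#' Serializable configuration of a response model
#'
#' @param model a [ResponseModel-class].
#' @return named list of all generator parameters (suitable for the JSON
#'   sidecar written by [writeMeasurements()]).
#' @export
modelConfig <- function(model) {
  list(
    generator = "etquant ResponseModel (R Mersenne-Twister, set.seed)",
    slope = model@slope, intercept = model@intercept,
    noise_constant_sd = model@noiseConstantSd,
    noise_proportional_sd = model@noiseProportionalSd,
    is_area_mean = model@isAreaMean, is_area_cv = model@isAreaCv,
    matrix_factor_by_donor = model@matrixFactorByDonor,
    carryover_fraction = model@carryoverFraction,
    slope_drift_per_day = model@slopeDriftPerDay,
    between_day_cv = model@betweenDayCv,
    seed = model@seed
  )
}

#' Simulate a calibration run
#'
#' Generates IS-normalized peak-area measurements on the model's line:
#' `ratio(conc) = slope * conc + intercept + e`, with Gaussian noise of
#' standard deviation `noiseConstantSd + noiseProportionalSd * slope *
#' conc` (constant plus proportional components). Internal-standard areas
#' are sampled per injection and analyte areas reconstructed as
#' `ratio * IS area`. Fully deterministic under the model seed.
#'
#' @param model a [ResponseModel-class].
#' @param levels ascending calibrator concentrations (ng/mL).
#' @param replicates number of replicate curves (one run index each).
#' @param analyte analyte name tag.
#' @return measurement `data.frame` (see [readMeasurements()]) with role
#'   `"calibrator"`.
#' @examples
#' m <- responseModel(noiseProportionalSd = 0.02, seed = 11)
#' head(simulateCalibrationRun(m, c(50, 125, 250, 375, 500), replicates = 3))
#' @export
simulateCalibrationRun <- function(model, levels, replicates = 1L,
                                   analyte = "Analyte") {
  stopifnot(is(model, "ResponseModel"))
  if (any(levels <= 0)) stop("calibrator levels must be positive")
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("calibrator levels must be ascending")
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  set.seed(model@seed)
  grid <- expand.grid(level = seq_along(levels), run = seq_len(replicates))
  conc <- levels[grid$level]
  n <- nrow(grid)
  ratio <- model@slope * conc + model@intercept +
    rnorm(n, 0, .ratioNoiseSd(model, conc))
  if (model@carryoverFraction > 0 && n > 1L) {
    for (i in 2:n) ratio[i] <- ratio[i] + model@carryoverFraction * ratio[i - 1L]
  }
  isArea <- .sampleIsAreas(model, n)
  data.frame(
    sample_id = sprintf("cal_L%d_r%d", grid$level, grid$run),
    analyte = analyte,
    analyte_area = ratio * isArea,
    is_area = isArea,
    nominal_conc = conc,
    sample_role = "calibrator",
    run_index = grid$run,
    day_index = 1L,
    timestamp = format(as.Date("2024-01-01") + grid$run - 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a QC-high monitoring time series
#'
#' Emulates long-term monitoring of an electronically stored calibration: a
#' fresh QC sample is measured every `cadenceDays` days while the true
#' instrument response slope decays linearly at `slopeDriftPerDay` per day.
#' Calculated concentrations are obtained through the *un-drifted* stored
#' line, so the expected deviation at day `t` is `-100 *
#' slopeDriftPerDay * t` percent (for intercept 0) and grows
#' deterministically.
#'
#' @param model a [ResponseModel-class]; `slope`/`intercept` define the
#'   stored calibration, `slopeDriftPerDay` the decay of the true response.
#' @param nominal nominal QC concentration (ng/mL).
#' @param nPoints number of monitoring points (48 points at a 14-day
#'   cadence span about two years).
#' @param cadenceDays days between points.
#' @param analyte analyte name tag.
#' @param startDate date of the first point.
#' @return `data.frame`: `timestamp`, `analyte`, `nominal`, `calculated`,
#'   `deviation_pct`.
#' @examples
#' m <- responseModel(slopeDriftPerDay = 0.02 / 30, seed = 3)
#' head(simulateQCTimeseries(m, nominal = 1600, nPoints = 10))
#' @export
simulateQCTimeseries <- function(model, nominal, nPoints = 48L,
                                 cadenceDays = 14L, analyte = "Analyte",
                                 startDate = as.Date("2024-01-15")) {
  stopifnot(is(model, "ResponseModel"), nPoints >= 1L)
  set.seed(model@seed)
  day <- (seq_len(nPoints) - 1L) * cadenceDays
  trueSlope <- pmax(model@slope * (1 - model@slopeDriftPerDay * day),
                    .Machine$double.eps)
  ratio <- trueSlope * nominal + model@intercept +
    rnorm(nPoints, 0, .ratioNoiseSd(model, nominal, slope = trueSlope))
  calculated <- (ratio - model@intercept) / model@slope
  data.frame(
    timestamp = startDate + day,
    analyte = analyte,
    nominal = nominal,
    calculated = calculated,
    deviation_pct = 100 * (calculated - nominal) / nominal,
    stringsAsFactors = FALSE
  )
}

#' Simulate a role-tagged validation batch
#'
#' Generates the sample sets of a validation experiment for one panel
#' entry: neat solutions and post-extraction donor spikes at QC low/high
#' (matrix effects; donor areas are scaled by the model's per-donor matrix
#' multipliers), and accuracy/precision replicates at LLOQ, QC low and QC
#' high over several days. Day-to-day variability is a multiplicative
#' response effect with CV `betweenDayCv`; a systematic bias can be
#' injected via `biasPct`.
#'
#' @param model a [ResponseModel-class].
#' @param entry panel entry list from [panelEntry()].
#' @param reps replicates per day and level (validation minimum 5).
#' @param days number of days (validation minimum 3).
#' @param donors number of donors for the matrix sets (validation
#'   minimum 6; recycled over `matrixFactorByDonor`).
#' @param biasPct systematic accuracy bias injected into the QC replicates,
#'   percent of nominal.
#' @return measurement `data.frame` with roles `neat`,
#'   `postextraction_spike`, `calibrator` (LLOQ replicates), `qc_low`,
#'   `qc_high`, plus a `donor_index` column for the matrix sets.
#' @export
simulateValidationBatch <- function(model, entry, reps = 5L, days = 3L,
                                    donors = 6L, biasPct = 0) {
  stopifnot(is(model, "ResponseModel"))
  if (reps < 5L) stop("validation needs at least 5 replicates per day")
  if (days < 3L) stop("validation needs at least 3 days")
  if (donors < 2L) stop("need at least 2 donors")
  set.seed(model@seed)
  mf <- rep(model@matrixFactorByDonor, length.out = donors)
  rows <- list()
  mkRow <- function(id, role, conc, ratio, donor = NA_integer_,
                    day = 1L, run = 1L) {
    isArea <- .sampleIsAreas(model, length(ratio))
    data.frame(
      sample_id = id, analyte = entry$analyte,
      analyte_area = ratio * isArea, is_area = isArea,
      nominal_conc = conc, sample_role = role,
      run_index = run, day_index = day,
      timestamp = format(as.Date("2024-02-01") + day - 1L),
      donor_index = donor, stringsAsFactors = FALSE
    )
  }
  # matrix-effect sets: neat solution vs post-extraction donor spikes
  for (lv in c("qc_low", "qc_high")) {
    conc <- entry[[lv]]
    neatRatio <- model@slope * conc + model@intercept +
      rnorm(donors, 0, .ratioNoiseSd(model, conc))
    rows[[paste0("neat_", lv)]] <- mkRow(
      sprintf("neat_%s_%d", lv, seq_len(donors)), "neat", conc, neatRatio)
    postRatio <- mf * (model@slope * conc) + model@intercept +
      rnorm(donors, 0, .ratioNoiseSd(model, conc))
    rows[[paste0("post_", lv)]] <- mkRow(
      sprintf("post_%s_d%d", lv, seq_len(donors)), "postextraction_spike",
      conc, postRatio, donor = seq_len(donors))
  }
  # accuracy/precision replicates at LLOQ, QC low, QC high over days
  levels <- c(lloq = entry$lloq, qc_low = entry$qc_low,
              qc_high = entry$qc_high)
  roles <- c(lloq = "calibrator", qc_low = "qc_low", qc_high = "qc_high")
  for (d in seq_len(days)) {
    dayMult <- if (model@betweenDayCv > 0) {
      max(rnorm(1, 1, model@betweenDayCv), 0.01)
    } else 1
    for (lv in names(levels)) {
      conc <- levels[[lv]] * (1 + biasPct / 100)
      ratio <- dayMult * model@slope * conc + model@intercept +
        rnorm(reps, 0, .ratioNoiseSd(model, conc))
      rows[[paste(lv, d)]] <- mkRow(
        sprintf("%s_d%d_r%d", lv, d, seq_len(reps)), roles[[lv]],
        levels[[lv]], ratio, day = d, run = d)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
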