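#' Matrix effects (matrix factor) at one QC level
#'
#' Compares post-extraction-spiked plasma from individual donors (sample
#' set 2) with neat analyte solution (sample set 1) at the same level:
#' `matrix_factor_pct = 100 * mean(postextraction) / mean(neat)`, with the
#' CV taken over the per-donor factors. A level passes when the matrix
#' factor deviates from 100% by no more than the limit (+/- 30%,
#' inclusive).
#'
#' @param neat numeric peak areas of the neat solution replicates
#'   (typically 6).
#' @param postextraction numeric peak areas of the post-extraction spiked
#'   donor samples (typically 6 donors).
#' @param level `"qc_low"` or `"qc_high"` (bookkeeping only).
#' @param analyte analyte name (bookkeeping only).
#' @param thresholds an [AcceptanceThresholds-class].
#' @return one-row `data.frame`: `analyte`, `level`, `matrix_factor_pct`,
#'   `cv_pct`, `pass`.
#' @examples
#' matrixEffects(neat = rep(1000, 6), postextraction = rep(800, 6))
#' @export
matrixEffects <- function(neat, postextraction, level = "qc_high",
                          analyte = NA_character_,
                          thresholds = defaultThresholds()) {
  stopifnot(length(neat) >= 2L, length(postextraction) >= 2L)
  if (mean(neat) == 0) stop("zero mean neat area")
  factors <- postextraction / mean(neat)
  mf <- 100 * mean(factors)
  cv <- if (mean(factors) == 0) NA_real_ else
    100 * sd(factors) / mean(factors)
  data.frame(
    analyte = analyte, level = level, matrix_factor_pct = mf, cv_pct = cv,
    pass = abs(mf - 100) <= thresholds@matrixPct,
    stringsAsFactors = FALSE
  )
}

#' Within- and between-run accuracy and precision
#'
#' Accuracy is the bias of the (grand) mean calculated concentration from
#' nominal. Within-run precision is the CV of one run of at least five
#' replicates. Between-run precision is an intermediate-precision CV from
#' one-way ANOVA variance components with runs (days) as groups:
#' `sd_IP = sqrt(s2_within + s2_between)` with
#' `s2_between = max(0, (MS_between - MS_within) / n0)` (`n0` the average
#' group size, negative estimates truncated at zero); `method = "pooled"`
#' falls back to the plain CV of all values. A level passes when
#' `|bias| <= 30%` and `CV <= 30%` (inclusive).
#'
#' @param conc numeric calculated concentrations.
#' @param nominal nominal concentration of the level.
#' @param day run/day index per value (required for `between_run`).
#' @param scope `"within_run"` or `"between_run"`.
#' @param level level label (`"lloq"`, `"qc_low"`, `"qc_high"`;
#'   bookkeeping).
#' @param analyte analyte name (bookkeeping).
#' @param method between-run CV estimator: ANOVA variance components
#'   (default) or pooled CV.
#' @param thresholds an [AcceptanceThresholds-class].
#' @return one-row `data.frame`: `analyte`, `level`, `scope`, `bias_pct`,
#'   `cv_pct`, `n`, `pass`.
#' @examples
#' accuracyPrecision(c(90, 95, 100, 105, 110), nominal = 100)
#' @export
accuracyPrecision <- function(conc, nominal, day = NULL,
                              scope = c("within_run", "between_run"),
                              level = NA_character_, analyte = NA_character_,
                              method = c("anova", "pooled"),
                              thresholds = defaultThresholds()) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  stopifnot(is.numeric(conc), is.finite(nominal), nominal > 0)
  if (scope == "within_run") {
    if (length(conc) < 5L) stop("within-run needs at least 5 replicates")
    m <- mean(conc)
    cv <- 100 * sd(conc) / m
  } else {
    if (is.null(day)) stop("between-run needs a day index per value")
    day <- as.factor(day)
    tab <- table(day)
    if (nlevels(day) < 3L) stop("between-run needs at least 3 days")
    if (any(tab < 5L)) stop("between-run needs at least 5 replicates per day")
    m <- mean(conc)
    if (method == "pooled") {
      cv <- 100 * sd(conc) / m
    } else {
      fit <- aov(conc ~ day)
      ms <- summary(fit)[[1L]][["Mean Sq"]]
      msb <- ms[1L]
      msw <- ms[2L]
      k <- nlevels(day)
      N <- length(conc)
      n0 <- (N - sum(tab^2) / N) / (k - 1)
      s2b <- max(0, (msb - msw) / n0)
      cv <- 100 * sqrt(msw + s2b) / m
    }
  }
  bias <- 100 * (m - nominal) / nominal
  data.frame(
    analyte = analyte, level = level, scope = scope,
    bias_pct = bias, cv_pct = cv, n = length(conc),
    pass = abs(bias) <= thresholds@accuracyPct &
      cv <= thresholds@precisionCvPct,
    stringsAsFactors = FALSE
  )
}

#' Ionization effects of co-eluting analytes
#'
#' Compares IS-normalized peak areas of an analyte measured in the
#' all-analyte mixture versus its single-analyte solution (triplicates):
#' `deviation_pct = 100 * (mean(mixture/IS) - mean(single/IS)) /
#' mean(single/IS)`. Ion suppression or enhancement passes within
#' +/- 25%, bounds inclusive.
#'
#' @param mixtureAreas analyte peak areas in the mixture (triplicate).
#' @param mixtureIsAreas matching IS peak areas.
#' @param singleAreas analyte peak areas in the single solution.
#' @param singleIsAreas matching IS peak areas.
#' @param analyte analyte name (bookkeeping).
#' @param thresholds an [AcceptanceThresholds-class].
#' @return one-row `data.frame`: `analyte`, `deviation_pct`, `pass`.
#' @examples
#' ionizationEffects(c(70, 72, 71), rep(100, 3), c(100, 99, 101), rep(100, 3))
#' @export
ionizationEffects <- function(mixtureAreas, mixtureIsAreas,
                              singleAreas, singleIsAreas,
                              analyte = NA_character_,
                              thresholds = defaultThresholds()) {
  if (any(mixtureIsAreas <= 0) || any(singleIsAreas <= 0)) {
    stop("IS areas must be positive")
  }
  mMix <- mean(mixtureAreas / mixtureIsAreas)
  mSingle <- mean(singleAreas / singleIsAreas)
  if (mSingle == 0) stop("zero single-solution mean")
  dev <- 100 * (mMix - mSingle) / mSingle
  data.frame(analyte = analyte, deviation_pct = dev,
             pass = abs(dev) <= thresholds@ionizationPct,
             stringsAsFactors = FALSE)
}

#' Carry-over check on a blank after the highest calibrator
#'
#' A blank plasma sample injected immediately after calibrator 5 passes
#' when its analyte response stays below 20% of the response of an LLOQ
#' sample, and its internal-standard response below 5% of the reference IS
#' response (strict inequalities).
#'
#' @param blank measurement (list/row) of the blank: `analyte_area`,
#'   `is_area`.
#' @param lloqReference measurement of the LLOQ-level reference sample.
#' @param analyte analyte name (bookkeeping).
#' @param thresholds an [AcceptanceThresholds-class].
#' @return one-row `data.frame`: `analyte`, `analyte_pct`, `is_pct`,
#'   `analyte_pass`, `is_pass`, `pass`.
#' @export
carryoverCheck <- function(blank, lloqReference, analyte = NA_character_,
                           thresholds = defaultThresholds()) {
  b <- as.list(blank)
  ref <- as.list(lloqReference)
  if (is.null(ref$analyte_area) || !is.finite(ref$analyte_area) ||
      ref$analyte_area <= 0) {
    stop("missing or empty LLOQ reference sample")
  }
  bArea <- if (is.null(b$analyte_area) || !is.finite(b$analyte_area)) 0
           else b$analyte_area
  aPct <- 100 * bArea / ref$analyte_area
  iPct <- 100 * b$is_area / ref$is_area
  aPass <- aPct < thresholds@carryoverAnalytePct
  iPass <- iPct < thresholds@carryoverIsPct
  data.frame(analyte = analyte, analyte_pct = aPct, is_pct = iPct,
             analyte_pass = aPass, is_pass = iPass,
             pass = aPass & iPass, stringsAsFactors = FALSE)
}

#' Selectivity check on drug-free donor plasma
#'
#' Scans blank plasma signals from at least six donors for interference:
#' a signal is flagged when its retention time falls within the
#' identification window (+/- 0.4 min) of a panel analyte and its response
#' exceeds the analyte carry-over limit (20% of that analyte's LLOQ
#' response). Panel entries without a retention time are skipped with a
#' warning.
#'
#' @param blankSignals `data.frame` of blank-plasma signals: `donor`,
#'   `rt_min`, `response`.
#' @param panel an [AnalytePanel-class] (uses `rt_min`).
#' @param lloqResponses `data.frame` mapping `analyte` to the `response` of
#'   its LLOQ sample.
#' @param thresholds an [AcceptanceThresholds-class].
#' @return `data.frame` of flagged interferences: `analyte`, `donor`,
#'   `rt_min`, `response`, `limit`; zero rows when selective.
#' @export
selectivityCheck <- function(blankSignals, panel, lloqResponses,
                             thresholds = defaultThresholds()) {
  stopifnot(is.data.frame(blankSignals),
            all(c("donor", "rt_min", "response") %in% names(blankSignals)))
  if (length(unique(blankSignals$donor)) < 6L &&
      nrow(blankSignals) > 0L) {
    warning("selectivity is usually assessed on >= 6 donors", call. = FALSE)
  }
  flags <- list()
  for (a in names(panel)) {
    entry <- panelEntry(panel, a)
    if (is.na(entry$rt_min)) {
      warning("no retention time for ", a, "; skipped", call. = FALSE)
      next
    }
    iRef <- match(a, lloqResponses$analyte)
    if (is.na(iRef)) next
    limit <- thresholds@carryoverAnalytePct / 100 * lloqResponses$response[iRef]
    hit <- abs(blankSignals$rt_min - entry$rt_min) <= thresholds@rtWindowMin &
      blankSignals$response > limit
    if (any(hit)) {
      flags[[a]] <- data.frame(
        analyte = a, donor = blankSignals$donor[hit],
        rt_min = blankSignals$rt_min[hit],
        response = blankSignals$response[hit], limit = limit,
        stringsAsFactors = FALSE)
    }
  }
  if (length(flags)) do.call(rbind, c(flags, list(make.row.names = FALSE)))
  else data.frame(analyte = character(), donor = character(),
                  rt_min = numeric(), response = numeric(),
                  limit = numeric(), stringsAsFactors = FALSE)
}

#' Validation report over a role-tagged measurement batch
#'
#' Computes matrix effects (neat vs post-extraction spike, per level) and
#' within-/between-run accuracy and precision (per level) for each analyte
#' present in a role-tagged validation batch, after quantifying QC
#' replicates against the supplied store.
#'
#' @param measurements role-tagged measurement `data.frame` (roles `neat`,
#'   `postextraction_spike`, `calibrator` for LLOQ replicates, `qc_low`,
#'   `qc_high`).
#' @param store a [CalibrationStore-class] used to convert areas to
#'   concentrations for accuracy/precision.
#' @param thresholds an [AcceptanceThresholds-class].
#' @return list with `matrix_effects` and `accuracy_precision`
#'   `data.frame`s.
#' @export
validationReport <- function(measurements, store,
                             thresholds = defaultThresholds()) {
  me <- list()
  ap <- list()
  for (a in unique(measurements$analyte)) {
    m <- measurements[measurements$analyte == a, ]
    for (lv in c("qc_low", "qc_high")) {
      neat <- m[m$sample_role == "neat" & m$nominal_conc %in%
                  unique(m$nominal_conc[m$sample_role == lv]), ]
      post <- m[m$sample_role == "postextraction_spike" & m$nominal_conc %in%
                  unique(m$nominal_conc[m$sample_role == lv]), ]
      if (nrow(neat) >= 2L && nrow(post) >= 2L) {
        me[[paste(a, lv)]] <- matrixEffects(
          neat$analyte_area, post$analyte_area, level = lv, analyte = a,
          thresholds = thresholds)
      }
    }
    rec <- try(calibRecord(store, a), silent = TRUE)
    if (inherits(rec, "try-error")) next
    qc <- m[m$sample_role %in% c("calibrator", "qc_low", "qc_high") &
              is.finite(m$nominal_conc), ]
    if (nrow(qc) == 0L) next
    qc$conc <- (qc$analyte_area / qc$is_area - rec$intercept) /
      rec$working_slope
    for (nom in unique(qc$nominal_conc)) {
      g <- qc[qc$nominal_conc == nom, ]
      lvl <- unique(g$sample_role)[1L]
      days <- unique(g$day_index)
      d1 <- g[g$day_index == days[1L], ]
      if (nrow(d1) >= 5L) {
        ap[[paste(a, nom, "within")]] <- accuracyPrecision(
          d1$conc, nom, scope = "within_run", level = lvl, analyte = a,
          thresholds = thresholds)
      }
      if (length(days) >= 3L) {
        ok <- try(accuracyPrecision(g$conc, nom, day = g$day_index,
                                    scope = "between_run", level = lvl,
                                    analyte = a, thresholds = thresholds),
                  silent = TRUE)
        if (!inherits(ok, "try-error")) {
          ap[[paste(a, nom, "between")]] <- ok
        }
      }
    }
  }
  list(
    matrix_effects = if (length(me)) {
      do.call(rbind, c(me, list(make.row.names = FALSE)))
    } else NULL,
    accuracy_precision = if (length(ap)) {
      do.call(rbind, c(ap, list(make.row.names = FALSE)))
    } else NULL
  )
}

#' Validation-status bookkeeping over the panel
#'
#' Cross-tabulates a list of analytes failing accuracy/precision criteria
#' against the panel: counts of failing and fully validated analytes, plus
#' the failing names resolved against the panel (unknown names error).
#'
#' @param panel an [AnalytePanel-class].
#' @param failing `data.frame` with a column `analyte` (optionally
#'   `failed_scope`), or a character vector of failing analyte names.
#' @return list with `n_panel`, `n_failing`, `n_validated` and the
#'   `failing` names.
#' @export
validationStatus <- function(panel, failing) {
  if (is.data.frame(failing)) failing <- failing$analyte
  failing <- unique(failing)
  unknown <- setdiff(failing, names(panel))
  if (length(unknown)) {
    stop("failing analytes not in panel: ", paste(unknown, collapse = ", "))
  }
  list(
    n_panel = length(panel),
    n_failing = length(failing),
    n_validated = length(setdiff(names(panel), failing)),
    failing = failing
  )
}
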