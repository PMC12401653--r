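#' @importFrom stats lm lm.wfit coef pf var sd aov setNames residuals
NULL

.calWeights <- function(conc, ratio, weighting) {
  switch(weighting,
    "equal" = rep(1, length(conc)),
    "1/x" = 1 / conc,
    "1/x2" = 1 / conc^2,
    "1/y" = 1 / ratio,
    "1/y2" = 1 / ratio^2,
    stop("unknown weighting label: ", weighting)
  )
}

.checkCalPoints <- function(points) {
  stopifnot(is.data.frame(points), all(c("conc", "ratio") %in% names(points)))
  if (any(!is.finite(points$conc)) || any(points$conc <= 0)) {
    stop("calibrator concentrations must be positive and finite")
  }
  if (any(!is.finite(points$ratio))) stop("ratios must be finite")
  points
}

#' Fit a weighted linear calibration curve
#'
#' Weighted least squares of the analyte/IS peak-area ratio on concentration,
#' minimizing `sum(w_i * (y_i - a*x_i - b)^2)` with per-point weights
#' `1`, `1/x`, `1/x^2`, `1/y` or `1/y^2` according to the weighting label.
#' The intercept is always estimated. The fit's `ssrRelative` is the sum of
#' squared relative back-calculation errors,
#' `sum(((backcalc(y_i) - x_i) / x_i)^2)`, a scale-free goodness measure
#' comparable across weighting models.
#'
#' @param points `data.frame` with columns `conc` (ng/mL) and `ratio`
#'   (analyte area / IS area); at least 3 points with distinct
#'   concentrations.
#' @param weighting weighting label; printed spellings such as `"1/x^2"` or
#'   `"Equal"` are accepted (see [normalizeWeighting()]).
#' @return A [CalibrationFit-class].
#' @examples
#' pts <- data.frame(conc = c(100, 500, 1000, 1500, 2000),
#'                   ratio = 0.002 * c(100, 500, 1000, 1500, 2000) + 0.01)
#' coef(fitWeightedLinear(pts, "1/x2"))
#' @export
fitWeightedLinear <- function(points, weighting) {
  points <- .checkCalPoints(points)
  weighting <- normalizeWeighting(weighting)
  if (nrow(points) < 3L) stop("need at least 3 calibration points")
  if (length(unique(points$conc)) < 2L) {
    stop("singular design: all concentrations equal")
  }
  if (weighting %in% c("1/y", "1/y2") && any(points$ratio <= 0)) {
    stop("nonpositive ratio under a 1/y weighting")
  }
  w <- .calWeights(points$conc, points$ratio, weighting)
  fit <- lm(ratio ~ conc, data = points, weights = w)
  b <- unname(coef(fit)[1L])
  a <- unname(coef(fit)[2L])
  back <- (points$ratio - b) / a
  new("CalibrationFit",
      slope = a, intercept = b, weighting = weighting,
      ssrRelative = sum(((back - points$conc) / points$conc)^2),
      nPoints = nrow(points),
      residuals = points$ratio - (a * points$conc + b),
      weights = w)
}

#' Mandel linearity test
#'
#' Compares the residual sums of squares of unweighted linear and quadratic
#' calibration fits. The statistic
#' `F = (SSE_lin - SSE_quad) / (SSE_quad / (n - 3))` is referred to an
#' F(1, n - 3) distribution; the linear model is accepted when the p-value
#' is at least `alpha`. With five calibrators the denominator has only two
#' degrees of freedom, so the test has low power; a warning notes this for
#' `n <= 5`.
#'
#' Degenerate cases: data exactly on a quadratic give `SSE_quad = 0` and the
#' linear model is rejected (F infinite) unless the data are also exactly
#' linear, in which case F is defined as 0 and the linear model accepted.
#'
#' @param points calibration points (`conc`, `ratio`); at least 4.
#' @param alpha significance level (default 0.05).
#' @return A [MandelResult-class].
#' @examples
#' x <- 1:6
#' mandelTest(data.frame(conc = x, ratio = x^2))
#' @export
mandelTest <- function(points, alpha = 0.05) {
  points <- .checkCalPoints(points)
  n <- nrow(points)
  if (n < 4L) {
    stop("Mandel test needs at least 4 points (quadratic fit leaves no df)")
  }
  if (n <= 5L) {
    warning("Mandel test with n <= 5 calibrators has low power (df = ",
            n - 3L, ")", call. = FALSE)
  }
  linFit <- lm(ratio ~ conc, data = points)
  quadFit <- lm(ratio ~ conc + I(conc^2), data = points)
  sseL <- sum(residuals(linFit)^2)
  sseQ <- sum(residuals(quadFit)^2)
  sseQ <- min(sseQ, sseL)   # guard tiny negative differences from roundoff
  tol <- 1e-12 * max(1, sseL)
  if (sseQ <= tol) {
    if (sseL <= tol) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
    }
  } else {
    f <- (sseL - sseQ) / (sseQ / (n - 3))
    p <- pf(f, 1, n - 3, lower.tail = FALSE)
  }
  new("MandelResult",
      sseLinear = sseL, sseQuadratic = sseQ,
      fStatistic = f, pValue = p,
      linearAccepted = p >= alpha, alpha = alpha, nPoints = as.integer(n))
}

#' Select the calibration weighting model across replicate curves
#'
#' Chooses the weighting whose implied variance model best describes the
#' replicate calibration data. Each candidate weighting `1/x^(2g)`
#' corresponds to a response-variance model `Var(y) ~ x^(2g)` with
#' `g = 0` (equal), `0.5` (1/x) or `1` (1/x2); the REML log-likelihood of
#' the pooled linear fit is computed under each variance model and the
#' heteroscedastic candidates carry a BIC penalty (`log(n)/2`) relative to
#' the homoscedastic one, so constant-variance data select "equal" and
#' data whose scatter grows with concentration select a 1/x-family label.
#' Because the response of a linear method is proportional to
#' concentration, the `1/y` and `1/y^2` weightings are statistically
#' equivalent to `1/x` and `1/x^2`; the simplicity tie-break order
#' equal > 1/x > 1/x2 > 1/y > 1/y2 therefore resolves the selection to the
#' x-family label (the y labels remain valid inputs to
#' [fitWeightedLinear()]). Exact ties - e.g. noiseless data, where every
#' model is perfect - return "equal".
#'
#' For reporting, the out-of-replicate relative back-calculation SSR of all
#' five labels (fit on all curves but one, evaluated on the held-out
#' curve, summed) is returned as a diagnostic; the in-sample version is
#' not used because it is minimized by construction under the 1/x2
#' weighting. A label under which the fits fail (for example a nonpositive
#' ratio under a 1/y weighting) is excluded from the table with a warning.
#'
#' @param curves list of at least 2 replicate calibration `data.frame`s
#'   (`conc`, `ratio`).
#' @param labels candidate weighting labels (default all five).
#' @param tol relative tie tolerance on the model scores.
#' @return A list with `weighting` (the selected canonical label), `score`
#'   (penalized REML log-likelihood per variance model), `ssr` (named
#'   numeric: out-of-replicate summed relative SSR per label, `NA` for
#'   excluded labels) and `heteroscedasticity` (see
#'   [heteroscedasticityFTest()]).
#' @export
selectWeighting <- function(curves, labels = .weightingLabels, tol = 1e-9) {
  stopifnot(is.list(curves))
  if (length(curves) < 2L) stop("need at least 2 replicate curves")
  labels <- normalizeWeighting(labels)
  pts <- do.call(rbind, lapply(curves, function(cv) {
    .checkCalPoints(cv)[c("conc", "ratio")]
  }))
  n <- nrow(pts)
  X <- cbind(1, pts$conc)
  gammas <- c(equal = 0, "1/x" = 0.5, "1/x2" = 1)
  gammas <- gammas[names(gammas) %in% labels]
  if (length(gammas) == 0L) gammas <- c(equal = 0)
  score <- vapply(gammas, function(g) {
    w <- pts$conc^(-2 * g)
    fit <- lm.wfit(X, pts$ratio, w)
    rss <- sum(w * fit$residuals^2)
    if (rss <= 1e-20 * sum(w * pts$ratio^2)) return(Inf)
    s2 <- rss / (n - 2L)
    -0.5 * ((n - 2L) * log(s2) +
              determinant(crossprod(X * sqrt(w)))$modulus[1L] -
              sum(log(w)))
  }, numeric(1))
  score <- score - ifelse(gammas > 0, 0.5 * log(n), 0)
  if (all(is.infinite(score))) {
    chosen <- "equal"              # perfect line: every model ties
  } else {
    best <- max(score)
    tied <- score >= best - tol * max(abs(best), 1)
    chosen <- names(gammas)[tied][.orderBySimplicity(names(gammas)[tied])][1L]
  }
  # diagnostic: out-of-replicate relative back-calculation SSR per label
  totals <- setNames(rep(NA_real_, length(labels)), labels)
  for (lab in labels) {
    tot <- try({
      s <- 0
      for (j in seq_along(curves)) {
        train <- do.call(rbind, lapply(curves[-j], function(cv) {
          cv[c("conc", "ratio")]
        }))
        f <- fitWeightedLinear(train, lab)
        held <- curves[[j]]
        back <- (held$ratio - f@intercept) / f@slope
        s <- s + sum(((back - held$conc) / held$conc)^2)
      }
      s
    }, silent = TRUE)
    if (inherits(tot, "try-error")) {
      warning("weighting ", lab, " excluded: ",
              conditionMessage(attr(tot, "condition")), call. = FALSE)
    } else {
      totals[lab] <- tot
    }
  }
  list(weighting = chosen, score = score, ssr = totals,
       heteroscedasticity = heteroscedasticityFTest(curves))
}

.orderBySimplicity <- function(labs) order(match(labs, .weightingLabels))

#' F-test for heteroscedasticity across the calibration range
#'
#' Diagnostic comparing the ratio variances at the lowest and highest
#' calibrator level across replicate curves. Reported alongside weighting
#' selection but not used for it.
#'
#' @param curves list of replicate calibration `data.frame`s.
#' @return list with `f` (variance ratio high/low), `p` (two-sided p-value)
#'   and the two variances; `NA`s when fewer than 2 replicates.
#' @export
heteroscedasticityFTest <- function(curves) {
  lo <- vapply(curves, function(cv) cv$ratio[which.min(cv$conc)], numeric(1))
  hi <- vapply(curves, function(cv) cv$ratio[which.max(cv$conc)], numeric(1))
  k <- length(curves)
  if (k < 2L) return(list(f = NA_real_, p = NA_real_,
                          var_low = NA_real_, var_high = NA_real_))
  vl <- var(lo)
  vh <- var(hi)
  if (vl == 0 && vh == 0) return(list(f = 1, p = 1, var_low = 0, var_high = 0))
  f <- vh / vl
  p <- 2 * min(pf(f, k - 1, k - 1), pf(f, k - 1, k - 1, lower.tail = FALSE))
  list(f = f, p = min(1, p), var_low = vl, var_high = vh)
}

#' EMA back-calculation acceptance check
#'
#' Back-calculates every calibrator from the fitted line and applies the
#' EMA rule: per-level bias within +/- 15% of nominal (+/- 20% at the LLOQ),
#' with at least 75% of calibrators passing - four out of five for a
#' five-point curve.
#'
#' @param fit a [CalibrationFit-class] for the same design.
#' @param points the calibrator points the rule is applied to.
#' @param lloq LLOQ concentration (levels equal to it get the wider limit).
#' @param thresholds an [AcceptanceThresholds-class].
#' @return A list of class `backcalcReport`: `levels` (a `data.frame` with
#'   `conc`, `backcalc`, `bias_pct`, `limit_pct`, `pass`), `n_pass`,
#'   `n_levels`, `min_pass` (the minimum passing count), `overall_pass`.
#' @examples
#' pts <- data.frame(conc = c(50, 125, 250, 375, 500),
#'                   ratio = 0.002 * c(50, 125, 250, 375, 500))
#' backcalcCheck(fitWeightedLinear(pts, "1/x"), pts, lloq = 50)
#' @export
backcalcCheck <- function(fit, points, lloq,
                          thresholds = defaultThresholds()) {
  stopifnot(is(fit, "CalibrationFit"))
  points <- .checkCalPoints(points)
  if (any(points$conc == 0)) stop("nominal concentration 0: undefined bias")
  back <- (points$ratio - fit@intercept) / fit@slope
  bias <- 100 * (back - points$conc) / points$conc
  limit <- ifelse(points$conc == lloq,
                  thresholds@backcalcLloqPct, thresholds@backcalcPct)
  pass <- abs(bias) <= limit
  n <- nrow(points)
  minPass <- as.integer(ceiling(thresholds@backcalcPassFraction * n))
  out <- list(
    levels = data.frame(conc = points$conc, backcalc = back,
                        bias_pct = bias, limit_pct = limit, pass = pass),
    n_pass = sum(pass), n_levels = n, min_pass = minPass,
    overall_pass = sum(pass) >= minPass
  )
  class(out) <- "backcalcReport"
  out
}

#' @export
print.backcalcReport <- function(x, ...) {
  cat(sprintf("Back-calculation: %d/%d levels pass (need >= %d) -> %s\n",
              x$n_pass, x$n_levels, x$min_pass,
              if (x$overall_pass) "PASS" else "FAIL"))
  print(x$levels, digits = 4)
  invisible(x)
}

#' Batch calibration: measurements to calibration store
#'
#' For each analyte with calibrator measurements: builds replicate curves by
#' run, selects the weighting model across replicates (or uses the panel's
#' label when `useStoredWeighting = TRUE`), fits the pooled points, runs the
#' Mandel linearity test and the EMA back-calculation check, and assembles
#' a calibration record (mean of per-replicate slopes and intercepts when
#' `replicateAverage = TRUE`, the pooled fit otherwise).
#'
#' @param measurements measurement `data.frame` with `sample_role ==
#'   "calibrator"` rows (see [readMeasurements()]).
#' @param panel an [AnalytePanel-class].
#' @param thresholds an [AcceptanceThresholds-class].
#' @param useStoredWeighting use the panel's weighting label instead of
#'   data-driven selection.
#' @param replicateAverage store the mean slope/intercept over per-run
#'   curves (the convention for the electronically stored calibration)
#'   rather than the pooled fit.
#' @return list with `store` (a [CalibrationStore-class]) and `diagnostics`
#'   (a `data.frame` per analyte: weighting chosen, slope, intercept, Mandel
#'   F/p/accepted, back-calculation pass counts).
#' @export
calibrateBatch <- function(measurements, panel,
                           thresholds = defaultThresholds(),
                           useStoredWeighting = FALSE,
                           replicateAverage = TRUE) {
  cal <- measurements[measurements$sample_role == "calibrator", ]
  if (nrow(cal) == 0L) stop("no calibrator measurements")
  analytes <- intersect(names(panel), unique(cal$analyte))
  if (length(analytes) == 0L) stop("no calibrator rows match the panel")
  recs <- list()
  diag <- list()
  for (a in analytes) {
    entry <- panelEntry(panel, a)
    ca <- cal[cal$analyte == a, ]
    ca$ratio <- ca$analyte_area / ca$is_area
    curves <- lapply(split(ca, ca$run_index), function(d) {
      data.frame(conc = d$nominal_conc, ratio = d$ratio)
    })
    if (useStoredWeighting || length(curves) < 2L) {
      wlab <- entry$weighting
      ssrTab <- NULL
    } else {
      sel <- selectWeighting(curves)
      wlab <- sel$weighting
      ssrTab <- sel$ssr
    }
    pooled <- data.frame(conc = ca$nominal_conc, ratio = ca$ratio)
    fitPooled <- fitWeightedLinear(pooled, wlab)
    if (replicateAverage && length(curves) >= 2L) {
      fits <- lapply(curves, fitWeightedLinear, weighting = wlab)
      slope <- mean(vapply(fits, function(f) f@slope, numeric(1)))
      intercept <- mean(vapply(fits, function(f) f@intercept, numeric(1)))
    } else {
      slope <- fitPooled@slope
      intercept <- fitPooled@intercept
    }
    mand <- withCallingHandlers(
      mandelTest(pooled, alpha = thresholds@alphaMandel),
      warning = function(w) invokeRestart("muffleWarning"))
    bc <- backcalcCheck(fitPooled, pooled, lloq = entry$lloq,
                        thresholds = thresholds)
    recs[[a]] <- data.frame(
      analyte = a, slope = slope, intercept = intercept,
      lloq = entry$lloq, uloq = entry$uloq,
      one_point_conc = entry$one_point_conc, stringsAsFactors = FALSE)
    diag[[a]] <- data.frame(
      analyte = a, weighting = wlab, slope = slope, intercept = intercept,
      mandel_f = mand@fStatistic, mandel_p = mand@pValue,
      linear_accepted = mand@linearAccepted,
      backcalc_n_pass = bc$n_pass, backcalc_n_levels = bc$n_levels,
      backcalc_pass = bc$overall_pass, stringsAsFactors = FALSE)
  }
  list(store = calibrationStore(do.call(rbind, recs)),
       diagnostics = do.call(rbind, c(diag, list(make.row.names = FALSE))))
}
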