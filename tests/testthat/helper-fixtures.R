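# Shared fixtures: the transcribed panel/PT tables and small builders.

fixturePanel <- function() {
  suppressWarnings(
    readPanel(system.file("extdata", "panel.csv", package = "etquant"))
  )
}

fixturePT <- function() {
  readPTTable(system.file("extdata", "pt_results.csv", package = "etquant"))
}

# exact points on a line, alprazolam-style levels by default
linePoints <- function(slope = 0.002, intercept = 0.01,
                       levels = c(50, 125, 250, 375, 500)) {
  data.frame(conc = levels, ratio = slope * levels + intercept)
}

# replicate curves with constant or proportional ratio noise
noisyCurves <- function(seed, nrep = 3, slope = 0.002, intercept = 0.01,
                        levels = c(50, 125, 250, 375, 500),
                        propCv = 0, constSd = 0) {
  set.seed(seed)
  lapply(seq_len(nrep), function(r) {
    sd <- constSd + propCv * slope * levels
    data.frame(conc = levels,
               ratio = slope * levels + intercept + rnorm(length(levels), 0, sd))
  })
}

# brute-force weighted normal equations: solve (X'WX) b = X'Wy
wlsOracle <- function(points, w) {
  X <- cbind(1, points$conc)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * points$ratio))
  c(intercept = beta[1L], slope = beta[2L])
}

# minimal calibration record for quantification tests
testRecord <- function(slope = 0.001, intercept = 0, lloq = 50, uloq = 500,
                       one_point_conc = 250, slopes = numeric()) {
  list(analyte = "TestAnalyte", istd = "Trimipramine-d3",
       slope = slope, intercept = intercept, lloq = lloq, uloq = uloq,
       unit = "ng/mL", one_point_conc = one_point_conc,
       quant_mz = NA_real_, archived = FALSE,
       one_point_slopes = slopes,
       working_slope = mean(c(slope, slopes)))
}
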