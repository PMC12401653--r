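test_that("matrix factor compares post-extraction spikes to neat solution", {
  r <- matrixEffects(neat = rep(1000, 6), postextraction = rep(1000, 6))
  expect_equal(r$matrix_factor_pct, 100)
  expect_equal(r$cv_pct, 0)
  expect_true(r$pass)
  r <- matrixEffects(rep(1000, 6), rep(800, 6))
  expect_equal(r$matrix_factor_pct, 80)
  expect_true(r$pass)
  r <- matrixEffects(rep(1000, 6), rep(650, 6))
  expect_equal(r$matrix_factor_pct, 65)
  expect_false(r$pass)
  # the +/-30% bound is inclusive
  expect_true(matrixEffects(rep(1000, 6), rep(700, 6))$pass)
  expect_error(matrixEffects(rep(0, 6), rep(1, 6)), "zero mean")
})

test_that("the matrix factor is scale-invariant", {
  set.seed(23)
  for (i in 1:20) {
    neat <- runif(6, 500, 2000)
    post <- runif(6, 400, 2200)
    k <- runif(1, 0.01, 100)
    a <- matrixEffects(neat, post)
    b <- matrixEffects(k * neat, k * post)
    expect_equal(a$matrix_factor_pct, b$matrix_factor_pct, tolerance = 1e-12)
    expect_equal(a$cv_pct, b$cv_pct, tolerance = 1e-10)
  }
})

test_that("within-run accuracy and precision match direct statistics", {
  r <- accuracyPrecision(rep(100, 5), nominal = 100)
  expect_equal(r$bias_pct, 0)
  expect_equal(r$cv_pct, 0)
  expect_true(r$pass)
  x <- c(90, 95, 100, 105, 110)
  r <- accuracyPrecision(x, nominal = 100)
  expect_equal(r$bias_pct, 0)
  # independent oracle: explicit sum-of-squares arithmetic
  sdOracle <- sqrt(sum((x - mean(x))^2) / 4)
  expect_equal(r$cv_pct, 100 * sdOracle / mean(x), tolerance = 1e-12)
  expect_equal(r$cv_pct, 7.9056942, tolerance = 1e-6)
  expect_error(accuracyPrecision(c(1, 2, 3, 4), nominal = 1), "at least 5")
})

test_that("between-run CV matches a hand-computed variance-components oracle", {
  set.seed(31)
  day <- rep(1:3, each = 5)
  x <- 100 + rep(rnorm(3, 0, 5), each = 5) + rnorm(15, 0, 5)
  r <- accuracyPrecision(x, nominal = 100, day = day, scope = "between_run")
  # oracle: one-way ANOVA components by explicit sums of squares
  gm <- mean(x)
  dayMeans <- tapply(x, day, mean)
  ssb <- 5 * sum((dayMeans - gm)^2)
  ssw <- sum((x - dayMeans[as.character(day)])^2)
  msb <- ssb / 2
  msw <- ssw / 12
  s2b <- max(0, (msb - msw) / 5)
  cvOracle <- 100 * sqrt(msw + s2b) / gm
  expect_equal(r$cv_pct, cvOracle, tolerance = 1e-10)
  expect_equal(r$bias_pct, 100 * (gm - 100) / 100, tolerance = 1e-12)
  # pooled fallback is the plain CV of all values
  rp <- accuracyPrecision(x, nominal = 100, day = day,
                          scope = "between_run", method = "pooled")
  expect_equal(rp$cv_pct, 100 * sd(x) / mean(x), tolerance = 1e-12)
  expect_error(accuracyPrecision(x[1:10], 100, day = day[1:10],
                                 scope = "between_run"), "at least 3 days")
})

test_that("negative between-day variance components are truncated at zero", {
  # groups identical -> MSB < MSW impossible; construct MSB << MSW instead
  x <- c(10, -10, 5, -5, 0, 10, -10, 5, -5, 0, 10, -10, 5, -5, 0) + 100
  r <- accuracyPrecision(x, 100, day = rep(1:3, each = 5),
                         scope = "between_run")
  expect_equal(r$cv_pct, 100 * sqrt(sum((x - 100)^2) / 12) / 100,
               tolerance = 1e-10)
})

test_that("validation passes reliably inside the acceptance region", {
  # batches generated with bias <= 20% and CV <= 20% at 3 days x 5
  # replicates stay within the +/-30% / CV <= 30% limits in at least 95%
  # of runs (at the exact 20/20 corner the sampling noise of the bias
  # estimate alone makes ~95% the ceiling, so the region is sampled)
  pass <- vapply(1:200, function(s) {
    set.seed(s)
    beta <- runif(1, 0, 20)
    gamma <- runif(1, 0, 20)
    x <- 100 * (1 + beta / 100) * (1 + rnorm(15, 0, gamma / 100))
    accuracyPrecision(x, 100, day = rep(1:3, each = 5),
                      scope = "between_run")$pass
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("ionization effects compare IS-normalized areas within +/-25%", {
  r <- ionizationEffects(c(100, 100, 100), rep(1000, 3),
                         c(100, 100, 100), rep(1000, 3))
  expect_equal(r$deviation_pct, 0)
  expect_true(r$pass)
  r <- ionizationEffects(c(70, 70, 70), rep(1000, 3),
                         c(100, 100, 100), rep(1000, 3))
  expect_equal(r$deviation_pct, -30)
  expect_false(r$pass)
  # +25.0% exactly passes (inclusive bound)
  r <- ionizationEffects(c(125, 125, 125), rep(1000, 3),
                         c(100, 100, 100), rep(1000, 3))
  expect_equal(r$deviation_pct, 25)
  expect_true(r$pass)
  expect_error(ionizationEffects(1:3, c(0, 1, 1), 1:3, rep(1, 3)),
               "IS areas")
})

test_that("carry-over limits are 20% of LLOQ response and 5% for IS", {
  ref <- list(analyte_area = 1000, is_area = 1e6)
  r <- carryoverCheck(list(analyte_area = 0, is_area = 1), ref)
  expect_true(r$pass)
  r <- carryoverCheck(list(analyte_area = 250, is_area = 1), ref)
  expect_false(r$analyte_pass)
  r <- carryoverCheck(list(analyte_area = 100, is_area = 0.04 * 1e6), ref)
  expect_true(r$analyte_pass)
  expect_true(r$is_pass)
  r <- carryoverCheck(list(analyte_area = 100, is_area = 0.06 * 1e6), ref)
  expect_false(r$is_pass)
  # the limits are strict: exactly 20% / 5% fails
  r <- carryoverCheck(list(analyte_area = 200, is_area = 0.05 * 1e6), ref)
  expect_false(r$analyte_pass)
  expect_false(r$is_pass)
  expect_error(carryoverCheck(list(analyte_area = 1, is_area = 1),
                              list(analyte_area = 0, is_area = 1)),
               "LLOQ reference")
})

test_that("selectivity flags blank signals inside the RT window", {
  full <- fixturePanel()
  # synthetic retention times: the transcription carries none
  mini <- new("AnalytePanel", entries = transform(
    full@entries[full@entries$analyte %in% c("Alprazolam", "Zopiclone"), ],
    rt_min = ifelse(analyte == "Alprazolam", 6.0, NA_real_)))
  lloqResp <- data.frame(analyte = "Alprazolam", response = 1000)
  blanks0 <- data.frame(donor = integer(), rt_min = numeric(),
                        response = numeric())
  expect_equal(nrow(suppressWarnings(
    selectivityCheck(blanks0, mini, lloqResp))), 0L)
  blanks <- data.frame(donor = c(1, 2), rt_min = c(6.3, 6.5),
                       response = c(500, 500))
  flagged <- suppressWarnings(selectivityCheck(blanks, mini, lloqResp))
  expect_equal(nrow(flagged), 1L)        # 0.3 min away flagged, 0.5 not
  expect_equal(flagged$rt_min, 6.3)
  # sub-threshold response in the window is not an interference
  low <- data.frame(donor = 1, rt_min = 6.1, response = 100)
  expect_equal(nrow(suppressWarnings(
    selectivityCheck(low, mini, lloqResp))), 0L)
  # entries without a retention time are skipped, not silently dropped
  w <- capture_warnings(selectivityCheck(blanks, mini, lloqResp))
  expect_true(any(grepl("no retention time for Zopiclone", w)))
})

test_that("pass/fail decisions are idempotent pure functions", {
  set.seed(41)
  neat <- runif(6, 800, 1200)
  post <- runif(6, 600, 1300)
  a <- matrixEffects(neat, post)
  b <- matrixEffects(neat, post)
  expect_identical(a, b)
  x <- rnorm(15, 100, 10)
  expect_identical(
    accuracyPrecision(x, 100, day = rep(1:3, each = 5), scope = "between_run"),
    accuracyPrecision(x, 100, day = rep(1:3, each = 5), scope = "between_run"))
})

test_that("validation bookkeeping counts failing and validated analytes", {
  panel <- fixturePanel()
  failing <- read.csv(system.file("extdata", "validation_status.csv",
                                  package = "etquant"))
  st <- validationStatus(panel, failing)
  expect_equal(st$n_panel, 69L)
  expect_equal(st$n_failing, 10L)
  expect_equal(st$n_validated, 59L)
  expect_error(validationStatus(panel, "NotAnAnalyte"), "not in panel")
})

test_that("a role-tagged batch yields a table-style validation report", {
  panel <- fixturePanel()
  entry <- panelEntry(panel, "Citalopram")
  model <- responseModel(slope = 0.002, noiseProportionalSd = 0.02,
                         betweenDayCv = 0.05,
                         matrixFactorByDonor = rep(0.9, 6), seed = 47)
  batch <- simulateValidationBatch(model, entry)
  store <- calibrationStore(data.frame(
    analyte = "Citalopram", slope = 0.002, intercept = 0,
    lloq = entry$lloq, uloq = entry$uloq,
    one_point_conc = entry$one_point_conc))
  rep <- validationReport(batch, store)
  expect_equal(nrow(rep$matrix_effects), 2L)
  expect_equal(rep$matrix_effects$matrix_factor_pct, c(90, 90),
               tolerance = 0.05)
  ap <- rep$accuracy_precision
  expect_setequal(unique(ap$scope), c("within_run", "between_run"))
  expect_true(all(abs(ap$bias_pct) < 20))
  expect_true(all(ap$pass))
})
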