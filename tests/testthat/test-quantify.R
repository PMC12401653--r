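test_that("quantification inverts the stored line", {
  rec <- testRecord(slope = 0.001, intercept = 0, lloq = 50, uloq = 500)
  q <- quantifySample(list(analyte_area = 0.25 * 1e6, is_area = 1e6), rec)
  expect_equal(q$status, "value")
  expect_equal(q$conc, 250)
  expect_equal(q$used_slope, 0.001)
})

test_that("censoring is exhaustive, exclusive and correctly bounded", {
  rec <- testRecord(slope = 0.001, intercept = 0.02, lloq = 50, uloq = 500)
  # ratio exactly at the intercept: zero concentration, below the LLOQ
  q0 <- quantifySample(list(analyte_area = 0.02 * 1e6, is_area = 1e6), rec)
  expect_equal(q0$status, "below_lloq")
  expect_true(is.na(q0$conc))
  # not detected: absent or zero analyte area
  expect_equal(quantifySample(list(analyte_area = NA, is_area = 1e6),
                              rec)$status, "nd")
  expect_equal(quantifySample(list(analyte_area = 0, is_area = 1e6),
                              rec)$status, "nd")
  # above the ULOQ
  hi <- quantifySample(list(analyte_area = (0.02 + 0.001 * 600) * 1e6,
                            is_area = 1e6), rec)
  expect_equal(hi$status, "above_uloq")
  # exactly one status for a sweep of signals, conc present iff value
  for (ratio in c(0, 0.01, 0.02, 0.05, 0.1, 0.52, 0.55, 1)) {
    q <- quantifySample(list(analyte_area = ratio * 1e6, is_area = 1e6), rec)
    expect_true(q$status %in% c("nd", "below_lloq", "value", "above_uloq"))
    expect_identical(!is.na(q$conc), q$status == "value")
    if (q$status == "value") {
      expect_gte(q$conc, rec$lloq)
      expect_lte(q$conc, rec$uloq)
    }
  }
})

test_that("zero-noise generation and quantification are inverse maps", {
  rec <- testRecord(slope = 0.002, intercept = 0.01, lloq = 50, uloq = 500)
  for (conc in seq(50, 500, length.out = 7)) {
    ratio <- rec$slope * conc + rec$intercept
    q <- quantifySample(list(analyte_area = ratio * 2e5, is_area = 2e5), rec)
    expect_equal(q$conc, conc, tolerance = 1e-9)
  }
})

test_that("quantification guards its preconditions", {
  rec <- testRecord()
  rec$archived <- TRUE
  expect_error(quantifySample(list(analyte_area = 1, is_area = 1), rec),
               "archived")
  rec <- testRecord(slope = -1)
  expect_error(quantifySample(list(analyte_area = 1, is_area = 1), rec),
               "nonpositive calibration slope")
  expect_error(quantifySample(list(analyte_area = 1, is_area = 0),
                              testRecord()), "is_area")
})

test_that("therapeutic/toxic banding follows the panel ranges", {
  panel <- fixturePanel()
  alp <- panelEntry(panel, "Alprazolam")      # therapeutic 5-50, toxic 100
  expect_equal(interpretConc(67, alp), "above_therapeutic")
  expect_equal(interpretConc(3, alp), "subtherapeutic")
  expect_equal(interpretConc(5, alp), "therapeutic")   # inclusive low bound
  expect_equal(interpretConc(50, alp), "therapeutic")  # inclusive high bound
  expect_equal(interpretConc(100, alp), "toxic")       # "toxic above" read as >=
  # overlapping ranges resolve toxic-first (therapeutic high 12000 > toxic 10000)
  cbz <- panelEntry(panel, "Carbamazepine")
  expect_equal(interpretConc(11000, cbz), "toxic")
  expect_equal(interpretConc(9000, cbz), "therapeutic")
  # nor-metabolite without any printed range
  expect_equal(interpretConc(100, panelEntry(panel, "Doxepin-M (nor-)")),
               "not_interpretable")
  # no toxic threshold: interpretation caps at above_therapeutic
  tap <- panelEntry(panel, "Tapentadol")
  expect_equal(interpretConc(500, tap), "above_therapeutic")
})

test_that("sum-range entries need an explicit partner concentration", {
  panel <- fixturePanel()
  dia <- panelEntry(panel, "Diazepam")   # sum range 100-2500, toxic 5000
  expect_equal(interpretConc(300, dia), "not_interpretable")
  expect_equal(interpretConc(300, dia, sumPartnerConc = 250), "therapeutic")
  expect_equal(interpretConc(3000, dia, sumPartnerConc = 2500), "toxic")
  # the partner's own (non-sum) range works standalone
  nor <- panelEntry(panel, "Diazepam-M (nor-)/Nordiazepam")
  expect_equal(interpretConc(500, nor), "therapeutic")
})

test_that("one-point recalibration averages slopes into the history", {
  rec <- testRecord(slope = 0.0010, intercept = 0, one_point_conc = 1000)
  # perfectly consistent triplicate: fixed point of the record
  ratios <- rep(0.0010 * 1000, 3)
  r1 <- onePointRecalibrate(rec, ratios)
  expect_equal(r1$one_point_slopes, 0.0010)
  expect_equal(r1$working_slope, 0.0010)
  # drifted response: observed slope 0.0008, working slope the mean
  r2 <- onePointRecalibrate(rec, c(0.8, 0.8, 0.8))
  expect_equal(r2$one_point_slopes, 0.0008)
  expect_equal(r2$working_slope, 0.0009)
  # second recalibration appends; mean now over three slopes
  r3 <- onePointRecalibrate(r2, c(0.7, 0.7, 0.7))
  expect_equal(r3$one_point_slopes, c(0.0008, 0.0007))
  expect_equal(r3$working_slope, mean(c(0.0010, 0.0008, 0.0007)))
  # guards
  expect_error(onePointRecalibrate(rec, c(0.8, 0.8), conc = 500),
               "does not match")
  rec2 <- testRecord(slope = 0.001, intercept = 0.9, one_point_conc = 1000)
  expect_error(onePointRecalibrate(rec2, c(0.5, 0.5, 0.5)),
               "nonpositive one-point slope")
})

test_that("store-level one-point recalibration grows the stored history", {
  store <- calibrationStore(data.frame(
    analyte = "A", slope = 0.0010, intercept = 0, lloq = 50, uloq = 500,
    one_point_conc = 1000))
  store <- storeOnePointRecalibration(store, "A", c(0.8, 0.8, 0.8))
  expect_equal(calibRecord(store, "A")$working_slope, 0.0009)
  store <- storeOnePointRecalibration(store, "A", c(0.9, 0.9, 0.9))
  expect_length(calibRecord(store, "A")$one_point_slopes, 2L)
})

test_that("QC monitoring fires on two consecutive failures and escalates", {
  mk <- function(dev) data.frame(nominal = 100, calculated = 100 + dev)
  expect_equal(nrow(qcMonitor(mk(c(10, -5, 20)))), 0L)
  a <- qcMonitor(mk(c(35, 32)))
  expect_equal(a$index, 2L)
  expect_equal(a$action, "one_point_recalibration")
  a <- qcMonitor(mk(c(35, 32, 33)))
  expect_equal(a$action,
               c("one_point_recalibration", "five_point_recalibration"))
  expect_equal(a$index, c(2L, 3L))
  # a pass directly after the one-point adjustment closes the episode
  a <- qcMonitor(mk(c(35, 32, 10, 40, 35)))
  expect_equal(a$action, rep("one_point_recalibration", 2))
  expect_equal(a$index, c(2L, 5L))
  # a single excursion does not trigger anything
  expect_equal(nrow(qcMonitor(mk(c(10, 40, 10, 40, 10)))), 0L)
  expect_error(qcMonitor(data.frame(nominal = 100, calculated = 1:2,
                                    timestamp = c(2, 1))), "ordered")
})

test_that("monitoring a drifting series fires exactly where the rule says", {
  model <- responseModel(slope = 0.002, slopeDriftPerDay = 0.02 / 30,
                         seed = 17)   # 2% of slope lost per month
  series <- simulateQCTimeseries(model, nominal = 1600, nPoints = 48,
                                 cadenceDays = 14)
  actions <- qcMonitor(series)
  # independent replay of the rule on the deviations
  dev <- 100 * (series$calculated - series$nominal) / series$nominal
  fail <- abs(dev) > 30
  oracle <- list()
  prev <- FALSE; watch <- FALSE
  for (i in seq_along(fail)) {
    if (watch) {
      if (fail[i]) {
        oracle[[length(oracle) + 1L]] <- c(i, "five_point_recalibration")
        prev <- FALSE; watch <- FALSE; next
      }
      watch <- FALSE
    }
    if (fail[i] && prev) {
      oracle[[length(oracle) + 1L]] <- c(i, "one_point_recalibration")
      watch <- TRUE; prev <- FALSE
    } else prev <- fail[i]
  }
  expect_equal(actions$index, as.integer(vapply(oracle, `[`, "", 1)))
  expect_equal(actions$action, vapply(oracle, `[`, "", 2))
  # deterministic drift: the first trigger index follows the closed form
  firstFail <- which(fail)[1]
  expect_equal(actions$index[1], firstFail + 1L)
  expect_equal(actions$action[1], "one_point_recalibration")
  expect_gt(nrow(actions), 0L)
})

test_that("batch quantification reports censoring and bands per sample", {
  store <- calibrationStore(data.frame(
    analyte = c("Alprazolam", "Carbamazepine"),
    slope = c(0.001, 0.0001), intercept = c(0, 0),
    lloq = c(50, 2500), uloq = c(500, 20000),
    one_point_conc = c(250, 10000)))
  panel <- fixturePanel()
  meas <- data.frame(
    sample_id = c("case1", "case1", "case2"),
    analyte = c("Alprazolam", "Carbamazepine", "Alprazolam"),
    analyte_area = c(0.067 * 1e6, 1.1 * 1e6, 0),
    is_area = 1e6, nominal_conc = NA, sample_role = "case",
    run_index = 1, day_index = 1, timestamp = "2024-03-01")
  res <- quantifyBatch(meas, store, panel)
  expect_equal(res$conc[1], 67, tolerance = 1e-9)
  expect_equal(res$band[1], "above_therapeutic")
  expect_equal(res$conc[2], 11000, tolerance = 1e-9)
  expect_equal(res$band[2], "toxic")
  expect_equal(res$status[3], "nd")
  rep <- caseReport(res, panel)
  expect_true(any(grepl("Alprazolam", rep)))
  expect_true(any(grepl("toxic", rep)))
})
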