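test_that("onset summary statistics match hand arithmetic", {
  rp <- mkReports(c("A", "B", "C"), onset = c(0L, 0L, 10L))
  st <- tabulateDemographics(vaersData(rp))$onset_stats
  expect_equal(st$mean, 10 / 3, tolerance = 1e-12)
  expect_identical(st$median, 0L)
  expect_identical(st$min, 0L)
  expect_identical(st$max, 10L)
  # onset above 365 and missing are excluded from the summary
  rp2 <- mkReports(c("A", "B"), onset = c(400L, NA))
  expect_true(is.na(tabulateDemographics(vaersData(rp2))$onset_stats$mean))
})

test_that("all onsets at day zero land in the 0-30 bin at 100%", {
  rp <- mkReports(sprintf("R%02d", 1:20), onset = 0L)
  on <- tabulateDemographics(vaersData(rp))$onset
  expect_identical(on$percent[on$stratum == "0-30"], 100)
})

test_that("age bands use completed years with exact boundaries", {
  rp <- mkReports(c("A", "B", "C", "D", "E", "F"),
                  age = c(17.9, 18, 64.9, 65, 85, NA))
  tab <- tabulateDemographics(vaersData(rp))$age
  cnt <- setNames(tab$count, tab$stratum)
  expect_identical(cnt[["<18"]], 1L)
  expect_identical(cnt[["18-64"]], 2L)
  expect_identical(cnt[["65-84"]], 1L)
  expect_identical(cnt[[">=85"]], 1L)
  expect_identical(cnt[["N/A"]], 1L)
})

test_that("outcome collapse follows the severity priority", {
  rp <- mkReports(c("A", "B", "C", "D"),
                  died = c("yes", "no", "absent", "absent"),
                  recovered = c("yes", "yes", "no", "absent"),
                  hospitalized = c("yes", "no", "no", "absent"))
  oc <- tabulateDemographics(vaersData(rp))$outcome
  cnt <- setNames(oc$count, oc$stratum)
  expect_identical(cnt[["Died"]], 1L)          # died outranks the others
  expect_identical(cnt[["Recovered"]], 1L)
  expect_identical(cnt[["Not recovered"]], 1L) # explicit RECOVD = N only
  expect_identical(cnt[["N/A"]], 1L)           # all flags absent
})

test_that("strata partition the reports and percents recompute", {
  vd <- generateDatabase(syntheticConfig(nTargetReports = 500,
                                         nBackgroundReports = 500,
                                         seed = 9))
  demo <- tabulateDemographics(vd)
  for (nm in c("sex", "age", "outcome", "onset")) {
    tab <- demo[[nm]]
    expect_identical(sum(tab$count), demo$total)
    expect_equal(tab$percent, round(100 * tab$count / demo$total, 2),
                 tolerance = 0.011)
    expect_lt(abs(sum(tab$percent) - 100), 0.05 * nrow(tab))
  }
})

test_that("dose categories bin 1..6, 7+ and N/A", {
  vx <- mkVax(sprintf("V%d", 1:5), dose = c("1", "6", "9", "7+", NA))
  vd <- vaersData(mkReports(sprintf("V%d", 1:5)), vx)
  tab <- tabulateVaccines(vd)$dose
  cnt <- setNames(tab$count, tab$stratum)
  expect_identical(cnt[["1"]], 1L)
  expect_identical(cnt[["6"]], 1L)
  expect_identical(cnt[["7+"]], 2L)
  expect_identical(cnt[["N/A"]], 1L)
})

test_that("vaccine tabulation is dose-level and flags unmapped brands", {
  vd <- vaersData(mkReports("A"), mkVax("A", brand = "MYSTERY SHOT"))
  expect_warning(tab <- tabulateVaccines(vd), "unmapped")
  expect_identical(tab$type$stratum, "UNKNOWN")
  expect_identical(tab$type$percent, 100)
  expect_identical(tab$total, 1L)
})

test_that("annual counts are (report, brand) pairs per year", {
  expect_identical(nrow(annualCounts(vaersData())), 0L)
  rp <- mkReports(c("A", "B", "C", "D"), year = c(2010L, 2010L, 2010L, 2011L))
  vx <- rbind(mkVax(c("A", "B", "C", "D")),
              mkVax("A", brand = "PNEUMO (PREVNAR13)"))
  ac <- annualCounts(vaersData(rp, vx))
  expect_identical(sum(ac$n), 5L)  # 5 distinct (report, brand) pairs
  expect_identical(ac$n[ac$brand_name == "PNEUMO (PNEUMOVAX)" &
                          ac$receive_year == 2010], 3L)
  expect_identical(ac$n[ac$brand_name == "PNEUMO (PREVNAR13)"], 1L)
})

test_that("empty input yields zero-count tables with zero percents", {
  demo <- tabulateDemographics(vaersData())
  expect_identical(demo$total, 0L)
  expect_true(all(demo$sex$count == 0))
  expect_true(all(demo$sex$percent == 0))
})
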