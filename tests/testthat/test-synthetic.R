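test_that("degenerate configs: empty cohorts and full masking", {
  vd <- generateDatabase(syntheticConfig(nTargetReports = 0,
                                         nBackgroundReports = 0))
  expect_identical(nReports(vd), 0L)
  expect_identical(nrow(vaccinations(vd)), 0L)
  expect_identical(nrow(symptoms(vd)), 0L)

  vd2 <- generateDatabase(syntheticConfig(nTargetReports = 50,
                                          nBackgroundReports = 50,
                                          missingRateAge = 1.0, seed = 3))
  expect_true(all(is.na(reports(vd2)$age_years)))

  vd3 <- generateDatabase(syntheticConfig(nTargetReports = 80,
                                          nBackgroundReports = 0,
                                          missingRateOutcome = 1.0,
                                          seed = 3))
  fl <- reports(vd3)[c("died", "recovered", "hospitalized")]
  expect_true(all(as.matrix(fl) == "absent"))
})

test_that("planted relative rate scales the target-arm PT frequency", {
  cat1 <- data.frame(pt_name = "EVENT X", soc_name = "SOME SOC",
                     background_probability = 0.05)
  cfg <- syntheticConfig(nTargetReports = 20000, nBackgroundReports = 20000,
                         ptCatalog = cat1,
                         plantedSignals = c("EVENT X" = 4.0), seed = 17)
  vd <- generateDatabase(cfg)
  tIds <- reports(vd)$report_id[
    vaccinations(vd)$brand_name == cfg@targetVaccineName]
  freqT <- sum(symptoms(vd)$report_id %in% tIds) / 20000
  freqB <- (nrow(symptoms(vd)) - sum(symptoms(vd)$report_id %in% tIds)) /
    20000
  se <- sqrt(0.20 * 0.80 / 20000)
  expect_lt(abs(freqT - 0.20), 3 * se)
  expect_lt(abs(freqB - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("unplanted marginal frequencies recover the catalog (n = 50,000)", {
  cfg <- syntheticConfig(nTargetReports = 0, nBackgroundReports = 50000,
                         plantedSignals = numeric(), seed = 5)
  vd <- generateDatabase(cfg)
  sy <- symptoms(vd)
  for (i in seq_len(nrow(cfg@ptCatalog))) {
    p <- cfg@ptCatalog$background_probability[i]
    f <- sum(sy$pt_name == cfg@ptCatalog$pt_name[i]) / 50000
    expect_lt(abs(f - p), 4 * sqrt(p * (1 - p) / 50000) + 1e-12)
  }
})

test_that("generation is a pure function of the config, down to CSV bytes", {
  cfg <- syntheticConfig(nTargetReports = 300, nBackgroundReports = 700,
                         seed = 11)
  vd1 <- generateDatabase(cfg)
  vd2 <- generateDatabase(cfg)
  expect_identical(reports(vd1), reports(vd2))
  expect_identical(symptoms(vd1), symptoms(vd2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- sort(writeVaersCsvs(vd1, d1))
  p2 <- sort(writeVaersCsvs(vd2, d2))
  expect_identical(basename(p1), basename(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("probabilities above 1 are clamped with a warning", {
  cat1 <- data.frame(pt_name = "EVENT X", soc_name = "S",
                     background_probability = 0.3)
  cfg <- syntheticConfig(nTargetReports = 200, nBackgroundReports = 0,
                         ptCatalog = cat1,
                         plantedSignals = c("EVENT X" = 10), seed = 2)
  expect_warning(vd <- generateDatabase(cfg), "clamp")
  expect_identical(nrow(symptoms(vd)), 200L)  # probability 1: every report
})

test_that("per-report PT count is truncated at the configured cap", {
  cat6 <- data.frame(pt_name = paste("EVENT", LETTERS[1:6]), soc_name = "S",
                     background_probability = 0.99)
  cfg <- syntheticConfig(nTargetReports = 0, nBackgroundReports = 100,
                         ptCatalog = cat6, plantedSignals = numeric(),
                         maxPtsPerReport = 3L, seed = 8)
  vd <- generateDatabase(cfg)
  expect_lte(max(table(symptoms(vd)$report_id)), 3L)
})

test_that("symptom rows pack five PTs per row (7 PTs -> 2 rows)", {
  pts <- c("PT ONE", "PT TWO", "PT THREE", "PT FOUR", "PT FIVE", "PT SIX",
           "PT SEVEN")
  vd <- vaersData(mkReports("A"), mkVax("A"), mkSymptoms(rep("A", 7), pts))
  d <- withr::local_tempdir()
  paths <- writeVaersCsvs(vd, d)
  sym <- utils::read.csv(grep("SYMPTOMS", paths, value = TRUE),
                         colClasses = "character")
  expect_identical(nrow(sym), 2L)
  expect_identical(sum(nzchar(unlist(sym[paste0("SYMPTOM", 1:5)]))), 7L)
})

test_that("empty database writes header-only CSV triplet", {
  d <- withr::local_tempdir()
  paths <- writeVaersCsvs(vaersData(), d)
  expect_length(paths, 3)
  for (p in paths) {
    df <- utils::read.csv(p, colClasses = "character")
    expect_identical(nrow(df), 0L)
  }
})
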