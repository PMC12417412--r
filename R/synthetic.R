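#' Default MedDRA PT catalog for the synthetic generator
#'
#' A small flat PT -> SOC catalog of adverse-event terms commonly reported
#' after vaccination, each with a background reporting probability (the
#' chance that a background-arm report mentions the PT). The probabilities
#' sum to about 2, so a typical synthetic report carries on the order of
#' two distinct PTs, in line with spontaneous-report databases. Four
#' intrinsically serious terms from the Designated Medical Event list are
#' included at rare background rates so DME screening is exercisable.
#'
#' @return data.frame(pt_name, soc_name, background_probability).
#' @export
defaultPtCatalog <- function() {
  soc_gen  <- "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS"
  soc_skin <- "SKIN AND SUBCUTANEOUS TISSUE DISORDERS"
  soc_nerv <- "NERVOUS SYSTEM DISORDERS"
  soc_gi   <- "GASTROINTESTINAL DISORDERS"
  soc_musc <- "MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS"
  soc_psy  <- "PSYCHIATRIC DISORDERS"
  soc_inf  <- "INFECTIONS AND INFESTATIONS"
  soc_prod <- "PRODUCT ISSUES"
  soc_blood <- "BLOOD AND LYMPHATIC SYSTEM DISORDERS"
  data.frame(
    pt_name = c("INJECTION SITE ERYTHEMA", "INJECTION SITE SWELLING",
                "INJECTION SITE PAIN", "INJECTION SITE WARMTH",
                "INJECTION SITE PRURITUS", "PYREXIA", "FATIGUE", "CHILLS",
                "MALAISE", "PAIN", "OEDEMA PERIPHERAL",
                "ERYTHEMA", "RASH", "PRURITUS", "URTICARIA", "SKIN WARM",
                "HEADACHE", "DIZZINESS", "SYNCOPE",
                "NAUSEA", "VOMITING", "DIARRHOEA",
                "MYALGIA", "ARTHRALGIA",
                "CRYING", "IRRITABILITY",
                "CELLULITIS",
                "ERYTHEMA MULTIFORME", "PRODUCT CONTAMINATION MICROBIAL",
                "HAEMOLYTIC ANAEMIA", "INTESTINAL PERFORATION"),
    soc_name = c(rep(soc_gen, 11), rep(soc_skin, 5), rep(soc_nerv, 3),
                 rep(soc_gi, 3), rep(soc_musc, 2), rep(soc_psy, 2),
                 soc_inf, soc_skin, soc_prod, soc_blood, soc_gi),
    background_probability = c(
      0.05, 0.04, 0.05, 0.02, 0.04, 0.20, 0.12, 0.10, 0.08, 0.12, 0.05,
      0.05, 0.12, 0.08, 0.05, 0.03,
      0.18, 0.10, 0.03,
      0.12, 0.08, 0.06,
      0.10, 0.08,
      0.04, 0.05,
      0.02,
      0.003, 0.001, 0.001, 0.001),
    stringsAsFactors = FALSE)
}

#' Default planted relative reporting rates
#'
#' Relative reporting rates planted on catalog PTs in the target arm,
#' mirroring the strongest reported disproportionality magnitudes for
#' pneumococcal vaccines (injection-site reactions around 4, crying /
#' irritability / cellulitis in pediatric reports far higher, and a rare
#' product-contamination DME signal above 11).
#'
#' @return named numeric vector of relative reporting rates.
#' @export
defaultPlantedSignals <- function() {
  c("INJECTION SITE ERYTHEMA" = 4.2, "INJECTION SITE SWELLING" = 4.2,
    "INJECTION SITE PAIN" = 2.8, "INJECTION SITE WARMTH" = 3.6,
    "ERYTHEMA" = 4.0, "SKIN WARM" = 3.6, "CRYING" = 7.2,
    "IRRITABILITY" = 10.8, "CELLULITIS" = 6.9,
    "ERYTHEMA MULTIFORME" = 5.0, "PRODUCT CONTAMINATION MICROBIAL" = 11.25)
}

#' Configure the synthetic report generator
#'
#' Builds a validated \linkS4class{SyntheticConfig}. All compositional
#' defaults are taken from the published pneumococcal-vaccine VAERS cohort:
#' sex mix 54.29/36.88/8.83 (female/male/unknown), age-band mix conditional
#' on a recorded age, clinical-outcome mix conditional on a documented
#' outcome, dose-number mix conditional on a recorded dose, and
#' missing-completely-at-random masking at the reported rates (19.23% age,
#' 41.45% dose, 34.22% clinical outcome). Onset delays follow a geometric
#' law (p = 0.5) capped at 365 days, reproducing the day-0 median of real
#' onset data.
#'
#' @param nTargetReports,nBackgroundReports cohort sizes.
#' @param ptCatalog PT catalog; see [defaultPtCatalog()].
#' @param plantedSignals named relative reporting rates (>= 0); a rate R
#'   multiplies the PT's background probability in the target arm (clamped
#'   at 1 with a warning).
#' @param maxPtsPerReport cap on distinct PTs per report (default 10,
#'   stored across multiple 5-column symptom rows on write).
#' @param sexProbs,ageBandProbs,outcomeProbs,doseProbs named probability
#'   vectors; each must sum to 1 within 1e-9.
#' @param onsetGeomProb geometric success probability for onset days.
#' @param missingRateAge,missingRateDose,missingRateOutcome MCAR masking
#'   fractions.
#' @param yearRange receive-year range (uniform).
#' @param targetVaccineName,backgroundVaccineName brand names for the two
#'   arms; the comparator ("all other vaccines") is pooled into one name.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nTargetReports = 100, nBackgroundReports = 1000)
#' vd <- generateDatabase(cfg)
#' nReports(vd)
#' @export
syntheticConfig <- function(nTargetReports = 5000L,
                            nBackgroundReports = 50000L,
                            ptCatalog = defaultPtCatalog(),
                            plantedSignals = defaultPlantedSignals(),
                            maxPtsPerReport = 10L,
                            sexProbs = c(female = 0.5429, male = 0.3688,
                                         unknown = 0.0883),
                            ageBandProbs = c("<18" = 60067, "18-64" = 26600,
                                             "65-84" = 37945,
                                             ">=85" = 2396) / 127008,
                            outcomeProbs = c(died = 2837,
                                             life_threatening = 3346,
                                             disability = 2564,
                                             prolonged_hospitalization = 636,
                                             hospitalized = 23499,
                                             recovered = 69505) / 102387,
                            doseProbs = c("1" = 51220, "2" = 21421,
                                          "3" = 9492, "4" = 9862, "5" = 832,
                                          "6" = 59, "7+" = 85) / 92971,
                            onsetGeomProb = 0.5,
                            missingRateAge = 0.1923,
                            missingRateDose = 0.4145,
                            missingRateOutcome = 0.3422,
                            yearRange = c(1990L, 2025L),
                            targetVaccineName = "PNEUMO (PNEUMOVAX)",
                            backgroundVaccineName = "OTHER VACCINE",
                            seed = 1L) {
  ptCatalog$pt_name <- normalizeTerm(ptCatalog$pt_name)
  if (length(plantedSignals))
    names(plantedSignals) <- normalizeTerm(names(plantedSignals))
  new("SyntheticConfig",
      nTargetReports = as.integer(nTargetReports),
      nBackgroundReports = as.integer(nBackgroundReports),
      ptCatalog = ptCatalog,
      plantedSignals = plantedSignals,
      maxPtsPerReport = as.integer(maxPtsPerReport),
      sexProbs = sexProbs, ageBandProbs = ageBandProbs,
      outcomeProbs = outcomeProbs, doseProbs = doseProbs,
      onsetGeomProb = onsetGeomProb,
      missingRateAge = missingRateAge,
      missingRateDose = missingRateDose,
      missingRateOutcome = missingRateOutcome,
      yearRange = as.integer(yearRange),
      targetVaccineName = targetVaccineName,
      backgroundVaccineName = backgroundVaccineName,
      seed = as.integer(seed))
}

# age drawn uniformly within the sampled band, one decimal, kept strictly
# inside band limits so completed-years banding round-trips
.drawAges <- function(band) {
  lo <- c("<18" = 0, "18-64" = 18, "65-84" = 65, ">=85" = 85)[band]
  hi <- c("<18" = 17.9, "18-64" = 64.9, "65-84" = 84.9, ">=85" = 99.9)[band]
  round(lo + stats::runif(length(band)) * (hi - lo), 1)
}

#' Generate a synthetic VAERS-style database
#'
#' Draws \code{nTargetReports} target-vaccine reports and
#' \code{nBackgroundReports} comparator reports. Each report draws every
#' catalog PT independently: with probability
#' \code{min(1, background_probability * R)} in the target arm when the PT
#' carries a planted relative rate R, and with the background probability
#' otherwise; the drawn set is then truncated at \code{maxPtsPerReport}.
#' Age, dose and clinical outcome are masked completely at random at the
#' configured rates. Generation is a pure function of the config: the same
#' config (including its seed) yields identical output.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{VaersData}.
#' @export
generateDatabase <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed)
  nT <- config@nTargetReports
  nB <- config@nBackgroundReports
  n <- nT + nB
  if (n == 0L) return(vaersData())

  id <- sprintf("SR%08d", seq_len(n))
  target <- c(rep(TRUE, nT), rep(FALSE, nB))

  yr <- sample(seq.int(config@yearRange[1], config@yearRange[2]), n,
               replace = TRUE)
  receive_date <- as.Date(sprintf("%d-01-01", yr)) +
    (sample.int(365L, n, replace = TRUE) - 1L)

  sex <- sample(names(config@sexProbs), n, TRUE, prob = config@sexProbs)
  band <- sample(names(config@ageBandProbs), n, TRUE,
                 prob = config@ageBandProbs)
  age <- .drawAges(band)
  age[stats::runif(n) < config@missingRateAge] <- NA_real_

  flags <- matrix("no", n, length(.FLAG_COLS),
                  dimnames = list(NULL, .FLAG_COLS))
  oc <- sample(names(config@outcomeProbs), n, TRUE,
               prob = config@outcomeProbs)
  flags[cbind(seq_len(n), match(oc, .FLAG_COLS))] <- "yes"
  flags[stats::runif(n) < config@missingRateOutcome, ] <- "absent"

  onset <- pmin(stats::rgeom(n, config@onsetGeomProb), 365L)

  rp <- data.frame(report_id = id, receive_date = receive_date,
                   receive_year = as.integer(yr), sex = sex,
                   age_years = age, stringsAsFactors = FALSE)
  rp <- cbind(rp, as.data.frame(flags, stringsAsFactors = FALSE))
  rp$onset_days <- as.integer(onset)

  dose <- sample(names(config@doseProbs), n, TRUE, prob = config@doseProbs)
  dose[stats::runif(n) < config@missingRateDose] <- NA_character_
  vx <- data.frame(
    report_id = id,
    vax_type = ifelse(target, "PPV", "OTH"),
    brand_name = ifelse(target, config@targetVaccineName,
                        config@backgroundVaccineName),
    manufacturer = ifelse(target, "MERCK & CO. INC.",
                          "UNKNOWN MANUFACTURER"),
    dose_series = dose, stringsAsFactors = FALSE)

  # per-PT Bernoulli draws; planted rates scale the target-arm probability
  cat <- config@ptCatalog
  K <- nrow(cat)
  pB <- cat$background_probability
  rr <- rep(1, K)
  if (length(config@plantedSignals)) {
    idx <- match(names(config@plantedSignals), cat$pt_name)
    rr[idx] <- config@plantedSignals
  }
  pT <- pB * rr
  if (any(pT > 1)) {
    warning(sprintf(
      "clamping %d planted PT probabilit%s at 1 (background x rate > 1)",
      sum(pT > 1), if (sum(pT > 1) == 1) "y" else "ies"))
    pT <- pmin(pT, 1)
  }
  pmat <- matrix(pB, n, K, byrow = TRUE)
  if (nT > 0) pmat[seq_len(nT), ] <- matrix(pT, nT, K, byrow = TRUE)
  hits <- matrix(stats::runif(n * K), n, K) < pmat

  # truncate at the per-report cap, dropping a random excess subset
  cnt <- rowSums(hits)
  over <- which(cnt > config@maxPtsPerReport)
  for (i in over) {
    drawn <- which(hits[i, ])
    hits[i, drawn[!drawn %in%
                    sample(drawn, config@maxPtsPerReport)]] <- FALSE
  }

  w <- which(hits, arr.ind = TRUE)
  sy <- data.frame(report_id = id[w[, 1]],
                   pt_name = cat$pt_name[w[, 2]],
                   meddra_version = "27.1", stringsAsFactors = FALSE)
  sy <- .sortBy(sy, sy$report_id, sy$pt_name)
  rownames(sy) <- NULL

  vaersData(rp, vx, sy)
}

# pack (report, PT) pairs into the 5-column VAERS symptom row layout
.packSymptomRows <- function(sy) {
  cols <- as.vector(rbind(paste0("SYMPTOM", 1:5),
                          paste0("SYMPTOMVERSION", 1:5)))
  if (!nrow(sy)) {
    out <- as.data.frame(matrix(character(), 0, 11), stringsAsFactors = FALSE)
    names(out) <- c("VAERS_ID", cols)
    return(out)
  }
  sy <- .sortBy(sy, sy$report_id, sy$pt_name)
  k <- stats::ave(seq_len(nrow(sy)), sy$report_id, FUN = seq_along)
  rowi <- (k - 1L) %/% 5L
  coli <- (k - 1L) %% 5L + 1L
  key <- paste(sy$report_id, rowi, sep = "\r")
  ukey <- unique(key)
  m <- matrix("", length(ukey), 10,
              dimnames = list(NULL, cols))
  ridx <- match(key, ukey)
  m[cbind(ridx, 2L * coli - 1L)] <- sy$pt_name
  m[cbind(ridx, 2L * coli)] <- sy$meddra_version
  out <- data.frame(VAERS_ID = sub("\r.*$", "", ukey),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m, stringsAsFactors = FALSE))
}

.flagOut <- c(yes = "Y", no = "N", absent = "")
.sexOut <- c(female = "F", male = "M", unknown = "U")

.writeCsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)))
  path
}

#' Write a database as yearly VAERS CSV triplets
#'
#' Emits one \code{<year>VAERSDATA.csv}, \code{<year>VAERSVAX.csv} and
#' \code{<year>VAERSSYMPTOMS.csv} per receive year, in the official VAERS
#' column dialect (symptoms packed five Preferred Terms per row). An empty
#' database yields a single header-only unprefixed triplet. Reading the
#' files back with [readDatabase()] reproduces the in-memory records.
#'
#' @param x a \linkS4class{VaersData}.
#' @param outDir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
writeVaersCsvs <- function(x, outDir) {
  stopifnot(is(x, "VaersData"))
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rp <- x@reports
  dataDf <- data.frame(
    VAERS_ID = rp$report_id,
    RECVDATE = format(rp$receive_date, "%m/%d/%Y"),
    SEX = unname(.sexOut[rp$sex]),
    AGE_YRS = ifelse(is.na(rp$age_years), "", as.character(rp$age_years)),
    DIED = unname(.flagOut[rp$died]),
    L_THREAT = unname(.flagOut[rp$life_threatening]),
    HOSPITAL = unname(.flagOut[rp$hospitalized]),
    X_STAY = unname(.flagOut[rp$prolonged_hospitalization]),
    DISABLE = unname(.flagOut[rp$disability]),
    RECOVD = unname(.flagOut[rp$recovered]),
    NUMDAYS = ifelse(is.na(rp$onset_days), "",
                     as.character(rp$onset_days)),
    stringsAsFactors = FALSE)
  if (!nrow(dataDf)) {
    dataDf <- dataDf[0, , drop = FALSE]
  }
  vx <- x@vaccinations
  vaxDf <- data.frame(
    VAERS_ID = vx$report_id, VAX_TYPE = vx$vax_type,
    VAX_MANU = vx$manufacturer, VAX_NAME = vx$brand_name,
    VAX_DOSE_SERIES = ifelse(is.na(vx$dose_series), "", vx$dose_series),
    stringsAsFactors = FALSE)
  symDf <- .packSymptomRows(x@symptoms)

  paths <- character()
  if (!nrow(rp)) {
    paths <- c(.writeCsv(dataDf, file.path(outDir, "VAERSDATA.csv")),
               .writeCsv(vaxDf, file.path(outDir, "VAERSVAX.csv")),
               .writeCsv(symDf, file.path(outDir, "VAERSSYMPTOMS.csv")))
    return(invisible(paths))
  }
  yearOf <- rp$receive_year[match(dataDf$VAERS_ID, rp$report_id)]
  vaxYear <- rp$receive_year[match(vaxDf$VAERS_ID, rp$report_id)]
  symYear <- rp$receive_year[match(symDf$VAERS_ID, rp$report_id)]
  for (y in sort(unique(yearOf))) {
    paths <- c(paths,
      .writeCsv(dataDf[yearOf == y, , drop = FALSE],
                file.path(outDir, sprintf("%dVAERSDATA.csv", y))),
      .writeCsv(vaxDf[vaxYear == y, , drop = FALSE],
                file.path(outDir, sprintf("%dVAERSVAX.csv", y))),
      .writeCsv(symDf[symYear == y, , drop = FALSE],
                file.path(outDir, sprintf("%dVAERSSYMPTOMS.csv", y))))
  }
  invisible(paths)
}
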