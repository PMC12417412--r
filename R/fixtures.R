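# Deterministic fixture reproducing the published marginal composition of
# the pneumococcal-vaccine VAERS cohort (1990 - March 2025).

# printed marginal counts of the cohort's characteristics tables
.T1_SEX <- c(Female = 85364L, Male = 57999L, `N/A` = 13881L)
.T1_AGE <- c(`<18` = 60067L, `18-64` = 26600L, `65-84` = 37945L,
             `>=85` = 2396L, `N/A` = 30236L)
.T1_OUTCOME <- c(Died = 2837L, Disability = 2564L, Hospitalized = 23499L,
                 `Life threatening` = 3346L,
                 `Prolonged hospitalization` = 636L, Recovered = 69505L,
                 `Not recovered` = 1048L, `N/A` = 53809L)
.T1_ONSET <- c(`0-30` = 121248L, `31-60` = 1289L, `61-90` = 492L,
               `91-120` = 273L, `121-150` = 186L, `151-180` = 145L,
               `181-365` = 604L, `N/A` = 33007L)
.T2_BRAND <- c("PNEUMO (CAPVAXIVE)" = 249L, "PNEUMO (PNEUMOVAX)" = 67391L,
               "PNEUMO (PNU-IMUNE)" = 2986L, "PNEUMO (PREVNAR)" = 29160L,
               "PNEUMO (PREVNAR13)" = 43773L, "PNEUMO (PREVNAR20)" = 4926L,
               "PNEUMO (SYNFLORIX)" = 1791L, "PNEUMO (VAXNEUVANCE)" = 1212L,
               "PNEUMO (NO BRAND NAME)" = 7290L)
.T2_MANU <- c("PNEUMO (CAPVAXIVE)" = "MERCK & CO. INC.",
              "PNEUMO (PNEUMOVAX)" = "MERCK & CO. INC.",
              "PNEUMO (PNU-IMUNE)" = "PFIZER\\WYETH",
              "PNEUMO (PREVNAR)" = "PFIZER\\WYETH",
              "PNEUMO (PREVNAR13)" = "PFIZER\\WYETH",
              "PNEUMO (PREVNAR20)" = "PFIZER\\WYETH",
              "PNEUMO (SYNFLORIX)" = "GLAXOSMITHKLINE BIOLOGICALS",
              "PNEUMO (VAXNEUVANCE)" = "MERCK & CO. INC.",
              "PNEUMO (NO BRAND NAME)" = "")
.T2_DOSE <- c("1" = 51220L, "2" = 21421L, "3" = 9492L, "4" = 9862L,
              "5" = 832L, "6" = 59L, "7+" = 85L, "N/A" = 65807L)

# representative in-band values used when expanding marginal counts
.AGE_REP <- c(`<18` = 5, `18-64` = 40, `65-84` = 70, `>=85` = 90,
              `N/A` = NA_real_)
.ONSET_REP <- c(`0-30` = 0L, `31-60` = 31L, `61-90` = 61L, `91-120` = 91L,
                `121-150` = 121L, `151-180` = 151L, `181-365` = 181L,
                `N/A` = NA_integer_)

#' Deterministic descriptive fixture (157,244 reports, 158,778 doses)
#'
#' Builds, by direct construction (no randomness), a
#' \linkS4class{VaersData} whose marginal stratum counts equal the
#' published characteristics of the pneumococcal-vaccine VAERS cohort:
#' 157,244 reports (85,364 female; 60,067 aged <18; 69,505 recovered;
#' 121,248 with onset within 30 days; ...) carrying 158,778 vaccination
#' entries distributed over the nine brand names with their printed
#' class/manufacturer/dose margins. The 1,048 reports by which the printed
#' outcome rows undersum the total are constructed as "recovered = no"
#' with no serious flag (an explicit not-recovered state outside the
#' printed categories). Marginals are assigned column-wise, so joint
#' distributions are not meaningful; the object exists to exercise the
#' descriptive tabulations at full scale.
#'
#' @return a \linkS4class{VaersData} (symptom table empty).
#' @export
descriptiveFixture <- function() {
  n <- sum(.T1_SEX)
  id <- sprintf("FX%08d", seq_len(n))

  sex <- rep(c("female", "male", "unknown"), .T1_SEX)
  age <- rep(unname(.AGE_REP[names(.T1_AGE)]), .T1_AGE)
  onset <- rep(unname(.ONSET_REP[names(.T1_ONSET)]), .T1_ONSET)

  flags <- matrix("absent", n, length(.FLAG_COLS),
                  dimnames = list(NULL, .FLAG_COLS))
  colOf <- c(Died = "died", Disability = "disability",
             Hospitalized = "hospitalized",
             `Life threatening` = "life_threatening",
             `Prolonged hospitalization` = "prolonged_hospitalization",
             Recovered = "recovered")
  start <- 1L
  for (cat in names(.T1_OUTCOME)) {
    k <- .T1_OUTCOME[[cat]]
    rows <- seq.int(start, length.out = k)
    if (cat %in% names(colOf)) {
      flags[rows, ] <- "no"
      flags[rows, colOf[[cat]]] <- "yes"
    } else if (cat == "Not recovered") {
      flags[rows, "recovered"] <- "no"
    } # "N/A": all flags stay absent
    start <- start + k
  }

  rp <- data.frame(report_id = id,
                   receive_date = as.Date("2010-06-15"),
                   receive_year = 2010L, sex = sex, age_years = age,
                   stringsAsFactors = FALSE)
  rp <- cbind(rp, as.data.frame(flags, stringsAsFactors = FALSE))
  rp$onset_days <- onset

  nDoses <- sum(.T2_BRAND)
  # every report gets one entry; the 1,534 extra doses go to the first ids
  vaxIds <- c(id, id[seq_len(nDoses - n)])
  brand <- rep(names(.T2_BRAND), .T2_BRAND)
  vx <- data.frame(
    report_id = vaxIds,
    vax_type = unname(pneumoTypeMap()[brand]),
    brand_name = brand,
    manufacturer = unname(.T2_MANU[brand]),
    dose_series = rep(c(as.character(1:6), "7+", NA_character_), .T2_DOSE),
    stringsAsFactors = FALSE)

  vaersData(rp, vx, .emptySymptoms())
}
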