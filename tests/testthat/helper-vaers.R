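# small hand-built databases for unit tests

mkReports <- function(id, sex = "female", age = 30, onset = 0L,
                      year = 2010L, died = "no", life_threatening = "no",
                      hospitalized = "no", prolonged_hospitalization = "no",
                      disability = "no", recovered = "yes") {
  n <- length(id)
  data.frame(report_id = id,
             receive_date = as.Date(sprintf("%d-06-15", rep_len(year, n))),
             receive_year = as.integer(rep_len(year, n)),
             sex = rep_len(sex, n),
             age_years = rep_len(age, n),
             died = rep_len(died, n),
             life_threatening = rep_len(life_threatening, n),
             hospitalized = rep_len(hospitalized, n),
             prolonged_hospitalization = rep_len(prolonged_hospitalization, n),
             disability = rep_len(disability, n),
             recovered = rep_len(recovered, n),
             onset_days = as.integer(rep_len(onset, n)),
             stringsAsFactors = FALSE)
}

mkVax <- function(id, brand = "PNEUMO (PNEUMOVAX)", dose = "1",
                  vax_type = "PPV", manufacturer = "MERCK & CO. INC.") {
  n <- length(id)
  data.frame(report_id = id, vax_type = rep_len(vax_type, n),
             brand_name = rep_len(brand, n),
             manufacturer = rep_len(manufacturer, n),
             dose_series = rep_len(dose, n), stringsAsFactors = FALSE)
}

mkSymptoms <- function(id, pt) {
  data.frame(report_id = id, pt_name = normalizeTerm(pt),
             meddra_version = "27.1", stringsAsFactors = FALSE)
}

# a tiny two-arm database: nT target reports (brand PNEUMOVAX), nB
# background, with symptom pairs given as list(report_index = pts)
mkTinyVd <- function(nT, nB, symptomMap = list()) {
  n <- nT + nB
  id <- sprintf("T%03d", seq_len(n))
  rp <- mkReports(id)
  vx <- mkVax(id, brand = c(rep("PNEUMO (PNEUMOVAX)", nT),
                            rep("OTHER VACCINE", nB)))
  sy <- if (length(symptomMap)) {
    do.call(rbind, lapply(seq_along(symptomMap), function(i) {
      mkSymptoms(rep(id[as.integer(names(symptomMap)[i])],
                     length(symptomMap[[i]])), symptomMap[[i]])
    }))
  } else mkSymptoms(character(), character())
  vaersData(rp, vx, sy)
}

# brute-force 2x2 recount, independent of buildTables
bruteTables <- function(vd, targetIds, unit = "report") {
  sy <- symptoms(vd)
  pts <- sort(unique(sy$pt_name))
  isT <- sy$report_id %in% targetIds
  if (unit == "report") {
    nT <- length(targetIds); nB <- nReports(vd) - nT
    do.call(rbind, lapply(pts, function(p) {
      a <- length(unique(sy$report_id[isT & sy$pt_name == p]))
      c_ <- length(unique(sy$report_id[!isT & sy$pt_name == p]))
      data.frame(pt_name = p, a = a, b = nT - a, c = c_, d = nB - c_)
    }))
  } else {
    Tn <- sum(isT); Bn <- sum(!isT)
    do.call(rbind, lapply(pts, function(p) {
      a <- sum(isT & sy$pt_name == p)
      c_ <- sum(!isT & sy$pt_name == p)
      data.frame(pt_name = p, a = a, b = Tn - a, c = c_, d = Bn - c_)
    }))
  }
}
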