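# Descriptive surfaces: demographics/outcome/onset strata, vaccine
# characteristics, and annual report counts.

.AGE_BANDS <- c("<18", "18-64", "65-84", ">=85", "N/A")
.ONSET_BREAKS <- c(0, 30, 60, 90, 120, 150, 180, 365)
.ONSET_LABELS <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                   "151-180", "181-365")

.ageBand <- function(age) {
  out <- rep("N/A", length(age))
  ok <- !is.na(age)
  out[ok & age < 18] <- "<18"
  out[ok & age >= 18 & age < 65] <- "18-64"
  out[ok & age >= 65 & age < 85] <- "65-84"
  out[ok & age >= 85] <- ">=85"
  out
}

.onsetBin <- function(onset) {
  out <- rep("N/A", length(onset))
  ok <- !is.na(onset) & onset >= 0 & onset <= 365
  idx <- findInterval(onset[ok], c(0L, 31L, 61L, 91L, 121L, 151L, 181L))
  out[ok] <- .ONSET_LABELS[idx]
  out
}

# collapse the six non-exclusive outcome flags to one category by a
# severity priority; an explicit RECOVD = "N" with no serious flag is a
# real VAERS state outside the printed categories and is kept as its own
# "Not recovered" stratum so the remaining strata partition exactly
.outcomeCategory <- function(rp, priority = .OUTCOME_PRIORITY) {
  n <- nrow(rp)
  out <- rep("N/A", n)
  for (fc in rev(priority)) {
    lab <- switch(fc, died = "Died", life_threatening = "Life threatening",
                  disability = "Disability",
                  prolonged_hospitalization = "Prolonged hospitalization",
                  hospitalized = "Hospitalized", recovered = "Recovered")
    out[rp[[fc]] == "yes"] <- lab
  }
  out[out == "N/A" & rp$recovered == "no"] <- "Not recovered"
  out
}

.stratify <- function(values, levels, total) {
  counts <- vapply(levels, function(l) sum(values == l), integer(1))
  data.frame(stratum = levels, count = unname(counts),
             percent = .pct(unname(counts), total),
             stringsAsFactors = FALSE)
}

#' Tabulate report demographics, outcomes, and onset
#'
#' Stratifies a report set by sex, age band (completed years: <18, 18-64,
#' 65-84, >=85, N/A), clinical outcome (severity-priority collapse of the
#' six flags), and onset-day bin (0-30 through 181-365; onset > 365 or
#' missing is excluded from bins and reported as N/A). All percentages use
#' the full report count as denominator. Onset summary statistics
#' (mean/SD/median/min/max) are computed over onset days in [0, 365].
#'
#' @param x a \linkS4class{VaersData} or a reports data.frame.
#' @param priority outcome severity order, most severe first.
#' @return list with data.frames \code{sex}, \code{age}, \code{outcome},
#'   \code{onset}, the scalar \code{total}, and \code{onset_stats}.
#' @examples
#' vd <- generateDatabase(syntheticConfig(nTargetReports = 200,
#'                                        nBackgroundReports = 0))
#' tabulateDemographics(vd)$sex
#' @export
tabulateDemographics <- function(x, priority = .OUTCOME_PRIORITY) {
  rp <- if (is(x, "VaersData")) x@reports else x
  total <- nrow(rp)

  sexLab <- c(female = "Female", male = "Male", unknown = "N/A")[rp$sex]
  sexTab <- .stratify(sexLab, c("Female", "Male", "N/A"), total)

  ageTab <- .stratify(.ageBand(rp$age_years), .AGE_BANDS, total)

  ocLevels <- c("Died", "Disability", "Hospitalized", "Life threatening",
                "Prolonged hospitalization", "Recovered", "Not recovered",
                "N/A")
  ocTab <- .stratify(.outcomeCategory(rp, priority), ocLevels, total)

  onTab <- .stratify(.onsetBin(rp$onset_days), c(.ONSET_LABELS, "N/A"),
                     total)

  ons <- rp$onset_days[!is.na(rp$onset_days) & rp$onset_days >= 0 &
                         rp$onset_days <= 365]
  stats <- if (length(ons)) {
    list(mean = mean(ons), sd = stats::sd(ons),
         median = stats::median(ons), min = min(ons), max = max(ons))
  } else {
    list(mean = NA_real_, sd = NA_real_, median = NA_real_,
         min = NA_real_, max = NA_real_)
  }

  list(sex = sexTab, age = ageTab, outcome = ocTab, onset = onTab,
       onset_stats = stats, total = total)
}

.doseCategory <- function(dose) {
  out <- rep("N/A", length(dose))
  known <- !is.na(dose) & nzchar(dose)
  num <- suppressWarnings(as.integer(dose))
  out[known & !is.na(num) & num >= 1 & num <= 6] <-
    dose[known & !is.na(num) & num >= 1 & num <= 6]
  out[known & !is.na(num) & num >= 7] <- "7+"
  out[known & dose == "7+"] <- "7+"
  out
}

#' Tabulate vaccine characteristics at dose level
#'
#' Stratifies vaccination entries (doses, not reports) by vaccine class,
#' brand name, manufacturer, and dose number ({1..6, 7+, N/A}).
#'
#' @param x a \linkS4class{VaersData} or a vaccinations data.frame.
#' @param typeMap named character vector brand -> vaccine class; unmapped
#'   brands are counted under \code{"UNKNOWN"} with a warning.
#' @return list with data.frames \code{type}, \code{brand},
#'   \code{manufacturer}, \code{dose}, and the scalar \code{total}.
#' @export
tabulateVaccines <- function(x, typeMap = pneumoTypeMap()) {
  vx <- if (is(x, "VaersData")) x@vaccinations else x
  total <- nrow(vx)

  type <- unname(typeMap[normalizeTerm(vx$brand_name)])
  if (anyNA(type)) {
    warning(sum(is.na(type)), " dose(s) with unmapped brand counted as ",
            "UNKNOWN")
    type[is.na(type)] <- "UNKNOWN"
  }
  typeTab <- .stratify(type, sort(unique(type)), total)

  brandTab <- .stratify(vx$brand_name, sort(unique(vx$brand_name)), total)

  manu <- ifelse(is.na(vx$manufacturer) | !nzchar(vx$manufacturer), "N/A",
                 vx$manufacturer)
  manuTab <- .stratify(manu, sort(unique(manu)), total)

  doseCat <- .doseCategory(vx$dose_series)
  doseTab <- .stratify(doseCat, c(as.character(1:6), "7+", "N/A"), total)

  list(type = typeTab, brand = brandTab, manufacturer = manuTab,
       dose = doseTab, total = total)
}

#' Annual report counts per vaccine brand
#'
#' Counts distinct (report, brand) pairs per receive year: the data behind
#' a reports-per-year-per-vaccine trend figure.
#'
#' @param x a \linkS4class{VaersData}.
#' @return long-format data.frame(brand_name, receive_year, n).
#' @export
annualCounts <- function(x) {
  stopifnot(is(x, "VaersData"))
  vx <- x@vaccinations
  if (!nrow(vx))
    return(data.frame(brand_name = character(), receive_year = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  yr <- x@reports$receive_year[match(vx$report_id, x@reports$report_id)]
  pairs <- unique(data.frame(brand_name = vx$brand_name,
                             receive_year = yr,
                             report_id = vx$report_id,
                             stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = pairs$report_id),
                          by = list(brand_name = pairs$brand_name,
                                    receive_year = pairs$receive_year),
                          FUN = length)
  .sortBy(agg, agg$brand_name, agg$receive_year)
}
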