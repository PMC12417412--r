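# Internal helpers shared across modules.

# Outcome flag columns on the report table, in VAERS order.
.FLAG_COLS <- c("died", "life_threatening", "hospitalized",
                "prolonged_hospitalization", "disability", "recovered")

# Severity priority used to collapse the non-exclusive flags into one
# outcome category (most severe wins).
.OUTCOME_PRIORITY <- c("died", "life_threatening", "disability",
                       "prolonged_hospitalization", "hospitalized",
                       "recovered")

#' Normalize a term or vaccine name
#'
#' Uppercases, trims, and collapses internal whitespace, matching VAERS
#' Preferred Term conventions. Used for PT names, vaccine names and DME
#' terms so that matching is exact after normalization.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalizeTerm <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# round() in R does banker's rounding at .5; printed tables round half up.
.roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.pct <- function(count, total, digits = 2) {
  if (total <= 0) return(rep(0, length(count)))
  .roundHalfUp(100 * count / total, digits)
}

.emptyReports <- function() {
  data.frame(report_id = character(), receive_date = as.Date(character()),
             receive_year = integer(), sex = character(),
             age_years = numeric(),
             died = character(), life_threatening = character(),
             hospitalized = character(),
             prolonged_hospitalization = character(),
             disability = character(), recovered = character(),
             onset_days = integer(), stringsAsFactors = FALSE)
}

.emptyVaccinations <- function() {
  data.frame(report_id = character(), vax_type = character(),
             brand_name = character(), manufacturer = character(),
             dose_series = character(), stringsAsFactors = FALSE)
}

.emptySymptoms <- function() {
  data.frame(report_id = character(), pt_name = character(),
             meddra_version = character(), stringsAsFactors = FALSE)
}

# stable data.frame sort by one or more columns
.sortBy <- function(df, ...) {
  df[do.call(order, list(...)), , drop = FALSE]
}
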