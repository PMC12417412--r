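#' @import methods
NULL

#' VaersData: a linked spontaneous-report database
#'
#' Container for the three linked tables of a VAERS-style database: one row
#' per safety report (demographics, outcome flags, onset), one row per
#' vaccination entry (a report can carry several doses/products), and one
#' row per (report, MedDRA Preferred Term) coded event. The validity method
#' enforces the referential and uniqueness invariants the downstream
#' statistics rely on.
#'
#' @slot reports data.frame with columns \code{report_id},
#'   \code{receive_date} (Date), \code{receive_year}, \code{sex}
#'   (\code{"female"/"male"/"unknown"}), \code{age_years} (NA when missing),
#'   the six outcome flags \code{died}, \code{life_threatening},
#'   \code{hospitalized}, \code{prolonged_hospitalization},
#'   \code{disability}, \code{recovered} (each \code{"yes"/"no"/"absent"}),
#'   and \code{onset_days} (nonnegative integer, NA when missing).
#' @slot vaccinations data.frame with columns \code{report_id},
#'   \code{vax_type}, \code{brand_name}, \code{manufacturer},
#'   \code{dose_series} (character, NA when missing).
#' @slot symptoms data.frame with columns \code{report_id}, \code{pt_name}
#'   (normalized, nonempty), \code{meddra_version}; (report_id, pt_name)
#'   pairs are unique.
#' @slot meta list of load diagnostics (orphan counts, unparseable cells).
#'
#' @seealso [vaersData()], [readDatabase()], [generateDatabase()]
#' @export
setClass("VaersData",
         representation(reports = "data.frame",
                        vaccinations = "data.frame",
                        symptoms = "data.frame",
                        meta = "list"))

setValidity("VaersData", function(object) {
  msg <- character()
  rep_cols <- c("report_id", "receive_date", "receive_year", "sex",
                "age_years", .FLAG_COLS, "onset_days")
  miss <- setdiff(rep_cols, names(object@reports))
  if (length(miss))
    msg <- c(msg, paste("reports: missing columns:",
                        paste(miss, collapse = ", ")))
  vax_cols <- c("report_id", "vax_type", "brand_name", "manufacturer",
                "dose_series")
  miss <- setdiff(vax_cols, names(object@vaccinations))
  if (length(miss))
    msg <- c(msg, paste("vaccinations: missing columns:",
                        paste(miss, collapse = ", ")))
  sym_cols <- c("report_id", "pt_name", "meddra_version")
  miss <- setdiff(sym_cols, names(object@symptoms))
  if (length(miss))
    msg <- c(msg, paste("symptoms: missing columns:",
                        paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)

  ids <- object@reports$report_id
  if (anyDuplicated(ids))
    msg <- c(msg, "reports: report_id values must be unique")
  if (nrow(object@vaccinations) &&
      !all(object@vaccinations$report_id %in% ids))
    msg <- c(msg, "vaccinations: report_id not present in reports")
  if (nrow(object@symptoms) && !all(object@symptoms$report_id %in% ids))
    msg <- c(msg, "symptoms: report_id not present in reports")
  od <- object@reports$onset_days
  if (any(!is.na(od) & od < 0))
    msg <- c(msg, "reports: onset_days must be >= 0 when present")
  for (fc in .FLAG_COLS) {
    v <- object@reports[[fc]]
    if (!all(v %in% c("yes", "no", "absent")))
      msg <- c(msg, paste0("reports: ", fc,
                           " must be 'yes', 'no' or 'absent'"))
  }
  if (nrow(object@symptoms)) {
    if (any(!nzchar(object@symptoms$pt_name)))
      msg <- c(msg, "symptoms: pt_name must be nonempty")
    if (anyDuplicated(object@symptoms[c("report_id", "pt_name")]))
      msg <- c(msg, "symptoms: duplicate (report_id, pt_name) pairs")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic report generator
#'
#' The stated world of the generator: cohort sizes, a PT catalog with
#' background reporting probabilities and SOC labels, planted relative
#' reporting rates for selected PTs, demographic/outcome/dose composition,
#' an onset-delay law concentrated at day 0, and missing-completely-at-
#' random masking rates for age, dose and clinical outcome. Defaults follow
#' the published composition of the pneumococcal-vaccine report cohort; see
#' [syntheticConfig()].
#'
#' @slot nTargetReports,nBackgroundReports cohort sizes (>= 0).
#' @slot ptCatalog data.frame(pt_name, soc_name, background_probability).
#' @slot plantedSignals named numeric, relative reporting rate per PT
#'   (>= 0); names must appear in the catalog.
#' @slot maxPtsPerReport cap on distinct PTs per report.
#' @slot sexProbs,ageBandProbs,outcomeProbs,doseProbs named probability
#'   vectors (each sums to 1 within 1e-9).
#' @slot onsetGeomProb success probability of the truncated geometric
#'   onset-day law.
#' @slot missingRateAge,missingRateDose,missingRateOutcome MCAR masking
#'   fractions in [0, 1].
#' @slot yearRange integer (start_year, end_year).
#' @slot targetVaccineName,backgroundVaccineName brand names written to the
#'   vaccination table for the two arms.
#' @slot seed integer RNG seed; generation is a pure function of the config.
#' @export
setClass("SyntheticConfig",
         representation(nTargetReports = "integer",
                        nBackgroundReports = "integer",
                        ptCatalog = "data.frame",
                        plantedSignals = "numeric",
                        maxPtsPerReport = "integer",
                        sexProbs = "numeric",
                        ageBandProbs = "numeric",
                        outcomeProbs = "numeric",
                        doseProbs = "numeric",
                        onsetGeomProb = "numeric",
                        missingRateAge = "numeric",
                        missingRateDose = "numeric",
                        missingRateOutcome = "numeric",
                        yearRange = "integer",
                        targetVaccineName = "character",
                        backgroundVaccineName = "character",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nTargetReports < 0 || object@nBackgroundReports < 0)
    msg <- c(msg, "cohort sizes must be >= 0")
  cat <- object@ptCatalog
  need <- c("pt_name", "soc_name", "background_probability")
  if (!all(need %in% names(cat))) {
    msg <- c(msg, "ptCatalog needs pt_name, soc_name, background_probability")
    return(msg)
  }
  bp <- cat$background_probability
  if (any(!is.finite(bp)) || any(bp < 0) || any(bp > 1))
    msg <- c(msg, "background probabilities must be finite in [0, 1]")
  if (anyDuplicated(cat$pt_name))
    msg <- c(msg, "ptCatalog pt_name values must be unique")
  ps <- object@plantedSignals
  if (length(ps)) {
    if (is.null(names(ps)) || any(!nzchar(names(ps))))
      msg <- c(msg, "plantedSignals must be a named numeric vector")
    else if (!all(names(ps) %in% cat$pt_name))
      msg <- c(msg, paste("planted PT not in catalog:",
                          paste(setdiff(names(ps), cat$pt_name),
                                collapse = ", ")))
    if (any(!is.finite(ps)) || any(ps < 0))
      msg <- c(msg, "planted relative rates must be finite and >= 0")
  }
  for (nm in c("sexProbs", "ageBandProbs", "outcomeProbs", "doseProbs")) {
    p <- slot(object, nm)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, paste(nm, "must be nonnegative and sum to 1 (1e-9)"))
  }
  for (nm in c("missingRateAge", "missingRateDose", "missingRateOutcome")) {
    r <- slot(object, nm)
    if (r < 0 || r > 1) msg <- c(msg, paste(nm, "must be in [0, 1]"))
  }
  if (object@onsetGeomProb <= 0 || object@onsetGeomProb > 1)
    msg <- c(msg, "onsetGeomProb must be in (0, 1]")
  if (length(object@yearRange) != 2 ||
      object@yearRange[1] > object@yearRange[2])
    msg <- c(msg, "yearRange must be (start_year, end_year)")
  if (object@maxPtsPerReport < 1)
    msg <- c(msg, "maxPtsPerReport must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BcpnnPriors: hyperparameters of the BCPNN information component
#'
#' Beta/Dirichlet prior constants of the Bayesian confidence propagation
#' neural network in its closed-form (single vaccine-event pair)
#' parameterization: marginal priors Beta(alpha1, alpha - alpha1) and
#' Beta(beta1, beta - beta1), joint cell prior weight gamma11, with the
#' dependent constant gamma derived from the table margins so that the
#' prior is centred on independence. Defaults are the classical choices
#' alpha = beta = 2, alpha1 = beta1 = 1, gamma11 = 1.
#'
#' @export
setClass("BcpnnPriors",
         representation(alpha = "numeric", beta = "numeric",
                        alpha1 = "numeric", beta1 = "numeric",
                        gamma11 = "numeric"))

setValidity("BcpnnPriors", function(object) {
  v <- c(object@alpha, object@beta, object@alpha1, object@beta1,
         object@gamma11)
  if (any(!is.finite(v)) || any(v <= 0)) "all priors must be > 0" else TRUE
})

#' MgpsHyperparams: fitted gamma-Poisson mixture prior
#'
#' The DuMouchel empirical-Bayes prior on the relative reporting rate
#' lambda: a two-component gamma mixture
#' P * Gamma(alpha1, beta1) + (1 - P) * Gamma(alpha2, beta2)
#' (shape/rate), fitted by maximizing the marginal negative-binomial
#' likelihood of the observed cell counts given their expected counts.
#'
#' @slot alpha1,beta1,alpha2,beta2 positive shape/rate parameters.
#' @slot pMix mixture weight in (0, 1).
#' @slot converged optimizer convergence flag.
#' @slot loglik maximized marginal log-likelihood.
#' @export
setClass("MgpsHyperparams",
         representation(alpha1 = "numeric", beta1 = "numeric",
                        alpha2 = "numeric", beta2 = "numeric",
                        pMix = "numeric", converged = "logical",
                        loglik = "numeric"))

setValidity("MgpsHyperparams", function(object) {
  v <- c(object@alpha1, object@beta1, object@alpha2, object@beta2)
  msg <- character()
  if (any(!is.finite(v)) || any(v <= 0))
    msg <- c(msg, "shape/rate parameters must be > 0")
  if (object@pMix <= 0 || object@pMix >= 1)
    msg <- c(msg, "pMix must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
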