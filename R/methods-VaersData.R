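#' Construct a VaersData object
#'
#' @param reports,vaccinations,symptoms the three linked tables; see
#'   \linkS4class{VaersData} for required columns.
#' @param meta optional list of load diagnostics.
#' @return a validated \linkS4class{VaersData}.
#' @examples
#' vd <- generateDatabase(syntheticConfig(nTargetReports = 50,
#'                                        nBackgroundReports = 200))
#' vd
#' @export
vaersData <- function(reports = .emptyReports(),
                      vaccinations = .emptyVaccinations(),
                      symptoms = .emptySymptoms(),
                      meta = list()) {
  new("VaersData", reports = reports, vaccinations = vaccinations,
      symptoms = symptoms, meta = meta)
}

#' @rdname vaersData
#' @param x a VaersData object.
#' @export
setGeneric("reports", function(x) standardGeneric("reports"))

#' @rdname vaersData
#' @export
setMethod("reports", "VaersData", function(x) x@reports)

#' @rdname vaersData
#' @export
setGeneric("vaccinations", function(x) standardGeneric("vaccinations"))

#' @rdname vaersData
#' @export
setMethod("vaccinations", "VaersData", function(x) x@vaccinations)

#' @rdname vaersData
#' @export
setGeneric("symptoms", function(x) standardGeneric("symptoms"))

#' @rdname vaersData
#' @export
setMethod("symptoms", "VaersData", function(x) x@symptoms)

#' @rdname vaersData
#' @export
setGeneric("nReports", function(x) standardGeneric("nReports"))

#' @rdname vaersData
#' @export
setMethod("nReports", "VaersData", function(x) nrow(x@reports))

setMethod("show", "VaersData", function(object) {
  cat("VaersData object\n")
  cat(sprintf("  reports      : %d\n", nrow(object@reports)))
  cat(sprintf("  vaccinations : %d entries, %d brands\n",
              nrow(object@vaccinations),
              length(unique(object@vaccinations$brand_name))))
  cat(sprintf("  symptoms     : %d (report, PT) pairs, %d distinct PTs\n",
              nrow(object@symptoms),
              length(unique(object@symptoms$pt_name))))
  yr <- object@reports$receive_year
  if (length(yr))
    cat(sprintf("  years        : %d-%d\n", min(yr), max(yr)))
  if (length(object@meta))
    cat("  meta         :", paste(names(object@meta), unlist(object@meta),
                                  sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

# Subset a database to a set of report ids, keeping links consistent.
.subsetVaers <- function(x, ids) {
  keep <- x@reports$report_id %in% ids
  vaersData(x@reports[keep, , drop = FALSE],
            x@vaccinations[x@vaccinations$report_id %in% ids, , drop = FALSE],
            x@symptoms[x@symptoms$report_id %in% ids, , drop = FALSE],
            meta = x@meta)
}

setMethod("show", "MgpsHyperparams", function(object) {
  cat("MgpsHyperparams (gamma-Poisson mixture prior)\n")
  cat(sprintf("  component 1: Gamma(shape=%.4g, rate=%.4g)\n",
              object@alpha1, object@beta1))
  cat(sprintf("  component 2: Gamma(shape=%.4g, rate=%.4g)\n",
              object@alpha2, object@beta2))
  cat(sprintf("  mixture weight P = %.4g; converged = %s; loglik = %.4g\n",
              object@pMix, object@converged, object@loglik))
  invisible(NULL)
})

setMethod("show", "BcpnnPriors", function(object) {
  cat(sprintf(
    "BcpnnPriors: alpha=%g beta=%g alpha1=%g beta1=%g gamma11=%g\n",
    object@alpha, object@beta, object@alpha1, object@beta1, object@gamma11))
  invisible(NULL)
})

#' @rdname bcpnnIc
#' @param alpha,beta,alpha1,beta1,gamma11 positive prior constants.
#' @export
bcpnnPriors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                        gamma11 = 1) {
  new("BcpnnPriors", alpha = alpha, beta = beta, alpha1 = alpha1,
      beta1 = beta1, gamma11 = gamma11)
}
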