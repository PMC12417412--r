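# Contingency-table construction, joint signal metrics, positivity
# classification, and SOC-level aggregation.

#' Signal positivity thresholds
#'
#' The field-standard quartet: ROR positive iff a >= min_count and the ROR
#' 95% lower bound exceeds \code{ror_lower}; PRR positive iff PRR >=
#' \code{prr_min}, chi-square >= \code{chi2_min} and a >= min_count; BCPNN
#' positive iff IC - 2SD > \code{ic_lower}; MGPS positive iff EBGM05 >
#' \code{ebgm05_min}. The overall call combines the four (all-of by
#' default, any-of optionally) and additionally requires the BH-adjusted
#' p-value <= \code{q}.
#'
#' @param min_count minimum report count a.
#' @param ror_lower,prr_min,chi2_min,ic_lower,ebgm05_min method thresholds.
#' @param q FDR level on the BH-adjusted chi-square p-value.
#' @param rule \code{"all"} or \code{"any"} combination of the four flags.
#' @return a list of thresholds for [classifySignals()].
#' @export
signalThresholds <- function(min_count = 3, ror_lower = 1, prr_min = 2,
                             chi2_min = 4, ic_lower = 0, ebgm05_min = 2,
                             q = 0.05, rule = c("all", "any")) {
  rule <- match.arg(rule)
  list(min_count = min_count, ror_lower = ror_lower, prr_min = prr_min,
       chi2_min = chi2_min, ic_lower = ic_lower, ebgm05_min = ebgm05_min,
       q = q, rule = rule)
}

#' Build per-PT 2x2 contingency tables
#'
#' Under \code{unit = "report"} (PT-level detection), a is the number of
#' target reports mentioning the PT, b the remaining target reports, c/d
#' the same in the comparator arm. Under \code{unit = "event"}
#' (occurrence-level, used for SOC aggregation), the margins are distinct
#' (report, PT) pairs rather than reports. Every PT observed at least once
#' gets a table.
#'
#' @param x a \linkS4class{VaersData}.
#' @param targetIds report ids of the target cohort (nonempty).
#' @param unit counting unit.
#' @return data.frame(pt_name, a, b, c, d), sorted by decreasing a.
#' @export
buildTables <- function(x, targetIds, unit = c("report", "event")) {
  stopifnot(is(x, "VaersData"))
  unit <- match.arg(unit)
  if (!length(targetIds)) stop("empty target set: no comparison possible")
  sy <- x@symptoms
  isT <- sy$report_id %in% targetIds
  aTab <- table(sy$pt_name[isT])
  cTab <- table(sy$pt_name[!isT])
  pts <- sort(unique(sy$pt_name))
  a <- as.integer(ifelse(is.na(match(pts, names(aTab))), 0L,
                         aTab[match(pts, names(aTab))]))
  c_ <- as.integer(ifelse(is.na(match(pts, names(cTab))), 0L,
                          cTab[match(pts, names(cTab))]))
  if (unit == "report") {
    nT <- length(unique(targetIds))
    nB <- nReports(x) - nT
    b <- nT - a
    d <- nB - c_
  } else {
    Tn <- sum(isT)
    Bn <- sum(!isT)
    b <- Tn - a
    d <- Bn - c_
  }
  out <- data.frame(pt_name = pts, a = a, b = b, c = c_, d = d,
                    stringsAsFactors = FALSE)
  out <- .sortBy(out, -out$a, out$pt_name)
  rownames(out) <- NULL
  out
}

#' Classify signal positivity
#'
#' Applies the threshold quartet of [signalThresholds()] to a metrics
#' data.frame (columns a, ror_lo95, prr, chi2, ic_minus_2sd, ebgm05,
#' p_adjust); NA statistics never classify as positive.
#'
#' @param metrics data.frame of signal metrics.
#' @param thresholds list from [signalThresholds()].
#' @return the metrics with logical columns positive_ror, positive_prr,
#'   positive_bcpnn, positive_mgps, positive_overall appended.
#' @export
classifySignals <- function(metrics, thresholds = signalThresholds()) {
  th <- thresholds
  isTRUEv <- function(x) !is.na(x) & x
  metrics$positive_ror <- isTRUEv(metrics$a >= th$min_count &
                                    metrics$ror_lo95 > th$ror_lower)
  metrics$positive_prr <- isTRUEv(metrics$prr >= th$prr_min &
                                    metrics$chi2 >= th$chi2_min &
                                    metrics$a >= th$min_count)
  metrics$positive_bcpnn <- isTRUEv(metrics$ic_minus_2sd > th$ic_lower)
  metrics$positive_mgps <- isTRUEv(metrics$ebgm05 > th$ebgm05_min)
  combo <- if (th$rule == "all") {
    metrics$positive_ror & metrics$positive_prr & metrics$positive_bcpnn &
      metrics$positive_mgps
  } else {
    metrics$positive_ror | metrics$positive_prr | metrics$positive_bcpnn |
      metrics$positive_mgps
  }
  metrics$positive_overall <- combo & isTRUEv(metrics$p_adjust <= th$q)
  metrics
}

# all four statistics + BH on a table frame; h may be NULL (fit here)
.computeMetrics <- function(tab, priors, h = NULL) {
  if (is.null(h)) h <- mgpsFit(tab)
  r <- rorStat(tab)
  p <- prrStat(tab)
  ic <- bcpnnIc(tab, priors)
  eb <- ebgmStat(tab, h)
  out <- cbind(tab, r, p, ic, eb)
  out$p_adjust <- bhAdjust(out$p_raw)
  attr(out, "mgps") <- h
  out
}

#' Run four-method disproportionality detection at the PT level
#'
#' Builds per-PT tables for the target cohort, fits the MGPS prior across
#' all PT cells of the target-vs-rest frame, computes ROR (with 95% CI),
#' PRR (with Pearson chi-square and its p-value), the BCPNN information
#' component (with IC - 2SD), and EBGM (with EBGM05), applies
#' Benjamini-Hochberg FDR adjustment to the chi-square p-values across all
#' PTs, and classifies positivity.
#'
#' @inheritParams buildTables
#' @param ptToSoc optional named character vector PT -> SOC (unmapped PTs
#'   get \code{"UNCLASSIFIED"}).
#' @param priors BCPNN priors.
#' @param thresholds positivity thresholds.
#' @return data.frame of signal metrics, one row per PT, sorted by
#'   decreasing a; the fitted \linkS4class{MgpsHyperparams} is attached as
#'   attribute \code{"mgps"}.
#' @export
detectSignals <- function(x, targetIds, ptToSoc = NULL,
                          unit = c("report", "event"),
                          priors = bcpnnPriors(),
                          thresholds = signalThresholds()) {
  tab <- buildTables(x, targetIds, unit = match.arg(unit))
  out <- .computeMetrics(tab, priors)
  soc <- if (is.null(ptToSoc)) rep(NA_character_, nrow(out)) else {
    s <- unname(ptToSoc[out$pt_name])
    s[is.na(s)] <- "UNCLASSIFIED"
    s
  }
  h <- attr(out, "mgps")
  out <- cbind(out[1], soc_name = soc, out[-1])
  out <- classifySignals(out, thresholds)
  rownames(out) <- NULL
  attr(out, "mgps") <- h
  out
}

#' Aggregate PT tables to System Organ Class level
#'
#' SOC cell counts are occurrence-level sums of the member-PT cells
#' (unit = "event"): the SOC a is the total number of distinct (report,
#' PT) pairs falling in the SOC's PTs in the target arm, which can exceed
#' the report total. All four statistics, BH adjustment (across SOCs) and
#' classification are recomputed on the aggregated tables.
#'
#' @inheritParams detectSignals
#' @param ptToSoc named character vector PT -> SOC; unmapped PTs are pooled
#'   under \code{"UNCLASSIFIED"}.
#' @return data.frame of SOC-level metrics sorted by decreasing a.
#' @export
aggregateSoc <- function(x, targetIds, ptToSoc,
                         priors = bcpnnPriors(),
                         thresholds = signalThresholds()) {
  tab <- buildTables(x, targetIds, unit = "event")
  soc <- unname(ptToSoc[tab$pt_name])
  soc[is.na(soc)] <- "UNCLASSIFIED"
  Tn <- tab$a[1] + tab$b[1]   # event-unit margins are shared across rows
  Bn <- tab$c[1] + tab$d[1]
  a <- tapply(tab$a, soc, sum)
  c_ <- tapply(tab$c, soc, sum)
  socTab <- data.frame(soc_name = names(a), a = as.integer(a),
                       b = as.integer(Tn - a), c = as.integer(c_),
                       d = as.integer(Bn - c_), stringsAsFactors = FALSE)
  # the empirical-Bayes prior is fitted on the full PT frame (more cells =
  # stabler prior; also keeps SOC metrics consistent with PT metrics when a
  # SOC holds a single PT)
  h <- mgpsFit(tab)
  out <- .computeMetrics(socTab, priors, h)
  out <- classifySignals(out, thresholds)
  out <- .sortBy(out, -out$a, out$soc_name)
  rownames(out) <- NULL
  out
}
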