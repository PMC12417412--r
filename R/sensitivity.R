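# Missing-data sensitivity analysis: re-run detection on complete-case
# subsets and quantify stability of the top signals.

#' Drop reports with a missing field
#'
#' Complete-case filtering for the sensitivity analysis. Age is present
#' when \code{age_years} is non-missing; dose when at least one
#' vaccination entry carries a known \code{dose_series}; clinical outcome
#' when at least one of the six outcome flags is not \code{"absent"}. The
#' filter is applied to the whole database (both arms symmetrically), which
#' avoids inducing artificial disproportion between arms.
#'
#' @param x a \linkS4class{VaersData}.
#' @param field one of \code{"age"}, \code{"dose"}, \code{"outcome"}.
#' @return the filtered \linkS4class{VaersData}.
#' @export
dropMissing <- function(x, field = c("age", "dose", "outcome")) {
  stopifnot(is(x, "VaersData"))
  field <- match.arg(field)
  rp <- x@reports
  keep <- switch(field,
    age = rp$report_id[!is.na(rp$age_years)],
    dose = unique(x@vaccinations$report_id[
      !is.na(x@vaccinations$dose_series)]),
    outcome = rp$report_id[
      rowSums(as.matrix(rp[.FLAG_COLS]) != "absent") > 0])
  if (!length(keep))
    warning("dropMissing('", field, "'): no reports retained")
  .subsetVaers(x, keep)
}

#' Compare top-k signal rankings between two runs
#'
#' Ranks both signal tables by the declared key (default: report count a,
#' ties by ROR, both decreasing), restricted to rows classified
#' positive_overall when that column is present. Returns the top-k overlap
#' fraction and the signed rank shift of each base top-k PT that is also
#' ranked in the subset run.
#'
#' @param base,subset PT-level metrics from [detectSignals()].
#' @param k size of the head-to-head list (capped at the shorter ranking,
#'   with a warning).
#' @return list(overlap, shifts, k) where \code{shifts} is
#'   data.frame(pt_name, rank_base, rank_subset, shift).
#' @export
compareRankings <- function(base, subset, k = 10) {
  rank_of <- function(s) {
    if ("positive_overall" %in% names(s))
      s <- s[!is.na(s$positive_overall) & s$positive_overall, ,
             drop = FALSE]
    s <- .sortBy(s, -s$a, -s$ror, s$pt_name)
    s$pt_name
  }
  rb <- rank_of(base)
  rs <- rank_of(subset)
  kmax <- min(length(rb), length(rs))
  if (k > kmax) {
    warning("k = ", k, " exceeds ranked list length; capped at ", kmax)
    k <- kmax
  }
  if (k == 0)
    return(list(overlap = NA_real_,
                shifts = data.frame(pt_name = character(),
                                    rank_base = integer(),
                                    rank_subset = integer(),
                                    shift = integer()), k = 0L))
  topB <- rb[seq_len(k)]
  topS <- rs[seq_len(k)]
  overlap <- length(intersect(topB, topS)) / k
  inBoth <- topB[topB %in% rs]
  shifts <- data.frame(pt_name = inBoth,
                       rank_base = match(inBoth, rb),
                       rank_subset = match(inBoth, rs),
                       stringsAsFactors = FALSE)
  shifts$shift <- shifts$rank_subset - shifts$rank_base
  list(overlap = overlap, shifts = shifts, k = as.integer(k))
}
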