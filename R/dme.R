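# Designated Medical Event screening.

#' Load a Designated Medical Event term list
#'
#' Reads a one-term-per-row CSV (column \code{pt_name}, or single
#' headerless column) of intrinsically serious MedDRA Preferred Terms.
#' Terms are normalized (uppercase, collapsed whitespace) and deduplicated.
#' The packaged default is a 62-term reconstruction of the public EMA
#' Designated Medical Event list, shipped as a user-editable CSV at
#' \code{system.file("extdata", "dme_list.csv", package = "vaersmine")}.
#'
#' @param path CSV path; \code{NULL} loads the packaged list.
#' @param sourceLabel provenance label stored alongside the terms.
#' @return list with \code{terms} (normalized character set) and
#'   \code{source_label}.
#' @export
loadDmeList <- function(path = NULL, sourceLabel = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dme_list.csv", package = "vaersmine")
    if (is.null(sourceLabel))
      sourceLabel <- "EMA designated medical events (packaged reconstruction)"
  }
  if (is.null(sourceLabel)) sourceLabel <- path
  df <- tryCatch(utils::read.csv(path, colClasses = "character"),
                 error = function(e)
                   stop("cannot read DME list '", path, "': ",
                        conditionMessage(e)))
  col <- if ("pt_name" %in% names(df)) df$pt_name else df[[1]]
  terms <- unique(normalizeTerm(col))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("DME list '", path, "' is empty")
  list(terms = sort(terms), source_label = sourceLabel)
}

#' Screen detected signals against a DME list
#'
#' Intersects the detected PT signals with the DME terms. The first
#' returned table holds every detected DME-listed PT (report count >= 1,
#' regardless of positivity); the second the subset classified
#' positive_overall. Each match keeps its SOC annotation and all four
#' statistics, i.e. the rows are forest-plot ready.
#'
#' @param signals PT-level metrics from [detectSignals()].
#' @param dme a DME list from [loadDmeList()].
#' @return list(all = data.frame, positive = data.frame).
#' @export
screenDme <- function(signals, dme) {
  stopifnot(is.list(dme), !is.null(dme$terms))
  hit <- normalizeTerm(signals$pt_name) %in% dme$terms & signals$a >= 1
  all <- signals[hit, , drop = FALSE]
  pos <- all[!is.na(all$positive_overall) & all$positive_overall, ,
             drop = FALSE]
  rownames(all) <- rownames(pos) <- NULL
  list(all = all, positive = pos)
}
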