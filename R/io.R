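# Reading and filtering VAERS-format CSV triplets.

.DATA_COLS <- c("VAERS_ID", "RECVDATE", "SEX", "AGE_YRS", "DIED", "L_THREAT",
                "HOSPITAL", "X_STAY", "DISABLE", "RECOVD", "NUMDAYS")
.VAX_COLS <- c("VAERS_ID", "VAX_TYPE", "VAX_MANU", "VAX_NAME",
               "VAX_DOSE_SERIES")
.SYM_COLS <- c("VAERS_ID", paste0("SYMPTOM", 1:5))

# real VAERS exports are Latin-1; fall back to UTF-8
.readVaersCsv <- function(path, required) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", fileEncoding = "latin1",
                    check.names = TRUE),
    error = function(e)
      utils::read.csv(path, colClasses = "character",
                      fileEncoding = "UTF-8"))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df
}

.parseFlag <- function(x) {
  out <- rep("absent", length(x))
  out[x %in% c("Y", "y")] <- "yes"
  out[x %in% c("N", "n")] <- "no"
  out
}

.parseDate <- function(x) {
  d <- as.Date(x, format = "%m/%d/%Y")
  iso <- is.na(d) & nzchar(x)
  d[iso] <- as.Date(x[iso], format = "%Y-%m-%d", optional = TRUE)
  d
}

#' Read a VAERS-format CSV database
#'
#' Loads one or more yearly VAERSDATA/VAERSVAX/VAERSSYMPTOMS triplets into
#' a linked \linkS4class{VaersData}. Symptom rows are unpivoted (each
#' nonempty SYMPTOM1..SYMPTOM5 cell becomes one coded event), duplicate
#' (report, PT) pairs are collapsed, and vaccination/symptom rows whose
#' VAERS_ID has no VAERSDATA row are dropped with a logged count.
#' Unparseable numeric cells are treated as absent and counted in the
#' load diagnostics (available via \code{x@meta}).
#'
#' @param path a directory containing the triplets, or a character vector
#'   of VAERSDATA csv paths (matching VAX/SYMPTOMS files are located by
#'   name substitution).
#' @return a \linkS4class{VaersData} with load diagnostics in \code{meta}.
#' @export
readDatabase <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    dataFiles <- list.files(path, pattern = "VAERSDATA\\.csv$",
                            full.names = TRUE)
  } else {
    dataFiles <- path
  }
  if (!length(dataFiles))
    stop("no VAERSDATA.csv files found under '", paste(path, collapse = ", "),
         "'")
  missing <- dataFiles[!file.exists(dataFiles)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))

  datL <- list(); vaxL <- list(); symL <- list()
  for (f in dataFiles) {
    datL[[f]] <- .readVaersCsv(f, .DATA_COLS)
    vf <- sub("VAERSDATA\\.csv$", "VAERSVAX.csv", f)
    sf <- sub("VAERSDATA\\.csv$", "VAERSSYMPTOMS.csv", f)
    if (!file.exists(vf)) stop("missing companion file: ", vf)
    if (!file.exists(sf)) stop("missing companion file: ", sf)
    vaxL[[vf]] <- .readVaersCsv(vf, .VAX_COLS)
    symL[[sf]] <- .readVaersCsv(sf, .SYM_COLS)
  }
  dat <- do.call(rbind, lapply(datL, function(d) d[.DATA_COLS]))
  vax <- do.call(rbind, lapply(vaxL, function(d) d[.VAX_COLS]))
  symRaw <- do.call(rbind, lapply(symL, function(d) {
    vcols <- paste0("SYMPTOMVERSION", 1:5)
    for (vc in vcols) if (!vc %in% names(d)) d[[vc]] <- ""
    d[c(.SYM_COLS, vcols)]
  }))

  dup <- duplicated(dat$VAERS_ID)
  if (any(dup)) {
    message(sum(dup), " duplicate VAERS_ID row(s) in VAERSDATA dropped")
    dat <- dat[!dup, , drop = FALSE]
  }

  age <- suppressWarnings(as.numeric(dat$AGE_YRS))
  badAge <- sum(nzchar(dat$AGE_YRS) & is.na(age))
  nd <- suppressWarnings(as.integer(dat$NUMDAYS))
  badNd <- sum(nzchar(dat$NUMDAYS) & is.na(nd))
  neg <- !is.na(nd) & nd < 0
  badNd <- badNd + sum(neg)
  nd[neg] <- NA_integer_
  rdate <- .parseDate(dat$RECVDATE)

  sex <- rep("unknown", nrow(dat))
  sex[dat$SEX %in% c("F", "f")] <- "female"
  sex[dat$SEX %in% c("M", "m")] <- "male"

  rp <- data.frame(
    report_id = dat$VAERS_ID,
    receive_date = rdate,
    receive_year = as.integer(format(rdate, "%Y")),
    sex = sex, age_years = age,
    died = .parseFlag(dat$DIED),
    life_threatening = .parseFlag(dat$L_THREAT),
    hospitalized = .parseFlag(dat$HOSPITAL),
    prolonged_hospitalization = .parseFlag(dat$X_STAY),
    disability = .parseFlag(dat$DISABLE),
    recovered = .parseFlag(dat$RECOVD),
    onset_days = nd, stringsAsFactors = FALSE)

  vx <- data.frame(
    report_id = vax$VAERS_ID, vax_type = vax$VAX_TYPE,
    brand_name = vax$VAX_NAME, manufacturer = vax$VAX_MANU,
    dose_series = ifelse(nzchar(vax$VAX_DOSE_SERIES), vax$VAX_DOSE_SERIES,
                         NA_character_),
    stringsAsFactors = FALSE)

  # unpivot the 5-PT-per-row symptom layout
  syL <- lapply(1:5, function(k) {
    pt <- normalizeTerm(symRaw[[paste0("SYMPTOM", k)]])
    data.frame(report_id = symRaw$VAERS_ID, pt_name = pt,
               meddra_version = symRaw[[paste0("SYMPTOMVERSION", k)]],
               stringsAsFactors = FALSE)[nzchar(pt), , drop = FALSE]
  })
  sy <- do.call(rbind, syL)
  sy <- sy[!duplicated(sy[c("report_id", "pt_name")]), , drop = FALSE]

  orphVax <- !(vx$report_id %in% rp$report_id)
  orphSym <- !(sy$report_id %in% rp$report_id)
  if (any(orphVax))
    message(sum(orphVax), " vaccination row(s) with unknown VAERS_ID dropped")
  if (any(orphSym))
    message(sum(orphSym), " symptom entr(ies) with unknown VAERS_ID dropped")
  vx <- vx[!orphVax, , drop = FALSE]
  sy <- .sortBy(sy[!orphSym, , drop = FALSE], sy$report_id[!orphSym],
                sy$pt_name[!orphSym])
  rownames(rp) <- rownames(vx) <- rownames(sy) <- NULL

  vaersData(rp, vx, sy,
            meta = list(orphan_vaccinations = sum(orphVax),
                        orphan_symptoms = sum(orphSym),
                        unparsed_age = badAge,
                        unparsed_numdays = badNd,
                        duplicate_reports = sum(dup)))
}

#' Select reports exposed to the target vaccines
#'
#' A report belongs to the target cohort iff at least one of its
#' vaccination entries matches one of \code{targetNames} exactly after
#' whitespace/case normalization, and (when a window is given) its receive
#' date falls inside the window. Reports are never double-counted: a report
#' with several target doses appears once in the returned set, while its
#' entries still count individually in dose-level tabulations.
#'
#' @param x a \linkS4class{VaersData}.
#' @param targetNames nonempty character vector of vaccine names.
#' @param window optional length-2 Date (or coercible) vector
#'   (start, end), applied to the receive date.
#' @return sorted character vector of report ids.
#' @export
selectTargetReports <- function(x, targetNames, window = NULL) {
  stopifnot(is(x, "VaersData"))
  if (!length(targetNames)) stop("targetNames must be nonempty")
  tn <- normalizeTerm(targetNames)
  vx <- x@vaccinations
  brands <- normalizeTerm(vx$brand_name)
  absent <- setdiff(tn, unique(brands))
  if (length(absent))
    warning("target vaccine name(s) absent from data: ",
            paste(absent, collapse = ", "))
  ids <- unique(vx$report_id[brands %in% tn])
  if (!is.null(window)) {
    window <- as.Date(window)
    rd <- x@reports$receive_date[match(ids, x@reports$report_id)]
    ids <- ids[!is.na(rd) & rd >= window[1] & rd <= window[2]]
  }
  if (!length(ids)) warning("target report set is empty")
  sort(ids)
}

#' Brand to vaccine-class map for U.S. pneumococcal vaccines
#'
#' Maps each VAERS pneumococcal brand string to its vaccine class
#' (PCV7/PCV10/PCV13/PCV15/PCV20/PCV21/PPSV); the unbranded entry is
#' pooled with the polysaccharide class, consistent with published
#' dose-level tabulations.
#'
#' @return named character vector brand -> class.
#' @export
pneumoTypeMap <- function() {
  c("PNEUMO (CAPVAXIVE)" = "PCV21",
    "PNEUMO (PNEUMOVAX)" = "PPSV",
    "PNEUMO (PNU-IMUNE)" = "PPSV",
    "PNEUMO (PREVNAR)" = "PCV7",
    "PNEUMO (PREVNAR13)" = "PCV13",
    "PNEUMO (PREVNAR20)" = "PCV20",
    "PNEUMO (SYNFLORIX)" = "PCV10",
    "PNEUMO (VAXNEUVANCE)" = "PCV15",
    "PNEUMO (NO BRAND NAME)" = "PPSV")
}
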