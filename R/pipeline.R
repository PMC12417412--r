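# End-to-end pipeline orchestration: config handling, step execution,
# output CSVs, and a JSON run manifest.

.CONFIG_KEYS <- c("input", "filter", "thresholds", "counting_unit", "dme",
                  "sensitivity", "output")

.defaultConfig <- function() {
  list(
    input = list(mode = "simulate", n_target_reports = 5000L,
                 n_background_reports = 50000L, seed = 1L,
                 csv_dir = NULL, pt_soc_map = NULL),
    filter = list(target_names = list("PNEUMO (PNEUMOVAX)"),
                  window = list("1990-01-01", "2025-03-31")),
    thresholds = list(min_count = 3, ror_lower = 1, prr_min = 2,
                      chi2_min = 4, ic_lower = 0, ebgm05_min = 2,
                      q = 0.05, rule = "all"),
    counting_unit = "report",
    dme = list(path = NULL),
    sensitivity = list(fields = list("age", "dose", "outcome"), k = 10L),
    output = list(dir = "vaersmine_run"))
}

# shallow-merge user config over defaults, rejecting unknown keys
.mergeConfig <- function(user) {
  bad <- setdiff(names(user), .CONFIG_KEYS)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(.CONFIG_KEYS, collapse = ", "))
  cfg <- .defaultConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      bad2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad2))
        stop("invalid config key(s) under '", k, "': ",
             paste(bad2, collapse = ", "), "; valid: ",
             paste(names(cfg[[k]]), collapse = ", "))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Read and validate a pipeline configuration
#'
#' Configurations are JSON (sections: input, filter, thresholds,
#' counting_unit, dme, sensitivity, output); omitted keys take packaged
#' defaults, unknown keys raise an error listing the valid ones.
#'
#' @param path JSON config path; \code{NULL} returns the packaged demo
#'   defaults.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path = NULL) {
  if (is.null(path)) return(.defaultConfig())
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = FALSE)
  .mergeConfig(user)
}

.writeOut <- function(df, dir, name, manifest) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE, na = "")
  c(manifest, stats::setNames(list(nrow(df)), name))
}

.sensColumns <- function(s, k) {
  s <- s[!is.na(s$positive_overall) & s$positive_overall, , drop = FALSE]
  s <- .sortBy(s, -s$a, -s$ror, s$pt_name)
  utils::head(data.frame(
    pt_name = s$pt_name, a = s$a,
    ror = s$ror, ror_lo95 = s$ror_lo95, ror_hi95 = s$ror_hi95,
    prr = s$prr, chi2 = s$chi2, ebgm = s$ebgm, ebgm05 = s$ebgm05,
    ic = s$ic, ic_minus_2sd = s$ic_minus_2sd,
    stringsAsFactors = FALSE), k)
}

#' Run the surveillance pipeline
#'
#' Executes the requested step(s) and writes the module outputs plus a JSON
#' run manifest under the output directory. Steps: \code{"simulate"}
#' (generate a synthetic database and write its VAERS CSV triplets),
#' \code{"describe"} (demographic/vaccine/annual tables),
#' \code{"detect"} (PT- and SOC-level four-method signal tables, volcano
#' and forest plot data), \code{"dme"} (DME screening report),
#' \code{"sensitivity"} (complete-case reruns and ranking stability), or
#' \code{"all"}. Identical config + seed produce identical outputs.
#'
#' @param config a config list from [readPipelineConfig()], a JSON path, or
#'   \code{NULL} for the packaged demo configuration.
#' @param step pipeline step.
#' @param outDir output directory (overrides the config's output.dir).
#' @param seed RNG seed (overrides the config's input.seed).
#' @return the run manifest, invisibly.
#' @export
runPipeline <- function(config = NULL, step = c("all", "simulate",
                                                "describe", "detect", "dme",
                                                "sensitivity"),
                        outDir = NULL, seed = NULL) {
  step <- match.arg(step)
  if (is.character(config)) config <- readPipelineConfig(config)
  else if (is.null(config)) config <- .defaultConfig()
  else config <- .mergeConfig(config)
  if (!is.null(seed)) config$input$seed <- as.integer(seed)
  dir <- if (!is.null(outDir)) outDir else config$output$dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  manifest <- list()

  # --- acquire data ---------------------------------------------------
  if (identical(config$input$mode, "simulate")) {
    scfg <- syntheticConfig(
      nTargetReports = config$input$n_target_reports,
      nBackgroundReports = config$input$n_background_reports,
      seed = config$input$seed)
    vd <- generateDatabase(scfg)
    ptToSoc <- stats::setNames(scfg@ptCatalog$soc_name,
                               scfg@ptCatalog$pt_name)
    targetNames <- scfg@targetVaccineName
    if (step %in% c("all", "simulate")) {
      simDir <- file.path(dir, "simdata")
      paths <- writeVaersCsvs(vd, simDir)
      manifest$simulated_csvs <- length(paths)
      manifest <- .writeOut(scfg@ptCatalog[c("pt_name", "soc_name")],
                            dir, "pt_soc_map.csv", manifest)
    }
  } else if (identical(config$input$mode, "csv")) {
    if (is.null(config$input$csv_dir))
      stop("input.mode = 'csv' requires input.csv_dir")
    vd <- readDatabase(config$input$csv_dir)
    ptToSoc <- if (!is.null(config$input$pt_soc_map)) {
      m <- utils::read.csv(config$input$pt_soc_map,
                           colClasses = "character")
      stats::setNames(m$soc_name, normalizeTerm(m$pt_name))
    } else stats::setNames(character(), character())
    targetNames <- unlist(config$filter$target_names)
  } else stop("input.mode must be 'simulate' or 'csv'")
  if (step == "simulate") {
    manifest$n_reports <- nReports(vd)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }

  window <- as.Date(unlist(config$filter$window))
  targetIds <- selectTargetReports(vd, targetNames, window = window)
  th <- do.call(signalThresholds, config$thresholds)

  # --- describe -------------------------------------------------------
  if (step %in% c("all", "describe")) {
    tvd <- .subsetVaers(vd, targetIds)
    demo <- tabulateDemographics(tvd)
    for (nm in c("sex", "age", "outcome", "onset"))
      manifest <- .writeOut(demo[[nm]], dir,
                            paste0("demographics_", nm, ".csv"), manifest)
    vac <- suppressWarnings(tabulateVaccines(tvd))
    for (nm in c("type", "brand", "manufacturer", "dose"))
      manifest <- .writeOut(vac[[nm]], dir,
                            paste0("vaccines_", nm, ".csv"), manifest)
    manifest <- .writeOut(annualCounts(tvd), dir, "annual_counts.csv",
                          manifest)
    jsonlite::write_json(
      list(total_reports = demo$total, total_doses = vac$total,
           onset = demo$onset_stats),
      file.path(dir, "descriptive_summary.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
  }

  # --- detect ---------------------------------------------------------
  signals <- NULL
  if (step %in% c("all", "detect", "dme", "sensitivity")) {
    signals <- detectSignals(vd, targetIds, ptToSoc = ptToSoc,
                             unit = config$counting_unit, thresholds = th)
  }
  if (step %in% c("all", "detect")) {
    manifest <- .writeOut(signals, dir, "signals.csv", manifest)
    socSig <- aggregateSoc(vd, targetIds, ptToSoc, thresholds = th)
    manifest <- .writeOut(socSig, dir, "soc_signals.csv", manifest)
    volcano <- data.frame(soc_name = socSig$soc_name, ror = socSig$ror,
                          neg_log10_p_adjust = -log10(socSig$p_adjust),
                          stringsAsFactors = FALSE)
    manifest <- .writeOut(volcano, dir, "volcano.csv", manifest)
    forest <- .sensColumns(signals, 50)
    forest$soc_name <-
      signals$soc_name[match(forest$pt_name, signals$pt_name)]
    manifest <- .writeOut(forest, dir, "forest.csv", manifest)
  }

  # --- dme ------------------------------------------------------------
  if (step %in% c("all", "dme")) {
    dme <- loadDmeList(config$dme$path)
    scr <- screenDme(signals, dme)
    rep <- scr$all
    manifest <- .writeOut(rep, dir, "dme_report.csv", manifest)
    manifest$dme_positive <- nrow(scr$positive)
  }

  # --- sensitivity ----------------------------------------------------
  if (step %in% c("all", "sensitivity")) {
    fields <- unlist(config$sensitivity$fields)
    k <- config$sensitivity$k
    summ <- data.frame(field = character(), retained = integer(),
                       overlap = numeric(), stringsAsFactors = FALSE)
    for (f in fields) {
      sub <- dropMissing(vd, f)
      subIds <- intersect(targetIds, sub@reports$report_id)
      subSig <- detectSignals(sub, subIds, ptToSoc = ptToSoc,
                              unit = config$counting_unit, thresholds = th)
      manifest <- .writeOut(.sensColumns(subSig, k), dir,
                            paste0("sensitivity_", f, ".csv"), manifest)
      cmp <- compareRankings(signals, subSig, k = k)
      summ <- rbind(summ, data.frame(field = f, retained = nReports(sub),
                                     overlap = cmp$overlap))
    }
    manifest <- .writeOut(summ, dir, "sensitivity_summary.csv", manifest)
  }

  # --- manifest -------------------------------------------------------
  cfgPath <- file.path(dir, "run_config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("vaersmine")),
    r_version = as.character(getRversion()),
    seed = config$input$seed,
    config_hash = unname(tools::md5sum(cfgPath)),
    n_reports = nReports(vd),
    n_target_reports = length(targetIds)), manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
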