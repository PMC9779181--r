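seriesCols <- c("subject_id", "mode", "t_sec", "hr_bpm", "vo2_mlkgmin",
                "rer")

#' Write a cohort to subjects.csv and series.csv
#'
#' Long-format series (one row per 15-s sample) and one row per subject;
#' the generating seed is recorded in a `#` header comment line of each
#' file.
#'
#' @param cohort An `hrvo2Cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrvo2Cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             series = file.path(dir, "series.csv"))
  for (nm in names(paths)) {
    con <- file(paths[[nm]], "w")
    writeLines(sprintf("# hrvo2 synthetic cohort (master seed %d)",
                       cohort$seed), con)
    utils::write.csv(cohort[[nm]], con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read a cohort from subjects.csv and series.csv
#'
#' Validates the schema (naming any missing column) and units: HR must
#' lie in 20-250 bpm and VO2 in (0, 90] mL/kg/min, with offending rows
#' named in the error.
#'
#' @param subjectsPath,seriesPath CSV paths in the schema written by
#'   [writeCohort()] (header comment lines starting `#` are skipped).
#' @return An `hrvo2Cohort` (without generating-truth fields).
#' @export
readCohort <- function(subjectsPath, seriesPath) {
  rd <- function(p) utils::read.csv(p, comment.char = "#")
  subjects <- rd(subjectsPath)
  series <- rd(seriesPath)
  needSub <- c("subject_id", "sex", "age_yr", "hr_rest", "vo2_rest",
               "hr_max_treadmill", "vo2_max_treadmill", "hr_max_cycle",
               "vo2_max_cycle")
  missSub <- setdiff(needSub, names(subjects))
  if (length(missSub))
    stop("subjects file lacks column(s): ", paste(missSub, collapse = ", "),
         call. = FALSE)
  missSer <- setdiff(seriesCols, names(series))
  if (length(missSer))
    stop("series file lacks column(s): ", paste(missSer, collapse = ", "),
         call. = FALSE)
  badHr <- which(series$hr_bpm < 20 | series$hr_bpm > 250)
  if (length(badHr))
    stop(sprintf("series row %d: HR %.1f bpm outside 20-250",
                 badHr[1], series$hr_bpm[badHr[1]]), call. = FALSE)
  badVo2 <- which(series$vo2_mlkgmin <= 0 | series$vo2_mlkgmin > 90)
  if (length(badVo2))
    stop(sprintf("series row %d: VO2 %.2f mL/kg/min outside (0, 90]",
                 badVo2[1], series$vo2_mlkgmin[badVo2[1]]), call. = FALSE)
  out <- list(subjects = subjects, series = series, seed = NA_integer_)
  class(out) <- "hrvo2Cohort"
  out
}

#' Pipeline configuration
#'
#' Exactly one of `inputPaths` (existing subjects/series CSVs) or
#' `synthetic` (a generation block) must be given; a master seed is
#' required when generating.
#'
#' @param inputPaths `list(subjects = ..., series = ...)` or `NULL`.
#' @param synthetic `list(config = cohortConfig(), truth =
#'   defaultTruth())` or `NULL`; defaults are filled in for omitted
#'   elements.
#' @param xScales x-scales to fit (default both).
#' @param gammaOn Gamma-prior target (see [modelSpec()]).
#' @param mcmc An [mcmcConfig()].
#' @param thresholds Diagnostic thresholds (see [diagnoseFit()]).
#' @param outputDir Where [runPipeline()] writes its outputs.
#' @param masterSeed Master seed for synthetic generation.
#' @param compareGroups Also run the cohort-description comparisons
#'   (slower; default FALSE).
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(inputPaths = NULL, synthetic = NULL,
                           xScales = c("percent_vo2max", "percent_vo2r"),
                           gammaOn = "variance",
                           mcmc = mcmcConfig(),
                           thresholds = c(rhat = 1.002, ess = 8600,
                                          raftery = 1.05),
                           outputDir = tempfile("hrvo2_run_"),
                           masterSeed = 1L,
                           compareGroups = FALSE) {
  if (is.null(inputPaths) == is.null(synthetic))
    stop("give exactly one of inputPaths or synthetic", call. = FALSE)
  if (!is.null(synthetic)) {
    if (is.null(masterSeed)) stop("masterSeed required when generating",
                                  call. = FALSE)
    if (is.null(synthetic$config)) synthetic$config <- cohortConfig()
    if (is.null(synthetic$truth)) synthetic$truth <- defaultTruth()
  }
  structure(list(inputPaths = inputPaths, synthetic = synthetic,
                 xScales = xScales, gammaOn = gammaOn, mcmc = mcmc,
                 thresholds = thresholds, outputDir = outputDir,
                 masterSeed = masterSeed, compareGroups = compareGroups),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file whose top-level keys
#'   match the arguments of [pipelineConfig()] (MCMC settings under an
#'   `mcmc` block).
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$mcmc)) args$mcmc <- do.call(mcmcConfig, raw$mcmc)
  if (!is.null(raw$thresholds)) args$thresholds <- unlist(raw$thresholds)
  if (isTRUE(raw$synthetic)) args$synthetic <- list()
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Generate or ingest a cohort, derive resting/maximal values and
#' reserves, fit the hierarchical model in all eight (x-scale, sex,
#' mode) cells, compute convergence diagnostics, and write the report
#' tables plus a JSON manifest. Deterministic for a fixed master seed.
#'
#' @param config A [pipelineConfig()].
#' @param quiet Suppress stage messages.
#' @return A list: `report`, `diagnostics` (per-cell), `fits`,
#'   `manifest`, `outputDir`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()["elapsed"]
  stage <- function(nm, expr) {
    s <- proc.time()["elapsed"]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-10s %6.1f s", nm, proc.time()["elapsed"] - s)
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(config$synthetic))
      generateCohort(config$synthetic$config,
                     truth = config$synthetic$truth,
                     masterSeed = config$masterSeed)
    else readCohort(config$inputPaths$subjects, config$inputPaths$series)
  })
  derived <- stage("derive", deriveCohort(cohort))

  fits <- list(); diags <- list(); cell <- 0L
  stage("fit", {
    for (sc in config$xScales) for (sx in c("male", "female"))
      for (md in c("treadmill", "cycle")) {
        cell <- cell + 1L
        dat <- scaleSeries(cohort, derived, xScale = sc, mode = md, sex = sx)
        mc <- config$mcmc
        mc$master_seed <- chainSeed(config$masterSeed, 1000L + cell)
        fit <- fitHierarchical(dat,
                               modelSpec(xScale = sc,
                                         gammaOn = config$gammaOn), mc)
        fits[[sc]][[sx]][[md]] <- fit
        dg <- diagnoseFit(fit, config$thresholds)
        dg$x_scale <- sc; dg$sex <- sx; dg$mode <- md
        diags[[cell]] <- dg
      }
    NULL
  })
  diagnostics <- do.call(rbind, diags)
  worst <- c(rhat = max(diagnostics$rhat), ess = min(diagnostics$ess),
             raftery = max(diagnostics$raftery_I))
  say("diagnostics worst case: Rhat %.4f, min ESS %.0f, max RL %.3f",
      worst["rhat"], worst["ess"], worst["raftery"])

  groupTable <- if (config$compareGroups)
    stage("groups", groupComparisonTable(derived, cohort$subjects,
                                         config = config$mcmc)) else NULL
  report <- stage("report", buildReport(fits, groupTable))

  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic)) writeCohort(cohort, config$outputDir)
  utils::write.csv(derived, file.path(config$outputDir, "derived.csv"),
                   row.names = FALSE)
  utils::write.csv(diagnostics, file.path(config$outputDir,
                                          "diagnostics.csv"),
                   row.names = FALSE)
  manifest <- writeReport(report, config$outputDir, manifest = list(
    master_seed = config$masterSeed,
    mcmc = unclass(config$mcmc), gamma_on = config$gammaOn,
    n_fits = cell, n_diagnostics_blocks = length(diags),
    worst_case = as.list(worst),
    elapsed_sec = unname(proc.time()["elapsed"] - t0)))
  say("pipeline done in %.1f s", proc.time()["elapsed"] - t0)
  list(report = report, diagnostics = diagnostics, fits = fits,
       manifest = manifest, outputDir = config$outputDir)
}
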