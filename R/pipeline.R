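# End-to-end study runner: phantom generation or manifest loading, feature
# extraction, LOOCV on the primary cohort, optional independent validation,
# and serialized reports.

#' Default run configuration
#'
#' Assembles the full configuration of [runFullStudy()]. Either phantom
#' settings or cohort manifests can drive each cohort; the validation
#' cohort is optional. The resolved configuration is written into the
#' output directory alongside every artifact so a run is reproducible from
#' (config, seeds).
#'
#' @param outDir output directory.
#' @param seed base seed for all stages.
#' @param primaryPhantom a [PhantomConfig-class] for the primary cohort,
#'   or NULL when `primaryManifest` is given.
#' @param validationPhantom optional [PhantomConfig-class].
#' @param primaryManifest,validationManifest optional manifest CSV paths.
#' @param extraction an [extractionConfig()] list.
#' @param alpha WMW screening level.
#' @param lambdas LASSO penalty grid.
#' @param selFolds,selRepeats penalty-tuning CV scheme.
#' @param tuneFolds,tuneRepeats model-tuning CV scheme.
#' @param reducedGrids use desk-scale model grids.
#' @return A named list (class `gliorad_run_config`).
#' @export
runConfig <- function(outDir, seed = 1L, primaryPhantom = NULL,
                      validationPhantom = NULL, primaryManifest = NULL,
                      validationManifest = NULL,
                      extraction = extractionConfig(), alpha = 0.001,
                      lambdas = lambdaGrid(), selFolds = 5L,
                      selRepeats = 5L, tuneFolds = 5L, tuneRepeats = 5L,
                      reducedGrids = FALSE) {
  if (is.null(primaryPhantom) && is.null(primaryManifest))
    gliostop("gliorad_config",
             "a primary cohort (phantom config or manifest) is required")
  structure(list(outDir = outDir, seed = as.integer(seed),
                 primaryPhantom = primaryPhantom,
                 validationPhantom = validationPhantom,
                 primaryManifest = primaryManifest,
                 validationManifest = validationManifest,
                 extraction = extraction, alpha = alpha, lambdas = lambdas,
                 selFolds = as.integer(selFolds),
                 selRepeats = as.integer(selRepeats),
                 tuneFolds = as.integer(tuneFolds),
                 tuneRepeats = as.integer(tuneRepeats),
                 reducedGrids = reducedGrids),
            class = "gliorad_run_config")
}

configAsYaml <- function(config) {
  ser <- lapply(config, function(x) {
    if (isS4(x)) {
      sl <- lapply(slotNames(x), function(s) slot(x, s))
      names(sl) <- slotNames(x)
      c(list(.class = class(x)[1]), sl)
    } else x
  })
  yaml::as.yaml(ser)
}

manifestHash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

cohortFor <- function(config, which) {
  phantom <- config[[paste0(which, "Phantom")]]
  manifest <- config[[paste0(which, "Manifest")]]
  if (!is.null(manifest)) {
    list(subjects = readCohort(manifest), manifest = manifest)
  } else if (!is.null(phantom)) {
    dir <- file.path(config$outDir, paste0(which, "_cohort"))
    subjects <- generateCohort(phantom)
    man <- writeCohort(subjects, dir, cohortTag = phantom@cohortTag)
    list(subjects = subjects, manifest = man)
  } else NULL
}

#' Run the full grading study
#'
#' Executes the configured stages end to end: cohort generation or
#' loading, preprocessing and feature extraction, LOOCV with per-fold
#' feature re-selection on the primary cohort, and (when a validation
#' cohort is configured) independent validation on the features selected
#' in all LOOCV folds. Feature tables, per-fold selections, metric tables,
#' the resolved configuration and manifest hashes are written to the
#' output directory.
#'
#' @param config a [runConfig()] list.
#' @return The output directory, invisibly; artifacts on disk include
#'   `report.json` with the per-model metrics.
#' @export
runFullStudy <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(configAsYaml(config), file.path(config$outDir, "config.yaml"))
  logfile <- file.path(config$outDir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
  }

  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED (%s)", name, conditionMessage(e))
      gliostop("gliorad_stage", "stage %s failed: %s", name,
               conditionMessage(e))
    })
  }

  primary <- stage("phantom/load-primary", cohortFor(config, "primary"))
  validation <- stage("phantom/load-validation",
                      cohortFor(config, "validation"))

  specs <- defaultModelSpecs(reduced = config$reducedGrids)

  ftPrimary <- stage("extract-primary", {
    ft <- buildFeatureTable(primary$subjects, config$extraction,
                            cohortTag = "primary")
    writeFeatureTable(ft, file.path(config$outDir, "features_primary.csv"))
    ft
  })

  loocvReport <- stage("crossval", {
    loocv(ftPrimary, specs, seed = config$seed, alpha = config$alpha,
          lambdas = config$lambdas, selFolds = config$selFolds,
          selRepeats = config$selRepeats, tuneFolds = config$tuneFolds,
          tuneRepeats = config$tuneRepeats)
  })

  valReport <- NULL
  if (!is.null(validation)) {
    ftVal <- stage("extract-validation", {
      ft <- buildFeatureTable(validation$subjects, config$extraction,
                              cohortTag = "validation")
      writeFeatureTable(ft,
                        file.path(config$outDir, "features_validation.csv"))
      ft
    })
    valReport <- stage("validate", {
      independentValidation(ftPrimary, ftVal, loocvReport, specs,
                            seed = config$seed,
                            tuneFolds = config$tuneFolds,
                            tuneRepeats = config$tuneRepeats)
    })
  }

  report <- list(
    provenance = list(
      primary_manifest_md5 = manifestHash(primary$manifest),
      validation_manifest_md5 =
        if (is.null(validation)) NULL else manifestHash(validation$manifest),
      seed = config$seed),
    loocv = list(metrics = loocvReport@metrics,
                 summary = summarizeReport(loocvReport),
                 failed_folds = loocvReport@failedFolds,
                 n_selected_per_fold =
                   vapply(loocvReport@foldSelections, length, integer(1))),
    validation = if (is.null(valReport)) "skipped" else
      list(metrics = valReport@metrics,
           summary = summarizeReport(valReport),
           intersection = valReport@foldSelections$intersection))
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write.csv(loocvReport@metrics,
            file.path(config$outDir, "metrics_loocv.csv"), row.names = FALSE)
  if (!is.null(valReport))
    write.csv(valReport@metrics,
              file.path(config$outDir, "metrics_validation.csv"),
              row.names = FALSE)
  logmsg("done")
  invisible(config$outDir)
}
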