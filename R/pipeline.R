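fixationSchema <- c(subjectId = "integer", sceneId = "integer",
                    task = "character", trialIndex = "integer",
                    fixationIndex = "integer", x = "numeric", y = "numeric",
                    durationMs = "numeric", onsetMs = "numeric",
                    blink = "logical")

#' Read a fixation report
#'
#' Reads a CSV fixation table with the documented schema (subjectId,
#' sceneId, task, trialIndex, fixationIndex, x, y, durationMs, onsetMs,
#' blink, optional responseTimeMs). Rows with non-finite coordinates,
#' non-positive durations or negative onsets are dropped and collected into
#' an error report attached as attribute \code{"rowErrors"}.
#'
#' @param path CSV file path.
#' @return typed data.frame of fixation records.
#' @export
readFixationTable <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(fixationSchema), names(raw))
  if (length(missing))
    stop("fixation table is missing required column(s): ",
         paste(missing, collapse = ", "))
  suppressWarnings({
    for (col in names(fixationSchema))
      raw[[col]] <- switch(fixationSchema[[col]],
                           integer = as.integer(raw[[col]]),
                           numeric = as.numeric(raw[[col]]),
                           logical = as.logical(raw[[col]]),
                           as.character(raw[[col]]))
    if (!"responseTimeMs" %in% names(raw))
      raw$responseTimeMs <- NA_real_
    else raw$responseTimeMs <- as.numeric(raw$responseTimeMs)
  })
  bad <- !is.finite(raw$x) | !is.finite(raw$y) |
    is.na(raw$durationMs) | raw$durationMs <= 0 |
    is.na(raw$onsetMs) | raw$onsetMs < 0 | is.na(raw$fixationIndex)
  errors <- data.frame(row = which(bad))
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rowErrors") <- errors
  out
}

#' @rdname readFixationTable
#' @param fixations fixation table to write.
#' @export
writeFixationTable <- function(fixations, path) {
  write.csv(fixations, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All knobs of an end-to-end run in one serialisable list: paths, the
#' degrees-to-pixels calibration, patch radius, the filter thresholds, the
#' feature-map parameters, quantile-bin count and seeds. Round-trips through
#' YAML and JSON without loss.
#'
#' @param outputDir directory for all artifacts.
#' @param fixationsPath optional existing fixation CSV; when NULL the
#'   simulate stage generates one.
#' @param nSubjects,nScenes simulated design size (divisible by 9 and 3).
#' @param sceneSize scene shape c(H, W) in px.
#' @param radiusDeg patch radius in degrees.
#' @param minSaccadeDeg triplet saccade-amplitude exclusion threshold (deg).
#' @param minDurationMs,maxDurationMs fixation-duration filter (ms).
#' @param nBins quantile bins for the descriptive summaries.
#' @param seed integer seed for all randomness.
#' @param feature a \code{\link{featureConfig}} (stored as a plain list).
#' @return list of class \code{fixdurPipelineConfig}.
#' @export
pipelineConfig <- function(outputDir, fixationsPath = NULL, nSubjects = 9L,
                           nScenes = 9L, sceneSize = c(120L, 160L),
                           radiusDeg = 1, minSaccadeDeg = 2,
                           minDurationMs = 50, maxDurationMs = 1000,
                           nBins = 10L, seed = 1L,
                           feature = featureConfig()) {
  stopifnot(radiusDeg > 0, minSaccadeDeg > 0, minDurationMs > 0,
            maxDurationMs > minDurationMs, nBins >= 2)
  structure(list(outputDir = outputDir, fixationsPath = fixationsPath,
                 nSubjects = as.integer(nSubjects),
                 nScenes = as.integer(nScenes),
                 sceneSize = as.integer(sceneSize),
                 radiusDeg = radiusDeg, minSaccadeDeg = minSaccadeDeg,
                 minDurationMs = minDurationMs,
                 maxDurationMs = maxDurationMs, nBins = as.integer(nBins),
                 seed = as.integer(seed), feature = unclass(feature)),
            class = "fixdurPipelineConfig")
}

#' @rdname pipelineConfig
#' @param path file to write to / read from; format by extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @param config a \code{fixdurPipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  obj <- unclass(config)
  obj$feature$clutterWeights <- as.list(obj$feature$clutterWeights)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipelineConfig, c(
    obj[setdiff(names(obj), "feature")],
    list(feature = do.call(featureConfig, as.list(obj$feature)))))
  cfg
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

pipelineStages <- c("simulate", "features", "patches", "triplets", "fit",
                    "report")

stageOutputs <- function(config) {
  out <- config$outputDir
  list(simulate = file.path(out, c("fixations.csv", "design.json",
                                   "ground_truth.json")),
       features = file.path(out, "feature_maps.rds"),
       patches = file.path(out, "patch_features.csv"),
       triplets = file.path(out, c("triplets.csv", "control.csv",
                                   "exclusion_audit.json")),
       fit = file.path(out, c("fixed_effects.csv", "model_fit.json")),
       report = file.path(out, c("binned_summary.csv",
                                 "partial_effects.csv")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (skipped when \code{fixationsPath} points at
#' existing data), features, patches, triplets, fit and report, writing
#' every intermediate artifact plus an exclusion audit and a run manifest
#' (config hash, seed, package version, completed stages) to
#' \code{outputDir}. Stages are resumable: a stage whose outputs exist under
#' an unchanged configuration is skipped, and deleting an intermediate file
#' recomputes only that stage and everything downstream.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print per-stage progress.
#' @return invisibly, a list of artifact paths by stage.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "fixdurPipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(config$outputDir, "manifest.json")
  hash <- configHash(config)
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  sameConfig <- !is.null(manifest) && identical(manifest$configHash, hash)
  outputs <- stageOutputs(config)
  ppd <- config$sceneSize[2] / 25.78
  radiusPx <- pxRadiusForDegrees(config$radiusDeg, ppd)
  mustRun <- FALSE
  ranStages <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))

  needs <- function(stage) {
    mustRun || !sameConfig || !all(file.exists(outputs[[stage]]))
  }

  ## simulate ---------------------------------------------------------------
  externalFix <- !is.null(config$fixationsPath)
  if (!externalFix && needs("simulate")) {
    say("stage simulate")
    design <- makeDesign(config$seed, config$nSubjects, config$nScenes)
    sp <- scanpathParams()
    fixrows <- list()
    withSeed(config$seed, {
      subjShift <- rnorm(config$nSubjects, 0, 0.13)
      itemShift <- rnorm(config$nScenes, 0, 0.09)
      tasks <- c("memorization", "preference", "search")
      for (i in seq_len(nrow(design$subjects))) {
        subj <- design$subjects[i, ]
        order <- strsplit(subj$taskOrder, "-")[[1]]
        trial <- 0L
        for (tk in order) {
          lst <- subj[[paste0("list_", tk)]]
          sceneIds <- design$scenes$sceneId[design$scenes$sceneList == lst]
          sceneIds <- sample(sceneIds)
          for (sc in sceneIds) {
            trial <- trial + 1L
            spTk <- sp
            spTk$meanLogDuration <- sp$meanLogDuration +
              subjShift[subj$subjectId] + itemShift[sc]
            scene <- makeScene(config$seed * 1000L + sc,
                               size = config$sceneSize, pxPerDeg = ppd,
                               sceneId = sc)
            path <- simulateScanpath(scene, spTk,
                                     seed = config$seed * 100000L +
                                       subj$subjectId * 1000L + sc)
            path$subjectId <- subj$subjectId
            path$sceneId <- sc
            path$task <- tk
            path$trialIndex <- trial
            path$sceneList <- lst
            path$subjectGroup <- subj$subjectGroup
            path$responseTimeMs <- if (tk == "search")
              min(sp$trialDurationMs, rlnorm(1, log(3770), 0.4)) else NA_real_
            fixrows[[length(fixrows) + 1L]] <- path
          }
        }
      }
    })
    fixations <- do.call(rbind, fixrows)
    writeFixationTable(fixations, outputs$simulate[1])
    jsonlite::write_json(design, outputs$simulate[2], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    jsonlite::write_json(
      list(subjectInterceptSd = 0.13, itemInterceptSd = 0.09,
           scanpath = unclass(sp), seed = config$seed),
      outputs$simulate[3], auto_unbox = TRUE, digits = NA)
    ranStages <- c(ranStages, "simulate")
    mustRun <- TRUE
  }
  fixPath <- if (externalFix) config$fixationsPath else outputs$simulate[1]

  ## features ---------------------------------------------------------------
  if (needs("features")) {
    say("stage features")
    fixations <- readFixationTable(fixPath)
    mapsBySceneId <- list()
    for (sc in sort(unique(fixations$sceneId))) {
      scene <- makeScene(config$seed * 1000L + sc, size = config$sceneSize,
                         pxPerDeg = ppd, sceneId = sc)
      maps <- computeFeatureMaps(
        scene, do.call(featureConfig, as.list(config$feature)))
      mapsBySceneId[[as.character(sc)]] <- maps
      png::writePNG(luminance(maps),
                    file.path(config$outputDir,
                              sprintf("preview_luminance_%s.png", sc)))
    }
    saveRDS(mapsBySceneId, outputs$features)
    ranStages <- c(ranStages, "features")
    mustRun <- TRUE
  }

  ## patches ----------------------------------------------------------------
  if (needs("patches")) {
    say("stage patches")
    fixations <- readFixationTable(fixPath)
    mapsBySceneId <- readRDS(outputs$features)
    parts <- lapply(split(fixations, fixations$sceneId), function(fx) {
      patchFeatures(mapsBySceneId[[as.character(fx$sceneId[1])]], fx,
                    radiusPx)
    })
    pf <- do.call(rbind, parts)
    rownames(pf) <- NULL
    write.csv(pf, outputs$patches, row.names = FALSE)
    ranStages <- c(ranStages, "patches")
    mustRun <- TRUE
  }

  ## triplets ---------------------------------------------------------------
  if (needs("triplets")) {
    say("stage triplets")
    pf <- read.csv(outputs$patches, stringsAsFactors = FALSE)
    trip <- buildTriplets(pf, ppd, config$sceneSize, radiusPx,
                          config$minSaccadeDeg, config$minDurationMs,
                          config$maxDurationMs)
    ctrl <- buildControlTable(pf, ppd, config$sceneSize,
                              config$minDurationMs, config$maxDurationMs)
    write.csv(trip, outputs$triplets[1], row.names = FALSE)
    write.csv(ctrl, outputs$triplets[2], row.names = FALSE)
    jsonlite::write_json(
      list(triplets = as.list(attr(trip, "audit")),
           control = as.list(attr(ctrl, "audit")),
           nTriplets = nrow(trip), nControl = nrow(ctrl)),
      outputs$triplets[3], auto_unbox = TRUE)
    ranStages <- c(ranStages, "triplets")
    mustRun <- TRUE
  }

  ## fit --------------------------------------------------------------------
  if (needs("fit")) {
    say("stage fit")
    trip <- read.csv(outputs$triplets[1], stringsAsFactors = FALSE)
    data <- prepareModelData(trip)
    spec <- recoveryModelSpec()
    coefs <- NULL
    fitInfo <- list()
    for (tk in unique(data$task)) {
      d <- droplevels(data[data$task == tk, , drop = FALSE])
      fit <- fitDurationLMM(d, spec, REML = TRUE)
      tt <- fixedEffectTests(fit)
      tt$task <- tk
      coefs <- rbind(coefs, tt)
      r2 <- r2LMM(fit)
      fitInfo[[tk]] <- list(criterion = fitCriterion(fit),
                            nObs = nObs(fit),
                            varComp = varComp(fit),
                            r2Marginal = r2$marginal,
                            r2Conditional = r2$conditional)
    }
    write.csv(coefs, outputs$fit[1], row.names = FALSE)
    jsonlite::write_json(fitInfo, outputs$fit[2], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    ranStages <- c(ranStages, "fit")
    mustRun <- TRUE
  }

  ## report -----------------------------------------------------------------
  if (needs("report")) {
    say("stage report")
    trip <- read.csv(outputs$triplets[1], stringsAsFactors = FALSE)
    summaries <- NULL
    for (pred in c("luminanceN", "contrastN", "clutterN")) {
      if (!pred %in% names(trip)) next
      bs <- binnedSummary(trip, pred, "durationMs",
                          min(config$nBins,
                              length(unique(trip[[pred]])) - 1L))
      bs$predictor <- pred
      summaries <- rbind(summaries, bs)
    }
    write.csv(summaries, outputs$report[1], row.names = FALSE)
    data <- prepareModelData(trip)
    tk <- unique(data$task)[1]
    fit <- fitDurationLMM(droplevels(data[data$task == tk, , drop = FALSE]),
                          recoveryModelSpec(), REML = TRUE)
    pe <- partialEffects(fit, "contrastN")
    write.csv(pe, outputs$report[2], row.names = FALSE)
    ranStages <- c(ranStages, "report")
  }

  jsonlite::write_json(
    list(configHash = hash, seed = config$seed,
         package = as.character(utils::packageVersion("fixdur")),
         stages = pipelineStages, lastRun = ranStages,
         timestamp = format(Sys.time(), tz = "UTC")),
    manifestPath, auto_unbox = TRUE)
  invisible(c(outputs, manifest = manifestPath))
}
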