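#' Generative parameters for the duration model
#'
#' The ground truth used by the simulator and recovered in validation
#' experiments: the fixed-effect vector on the log-ms scale, the
#' zero-correlation random-effect standard deviations per grouping factor,
#' and the residual SD. The default fixed effects are the memorization-task
#' estimates that also serve as this package's reference effect sizes
#' (intercept 5.534 log-ms, i.e. around 253 ms; strongest covariate effects
#' for the saccade-direction change and viewing time; feature effects around
#' 0.01-0.02 SD units). Default variance components are chosen to give a
#' conditional-minus-marginal R2 gap of roughly 10-15 percentage points.
#'
#' @param b named fixed-effect vector over the 23 model terms.
#' @param random named list per grouping factor of named random-effect SDs.
#' @param residualSd residual SD of log duration.
#' @return list of class \code{fixdurGenerativeParams}.
#' @export
generativeParams <- function(
    b = c("(Intercept)" = 5.534,
          luminanceN = -0.014, luminancePrev = 0.004, luminanceNext = -0.006,
          contrastN = -0.017, contrastPrev = -0.001, contrastNext = 0.007,
          edgeDensityN = 0.021, edgeDensityPrev = 0.004,
          edgeDensityNext = -0.005,
          clutterN = 0.021, clutterPrev = -0.009, clutterNext = -0.008,
          nSegmentsN = 0.023, nSegmentsPrev = 0.004, nSegmentsNext = -0.003,
          prevSaccade = 0.028, prevSaccadeSq = -0.011, nextSaccade = -0.025,
          deltaAngle = 0.065, viewingTime = 0.040, viewingTimeSq = -0.030,
          centralDistance = 0.004),
    random = list(subject = c("(Intercept)" = 0.13, deltaAngle = 0.02,
                              viewingTime = 0.02),
                  item = c("(Intercept)" = 0.09, clutterN = 0.01),
                  list = c("(Intercept)" = 0.02),
                  group = c("(Intercept)" = 0.02)),
    residualSd = 0.415) {
  stopifnot(residualSd > 0, all(unlist(random) >= 0))
  structure(list(b = b, random = random, residualSd = residualSd),
            class = "fixdurGenerativeParams")
}

#' Scanpath simulation parameters
#'
#' Controls the synthetic gaze behaviour: a gamma-distributed saccade
#' amplitude with a target median near the empirical 5.1 degrees, a
#' direction-persistence (saccadic momentum) parameter, a central-bias
#' strength, an independent per-fixation blink rate, and the 8-second trial
#' duration. Provisional fixation durations (used for the trial's timeline)
#' are log-normal around the generative intercept.
#'
#' @param saccadeMedianDeg target median saccade amplitude (degrees).
#' @param saccadeShape gamma shape of the amplitude distribution.
#' @param momentum direction persistence in [0, 1); 1 means the next saccade
#'   continues the previous direction exactly.
#' @param centralBias strength (>= 0) of the Gaussian centre prior; 0 means
#'   no central bias (positions stay approximately uniform).
#' @param blinkRate independent per-fixation blink probability.
#' @param trialDurationMs trial length in ms.
#' @param meanLogDuration,sdLogDuration log-normal parameters of the
#'   provisional fixation durations (ms).
#' @return list of class \code{fixdurScanpathParams}.
#' @export
scanpathParams <- function(saccadeMedianDeg = 5.1, saccadeShape = 2,
                           momentum = 0.5, centralBias = 0.3,
                           blinkRate = 0.02, trialDurationMs = 8000,
                           meanLogDuration = 5.534, sdLogDuration = 0.35) {
  stopifnot(saccadeMedianDeg > 0, momentum >= 0, momentum < 1,
            centralBias >= 0, blinkRate >= 0, blinkRate <= 1,
            trialDurationMs > 0)
  structure(list(saccadeMedianDeg = saccadeMedianDeg,
                 saccadeShape = saccadeShape, momentum = momentum,
                 centralBias = centralBias, blinkRate = blinkRate,
                 trialDurationMs = trialDurationMs,
                 meanLogDuration = meanLogDuration,
                 sdLogDuration = sdLogDuration),
            class = "fixdurScanpathParams")
}

#' Dual Latin-square design assignment
#'
#' Reconstructs the study design: 72 subjects in nine groups of eight,
#' crossing three scene-list rotations with the three task orders
#' (search-memorization-preference, preference-search-memorization,
#' memorization-preference-search); 135 scenes in three lists of 45. Every
#' subject sees every scene exactly once, 24 subjects share any list-by-task
#' combination and eight share list, task and task order.
#'
#' @param seed integer seed (the assignment itself is deterministic; the
#'   seed is recorded for downstream trial-order shuffling).
#' @param nSubjects,nScenes total subjects and scenes; must be divisible by
#'   9 and 3 respectively.
#' @return list with data.frames \code{subjects} (subjectId, subjectGroup,
#'   rotation, orderIndex, taskOrder, and the list assigned per task) and
#'   \code{scenes} (sceneId, sceneList), plus the seed.
#' @export
makeDesign <- function(seed = 1L, nSubjects = 72L, nScenes = 135L) {
  stopifnot(nSubjects %% 9 == 0, nScenes %% 3 == 0)
  taskOrders <- list(c("search", "memorization", "preference"),
                     c("preference", "search", "memorization"),
                     c("memorization", "preference", "search"))
  tasks <- c("memorization", "preference", "search")
  groups <- expand.grid(rotation = 0:2, orderIndex = 1:3)
  subjects <- data.frame(
    subjectId = seq_len(nSubjects),
    subjectGroup = rep(seq_len(9), each = nSubjects / 9))
  subjects$rotation <- groups$rotation[subjects$subjectGroup]
  subjects$orderIndex <- groups$orderIndex[subjects$subjectGroup]
  subjects$taskOrder <- vapply(subjects$orderIndex, function(o)
    paste(taskOrders[[o]], collapse = "-"), character(1))
  for (t in seq_along(tasks))
    subjects[[paste0("list_", tasks[t])]] <-
      (subjects$rotation + t - 1) %% 3 + 1
  scenes <- data.frame(sceneId = seq_len(nScenes),
                       sceneList = rep(1:3, each = nScenes / 3))
  list(subjects = subjects, scenes = scenes, seed = as.integer(seed))
}

#' Synthesise a scene image
#'
#' Builds a stand-in for a photograph with controllable spatial variation in
#' all five features: a smooth luminance gradient background, solid-colour
#' rectangles (segments and edges), and band-limited noise patches (texture,
#' hence clutter and edge density). \code{"flat"} gives a constant image and
#' \code{"halves"} two solid half-fields split at the vertical midline.
#'
#' @param seed integer seed; the same seed yields the identical image.
#' @param size image shape c(H, W) in pixels (default 600 x 800, the study's
#'   display resolution).
#' @param textureSpec \code{"mixed"}, \code{"flat"} or \code{"halves"}.
#' @param pxPerDeg calibration; defaults to width / 25.78 (the display
#'   subtended 25.78 degrees horizontally).
#' @param sceneId identifier.
#' @return A \linkS4class{SceneImage}.
#' @export
makeScene <- function(seed, size = c(600L, 800L),
                      textureSpec = c("mixed", "flat", "halves"),
                      pxPerDeg = size[2] / 25.78,
                      sceneId = paste0("scene", seed)) {
  textureSpec <- match.arg(textureSpec)
  H <- size[1]; W <- size[2]
  withSeed(seed, {
    px <- array(0, c(H, W, 3))
    if (textureSpec == "flat") {
      px[] <- 128
    } else if (textureSpec == "halves") {
      left <- seq_len(floor(W / 2))
      px[, left, ] <- 60
      px[, setdiff(seq_len(W), left), ] <- 190
    } else {
      # smooth gradient background in a random direction, random base colour
      theta <- runif(1, 0, 2 * pi)
      g <- outer(seq_len(H) / H * sin(theta), rep(1, W)) +
        outer(rep(1, H), seq_len(W) / W * cos(theta))
      g <- (g - min(g)) / max(1e-9, diff(range(g)))
      base <- runif(3, 60, 200)
      for (k in 1:3) px[, , k] <- base[k] + 80 * (g - 0.5)
      # solid rectangles: well-separated segments with sharp edges
      for (r in seq_len(8)) {
        h <- sample(round(H / 10):round(H / 3), 1)
        w <- sample(round(W / 10):round(W / 3), 1)
        r0 <- sample(seq_len(H - h), 1); c0 <- sample(seq_len(W - w), 1)
        colr <- runif(3, 20, 235)
        for (k in 1:3) px[r0:(r0 + h - 1), c0:(c0 + w - 1), k] <- colr[k]
      }
      # band-limited noise patches: local texture, high clutter
      for (r in seq_len(4)) {
        h <- sample(round(H / 8):round(H / 3), 1)
        w <- sample(round(W / 8):round(W / 3), 1)
        r0 <- sample(seq_len(H - h), 1); c0 <- sample(seq_len(W - w), 1)
        for (k in 1:3) {
          noise <- matrix(rnorm(h * w, 0, 60), h, w)
          noise <- gaussBlur(noise, 0.8)
          px[r0:(r0 + h - 1), c0:(c0 + w - 1), k] <-
            px[r0:(r0 + h - 1), c0:(c0 + w - 1), k] + noise
        }
      }
      px <- pmin(pmax(px, 0), 255)
    }
    SceneImage(px, pxPerDeg, sceneId)
  })
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

reflectInto <- function(p, hi) {
  if (hi <= 0) return(rep(0, length(p)))
  period <- 2 * hi
  k <- p %% period
  k[k < 0] <- k[k < 0] + period
  ifelse(k <= hi, k, period - k)
}

#' Simulate a scanpath on a scene
#'
#' Sequential fixation locations from a reflected random walk with
#' gamma-distributed saccade amplitudes, wrapped-normal direction
#' persistence (saccadic momentum) and a Metropolis-style Gaussian central
#' bias. Onsets accumulate the provisional log-normal fixation durations
#' plus amplitude-dependent saccade durations until the trial ends; blinks
#' are independent per-fixation events.
#'
#' @param scene a \linkS4class{SceneImage}.
#' @param params a \code{\link{scanpathParams}}.
#' @param seed integer seed; identical seeds give identical paths.
#' @return data.frame with \code{fixationIndex}, \code{x}, \code{y} (0-based
#'   pixels), \code{durationMs}, \code{onsetMs}, \code{blink}.
#' @export
simulateScanpath <- function(scene, params = scanpathParams(), seed = 1L) {
  d <- dim(pixels(scene))
  H <- d[1]; W <- d[2]
  ppd <- pxPerDeg(scene)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  sigmaC2 <- (min(W, H) / 4)^2
  scale <- params$saccadeMedianDeg / qgamma(0.5, params$saccadeShape)
  dirSd <- max(0.05, pi * (1 - params$momentum))
  centerWeight <- function(x, y)
    exp(-params$centralBias * ((x - cx)^2 + (y - cy)^2) / (2 * sigmaC2))
  withSeed(seed, {
    x <- numeric(0); y <- numeric(0); dur <- numeric(0); onset <- numeric(0)
    # start from the positional prior itself: uniform without central bias,
    # centre-weighted otherwise (rejection sampling; the weight peaks at 1)
    repeat {
      curX <- runif(1, 0, W - 1); curY <- runif(1, 0, H - 1)
      if (runif(1) <= centerWeight(curX, curY)) break
    }
    prevDir <- runif(1, 0, 2 * pi)
    t <- 0
    while (t < params$trialDurationMs) {
      thisDur <- rlnorm(1, params$meanLogDuration, params$sdLogDuration)
      x <- c(x, curX); y <- c(y, curY); dur <- c(dur, thisDur)
      onset <- c(onset, t)
      ampDeg <- rgamma(1, params$saccadeShape) * scale
      dir <- rnorm(1, prevDir, dirSd)
      candX <- reflectInto(curX + ampDeg * ppd * cos(dir), W - 1)
      candY <- reflectInto(curY + ampDeg * ppd * sin(dir), H - 1)
      if (params$centralBias > 0) {
        ratio <- centerWeight(candX, candY) / centerWeight(curX, curY)
        tries <- 0
        while (runif(1) > ratio && tries < 10) {
          dir <- rnorm(1, prevDir, dirSd)
          ampDeg <- rgamma(1, params$saccadeShape) * scale
          candX <- reflectInto(curX + ampDeg * ppd * cos(dir), W - 1)
          candY <- reflectInto(curY + ampDeg * ppd * sin(dir), H - 1)
          ratio <- centerWeight(candX, candY) / centerWeight(curX, curY)
          tries <- tries + 1
        }
      }
      prevDir <- atan2(candY - curY, candX - curX)
      saccDurMs <- 30 + 2 * ampDeg
      t <- t + thisDur + saccDurMs
      curX <- candX; curY <- candY
    }
    data.frame(fixationIndex = seq_along(x), x = x, y = y,
               durationMs = dur, onsetMs = onset,
               blink = runif(length(x)) < params$blinkRate)
  })
}

#' Simulate log-normal durations from the generative LMM
#'
#' Draws the response of the duration model conditional on a realised design:
#' log d = X b + sum of random-effect contributions + Gaussian residual,
#' d = exp(log d). Random effects are independent normal draws per grouping
#' level and term, with SDs taken from the generative parameters (terms
#' absent from \code{params$random} contribute nothing).
#'
#' @param design a design list from \code{\link{buildDesign}} (fixed matrix
#'   \code{X} with named columns and grouping factors \code{groups}).
#' @param params a \code{\link{generativeParams}}.
#' @return list with \code{logDuration}, \code{durationMs} and the random
#'   draws \code{u}.
#' @export
simulateDurations <- function(design, params = generativeParams()) {
  X <- design$X
  missing <- setdiff(colnames(X), names(params$b))
  if (length(missing))
    stop("no generative coefficient for: ", paste(missing, collapse = ", "))
  b <- params$b[colnames(X)]
  eta <- as.numeric(X %*% b)
  u <- list()
  for (g in names(design$groups)) {
    fac <- design$groups[[g]]
    sds <- params$random[[g]]
    if (is.null(sds)) next
    for (tm in names(sds)) {
      if (sds[[tm]] == 0) next
      lev <- levels(fac)
      draws <- rnorm(length(lev), 0, sds[[tm]])
      names(draws) <- lev
      xcol <- if (tm == "(Intercept)") 1 else X[, tm]
      eta <- eta + draws[as.character(fac)] * xcol
      u[[paste(g, tm, sep = ":")]] <- draws
    }
  }
  logd <- eta + rnorm(nrow(X), 0, params$residualSd)
  list(logDuration = logd, durationMs = exp(logd), u = u)
}

#' Model specification used by the recovery experiments
#'
#' The full 23-term fixed structure with a compact zero-correlation random
#' structure matching the generative defaults: by-subject intercept plus
#' direction-change and viewing-time slopes, by-item intercept plus a
#' foveal-clutter slope.
#'
#' @return a \code{fixdurModelSpec}.
#' @export
recoveryModelSpec <- function() {
  modelSpec(fixed = c("(Intercept)", featureTerms(), oculomotorTerms()),
            random = list(subject = c("(Intercept)", "deltaAngle",
                                      "viewingTime"),
                          item = c("(Intercept)", "clutterN")))
}

#' Simulate a complete analysis-ready triplet dataset
#'
#' Generates scenes, feature maps and scanpaths for a subjects-by-scenes
#' crossed design (single task), runs the patch and triplet stages of the
#' pipeline, and returns the prepared (standardized) model data together
#' with the design matrices of a model specification. Durations are
#' generated conditionally on the realised covariates: the scanpath supplies
#' the geometry and timeline, and the response log durations are then drawn
#' from the generative model, which makes the true coefficients recoverable
#' by construction.
#'
#' @param nSubjects,nScenes crossed design size.
#' @param seed integer seed.
#' @param sceneSize scene shape c(H, W) in px; the default 150 x 200 keeps
#'   the full 25.78-degree field of view at a reduced pixel density.
#' @param params generative parameters.
#' @param spec model specification (defaults to
#'   \code{\link{recoveryModelSpec}}).
#' @param scanpath scanpath parameters.
#' @param task task label for the simulated trials.
#' @return list with \code{data} (prepared model data, response filled from
#'   the generative draw), \code{design}, \code{truth} (the generative
#'   draw), \code{params}, \code{spec}.
#' @export
simulateTripletData <- function(nSubjects = 24, nScenes = 45, seed = 1L,
                                sceneSize = c(150L, 200L),
                                params = generativeParams(),
                                spec = recoveryModelSpec(),
                                scanpath = scanpathParams(),
                                task = "memorization") {
  ppd <- sceneSize[2] / 25.78
  radiusPx <- pxRadiusForDegrees(1, ppd)
  rows <- vector("list", nScenes)
  withSeed(seed, {
    sceneSeeds <- sample.int(1e6, nScenes)
    pathSeeds <- matrix(sample.int(1e7, nSubjects * nScenes),
                        nSubjects, nScenes)
    for (s in seq_len(nScenes)) {
      scene <- makeScene(sceneSeeds[s], size = sceneSize, pxPerDeg = ppd,
                         sceneId = s)
      maps <- computeFeatureMaps(scene)
      fixs <- vector("list", nSubjects)
      for (sub in seq_len(nSubjects)) {
        path <- simulateScanpath(scene, scanpath, pathSeeds[sub, s])
        path$subjectId <- sub
        path$sceneId <- s
        path$task <- task
        path$trialIndex <- s
        fixs[[sub]] <- path
      }
      fx <- do.call(rbind, fixs)
      rows[[s]] <- list(pf = patchFeatures(maps, fx, radiusPx),
                        dim = dim(luminance(maps)))
    }
    pf <- do.call(rbind, lapply(rows, `[[`, "pf"))
    trip <- buildTriplets(pf, ppd, rows[[1]]$dim, radiusPx)
    data <- prepareModelData(trip)
    design <- buildDesign(data, spec)
    truth <- simulateDurations(design, params)
    data$logDuration <- truth$logDuration
    data$durationMs <- truth$durationMs
    list(data = data, design = design, truth = truth, params = params,
         spec = spec, tripletTable = trip)
  })
}

#' Parameter-recovery experiment
#'
#' Simulates the covariate structure once (full pipeline: scenes, feature
#' maps, scanpaths, patches, triplets, standardisation), then repeatedly
#' draws responses from the generative model and refits the LMM, recording
#' coefficient bias, 95 percent interval coverage of the truth, and the
#' significance rate. With \code{nullFeatures = TRUE} all 15 image-feature
#' coefficients are set to zero in the generator, so their significance
#' rate estimates the type-I error.
#'
#' @inheritParams simulateTripletData
#' @param nReps number of simulated replicates.
#' @param nullFeatures zero out the image-feature fixed effects in the
#'   generator.
#' @param sim optional precomputed covariate structure from
#'   \code{\link{simulateTripletData}}; the realised design is independent
#'   of the generative coefficients, so it can be shared between recovery
#'   runs with different truths.
#' @return list with per-term summary (\code{terms} data.frame: bTrue, mean
#'   estimate, bias, coverage, significance rate), the replicate-level
#'   estimates, and \code{nObs}.
#' @export
recoveryExperiment <- function(nSubjects = 24, nScenes = 45, nReps = 200,
                               seed = 1L, params = generativeParams(),
                               spec = recoveryModelSpec(),
                               sceneSize = c(150L, 200L),
                               nullFeatures = FALSE, sim = NULL) {
  if (nullFeatures) params$b[featureTerms()] <- 0
  if (is.null(sim))
    sim <- simulateTripletData(nSubjects, nScenes, seed = seed,
                               sceneSize = sceneSize, params = params,
                               spec = spec)
  baseFit <- fitDurationLMM(sim$data, spec, REML = TRUE)
  terms <- coefTable(baseFit)$term
  bTrue <- params$b[terms]
  est <- se <- matrix(NA_real_, nReps, length(terms),
                      dimnames = list(NULL, terms))
  withSeed(seed + 1L, {
    for (r in seq_len(nReps)) {
      resp <- simulateDurations(sim$design, params)$logDuration
      ft <- tryCatch(lme4::refit(baseFit@fit, newresp = resp),
                     error = function(e) NULL)
      if (is.null(ft)) next
      bb <- lme4::fixef(ft)
      est[r, names(bb)] <- bb
      se[r, names(bb)] <- sqrt(diag(as.matrix(vcov(ft))))
    }
  })
  ok <- complete.cases(est)
  est <- est[ok, , drop = FALSE]; se <- se[ok, , drop = FALSE]
  cover <- abs(sweep(est, 2, bTrue)) <= 1.96 * se
  sig <- abs(est / se) > 1.96
  summary <- data.frame(term = terms, bTrue = unname(bTrue),
                        meanEstimate = colMeans(est),
                        bias = colMeans(est) - unname(bTrue),
                        coverage = colMeans(cover),
                        signifRate = colMeans(sig))
  rownames(summary) <- NULL
  list(terms = summary, estimates = est, se = se,
       nObs = nrow(sim$data), nRepsUsed = sum(ok), fit = baseFit,
       simulation = sim)
}
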