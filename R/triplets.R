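#' Saccade amplitude in degrees of visual angle
#'
#' Euclidean pixel distance between two consecutive fixations divided by the
#' pixels-per-degree calibration.
#'
#' @param fixA,fixB lists or one-row data.frames with numeric \code{x},
#'   \code{y} (pixels) and, if available, \code{fixationIndex}; when both
#'   indices are present they must be consecutive.
#' @param pxPerDeg pixels per degree.
#' @return amplitude in degrees.
#' @examples
#' saccadeAmplitude(list(x = 0, y = 0), list(x = 93, y = 124), 31)  # 5
#' @export
saccadeAmplitude <- function(fixA, fixB, pxPerDeg) {
  stopifnot(pxPerDeg > 0)
  ia <- fixA$fixationIndex; ib <- fixB$fixationIndex
  if (!is.null(ia) && !is.null(ib) && abs(ib - ia) != 1)
    stop("fixations are not consecutive")
  sqrt((fixB$x - fixA$x)^2 + (fixB$y - fixA$y)^2) / pxPerDeg
}

# vectorised angle between saccade vectors, folded into [0, 180];
# zero-length vectors give NA
deltaAngleVec <- function(dx1, dy1, dx2, dy2) {
  n1 <- sqrt(dx1^2 + dy1^2); n2 <- sqrt(dx2^2 + dy2^2)
  cosang <- (dx1 * dx2 + dy1 * dy2) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[n1 == 0 | n2 == 0] <- NA_real_
  ang
}

#' Change in saccade direction
#'
#' Absolute angular difference between the incoming saccade (previous to
#' current fixation) and the outgoing saccade (current to next), folded into
#' [0, 180]. 0 degrees continues the previous trajectory (saccadic momentum);
#' 180 degrees is a complete reversal (return saccade).
#'
#' @param fixPrev,fixN,fixNext lists or rows with numeric \code{x}, \code{y}.
#' @return angle in degrees.
#' @export
deltaAngle <- function(fixPrev, fixN, fixNext) {
  ang <- deltaAngleVec(fixN$x - fixPrev$x, fixN$y - fixPrev$y,
                       fixNext$x - fixN$x, fixNext$y - fixN$y)
  if (anyNA(ang)) stop("zero-length saccade vector")
  ang
}

#' Distance of a fixation from the image centre
#'
#' @param fix list or row with numeric \code{x}, \code{y} (0-based pixels).
#' @param imageDim image shape c(H, W); the centre is
#'   ((W - 1) / 2, (H - 1) / 2).
#' @param pxPerDeg pixels per degree.
#' @return distance in degrees.
#' @export
centralDistance <- function(fix, imageDim, pxPerDeg) {
  stopifnot(length(imageDim) == 2, pxPerDeg > 0)
  cx <- (imageDim[2] - 1) / 2; cy <- (imageDim[1] - 1) / 2
  sqrt((fix$x - cx)^2 + (fix$y - cy)^2) / pxPerDeg
}

#' Viewing time at the end of a fixation
#'
#' Time elapsed between scene onset and the end of the fixation:
#' onset + duration, in milliseconds.
#'
#' @param onsetMs fixation onset relative to scene onset (ms).
#' @param durationMs fixation duration (ms).
#' @return viewing time in ms.
#' @export
viewingTime <- function(onsetMs, durationMs) onsetMs + durationMs

#' Validate fixations against the analysis filters
#'
#' Flags each fixation with the first reason it fails: \code{boundary}
#' (first or last fixation of its trial), \code{too_short} (< minDurationMs),
#' \code{too_long} (> maxDurationMs), \code{blink} (blink-adjacent), or
#' \code{after_response} (search task only: fixation starting at or after
#' the button press). Valid fixations get reason \code{ok}.
#'
#' @param fixations fixation table (see \code{\link{readFixationTable}} for
#'   the schema).
#' @param minDurationMs,maxDurationMs duration window in ms (defaults 50 and
#'   1000).
#' @return \code{fixations} with logical \code{valid} and character
#'   \code{reason} columns appended.
#' @export
validateFixations <- function(fixations, minDurationMs = 50,
                              maxDurationMs = 1000) {
  f <- fixations
  trialKey <- interaction(f$subjectId, f$sceneId, f$task, f$trialIndex,
                          drop = TRUE)
  firstIdx <- ave(f$fixationIndex, trialKey, FUN = min)
  lastIdx <- ave(f$fixationIndex, trialKey, FUN = max)
  boundary <- f$fixationIndex == firstIdx | f$fixationIndex == lastIdx
  tooShort <- f$durationMs < minDurationMs
  tooLong <- f$durationMs > maxDurationMs
  blink <- as.logical(f$blink %||% rep(FALSE, nrow(f)))
  blink[is.na(blink)] <- FALSE
  rt <- f$responseTimeMs %||% rep(NA_real_, nrow(f))
  afterResponse <- f$task == "search" & !is.na(rt) & f$onsetMs >= rt
  reason <- rep("ok", nrow(f))
  reason[afterResponse] <- "after_response"
  reason[blink] <- "blink"
  reason[tooLong] <- "too_long"
  reason[tooShort] <- "too_short"
  reason[boundary] <- "boundary"
  f$valid <- reason == "ok"
  f$reason <- reason
  f
}

featureCols <- c(luminance = "luminance", contrast = "contrast",
                 edgeDensityRaw = "edgeDensityRaw",
                 clutterValue = "clutterValue",
                 nSegmentsPatch = "nSegmentsPatch")
tripletFeatureNames <- c(luminance = "luminance", contrast = "contrast",
                         edgeDensityRaw = "edgeDensityRaw",
                         clutterValue = "clutter", nSegmentsPatch = "nSegments")

idCols <- function(f) {
  intersect(c("subjectId", "sceneId", "task", "trialIndex", "sceneList",
              "subjectGroup"), names(f))
}

#' Build the fixation-triplet analysis table
#'
#' Slides a (previous, current, next) window over each trial's fixation
#' sequence. A triplet is retained when all three fixations pass the validity
#' filters, both flanking saccades exceed \code{minSaccadeDeg}, and the three
#' 1-degree patches are pairwise disjoint (guaranteed by the amplitude rule
#' and asserted via the circle-overlap closed form). Windows overlap, so one
#' fixation can serve as previous, current and next in successive triplets;
#' an all-valid sequence of k fixations yields k - 2 triplets.
#'
#' @param patchTable fixation table with patch-feature columns appended by
#'   \code{\link{patchFeatures}}.
#' @param pxPerDeg pixels per degree.
#' @param imageDim image shape c(H, W).
#' @param radiusPx patch radius in pixels.
#' @param minSaccadeDeg minimum flanking saccade amplitude in degrees
#'   (default 2; exclusive).
#' @param minDurationMs,maxDurationMs duration filter bounds in ms.
#' @return data.frame with one row per triplet: identifiers, the response
#'   (\code{durationMs} of the current fixation and its natural log
#'   \code{logDuration}), the five features at the previous/current/next
#'   patches (suffixes \code{Prev}/\code{N}/\code{Next}), and the oculomotor
#'   and spatiotemporal covariates \code{prevSaccade}, \code{nextSaccade},
#'   \code{deltaAngle}, \code{viewingTime}, \code{centralDistance}.
#'   Attribute \code{"audit"} carries exclusion counts per reason.
#' @export
buildTriplets <- function(patchTable, pxPerDeg, imageDim, radiusPx,
                          minSaccadeDeg = 2, minDurationMs = 50,
                          maxDurationMs = 1000) {
  f <- validateFixations(patchTable, minDurationMs, maxDurationMs)
  ord <- order(f$subjectId, f$sceneId, f$task, f$trialIndex, f$fixationIndex)
  f <- f[ord, , drop = FALSE]
  trialKey <- interaction(f$subjectId, f$sceneId, f$task, f$trialIndex,
                          drop = TRUE)
  n <- nrow(f)
  prev <- seq_len(n) - 1L; nxt <- seq_len(n) + 1L
  okWindow <- seq_len(n) > 1 & seq_len(n) < n
  okWindow[okWindow] <- trialKey[prev[okWindow]] == trialKey[okWindow] &
    trialKey[nxt[okWindow]] == trialKey[okWindow] &
    f$fixationIndex[prev[okWindow]] == f$fixationIndex[okWindow] - 1L &
    f$fixationIndex[nxt[okWindow]] == f$fixationIndex[okWindow] + 1L
  ampPrev <- c(NA, sqrt(diff(f$x)^2 + diff(f$y)^2)) / pxPerDeg
  ampNext <- c(ampPrev[-1], NA)
  dAng <- rep(NA_real_, n)
  mid <- which(okWindow)
  dAng[mid] <- deltaAngleVec(f$x[mid] - f$x[mid - 1], f$y[mid] - f$y[mid - 1],
                             f$x[mid + 1] - f$x[mid], f$y[mid + 1] - f$y[mid])
  allValid <- okWindow
  allValid[mid] <- f$valid[mid] & f$valid[mid - 1] & f$valid[mid + 1]
  keepAmp <- okWindow & allValid & !is.na(ampPrev) & !is.na(ampNext) &
    ampPrev > minSaccadeDeg & ampNext > minSaccadeDeg & !is.na(dAng)
  # pairwise patch disjointness: centre distance of at least two radii.
  # The 2-degree amplitude rule implies this at the reference calibration
  # (1 degree = radius); the explicit filter also covers coarser pixel
  # grids where the rounded radius slightly exceeds one degree.
  disjoint <- keepAmp
  disjoint[keepAmp] <- ampPrev[keepAmp] * pxPerDeg >= 2 * radiusPx &
    ampNext[keepAmp] * pxPerDeg >= 2 * radiusPx
  keep <- which(keepAmp & disjoint)
  # audit: why windows were lost
  audit <- c(window = sum(!okWindow),
             invalid_fixation = sum(okWindow & !allValid),
             short_saccade = sum(okWindow & allValid & !keepAmp),
             patch_overlap = sum(keepAmp & !disjoint))
  # patch disjointness assertion (amplitude > 2 radii implies zero overlap)
  if (length(keep)) {
    ov <- vapply(keep, function(i) max(
      patchOverlapFraction(c(f$x[i - 1], f$y[i - 1]), c(f$x[i], f$y[i]),
                           radiusPx),
      patchOverlapFraction(c(f$x[i], f$y[i]), c(f$x[i + 1], f$y[i + 1]),
                           radiusPx)), numeric(1))
    stopifnot(all(ov == 0))
  }
  pickFeatures <- function(rows, suffix) {
    out <- f[rows, names(featureCols), drop = FALSE]
    names(out) <- paste0(tripletFeatureNames[names(featureCols)], suffix)
    out
  }
  cx <- (imageDim[2] - 1) / 2; cy <- (imageDim[1] - 1) / 2
  res <- cbind(
    f[keep, idCols(f), drop = FALSE],
    data.frame(fixationIndex = f$fixationIndex[keep],
               x = f$x[keep], y = f$y[keep],
               durationMs = f$durationMs[keep],
               logDuration = log(f$durationMs[keep])),
    pickFeatures(keep - 1L, "Prev"), pickFeatures(keep, "N"),
    pickFeatures(keep + 1L, "Next"),
    data.frame(prevSaccade = ampPrev[keep], nextSaccade = ampNext[keep],
               deltaAngle = dAng[keep],
               viewingTime = viewingTime(f$onsetMs[keep], f$durationMs[keep]),
               centralDistance = sqrt((f$x[keep] - cx)^2 +
                                      (f$y[keep] - cy)^2) / pxPerDeg))
  rownames(res) <- NULL
  attr(res, "audit") <- audit
  res
}

#' Build the control-analysis table
#'
#' The control analyses test immediacy effects only: one row per valid
#' fixation with its incoming and outgoing saccades of any amplitude (the
#' 2-degree rule is dropped), the five features at the current patch, and the
#' full set of oculomotor and spatiotemporal covariates. The duration,
#' blink, boundary and (for search) button-press filters are retained for
#' the focal fixation; flanking fixations only need to exist so that the
#' saccade covariates are defined.
#'
#' @inheritParams buildTriplets
#' @return data.frame, one row per retained fixation, with attribute
#'   \code{"audit"}.
#' @export
buildControlTable <- function(patchTable, pxPerDeg, imageDim,
                              minDurationMs = 50, maxDurationMs = 1000) {
  f <- validateFixations(patchTable, minDurationMs, maxDurationMs)
  ord <- order(f$subjectId, f$sceneId, f$task, f$trialIndex, f$fixationIndex)
  f <- f[ord, , drop = FALSE]
  trialKey <- interaction(f$subjectId, f$sceneId, f$task, f$trialIndex,
                          drop = TRUE)
  n <- nrow(f)
  okWindow <- seq_len(n) > 1 & seq_len(n) < n
  mid <- which(okWindow)
  okWindow[mid] <- trialKey[mid - 1] == trialKey[mid] &
    trialKey[mid + 1] == trialKey[mid] &
    f$fixationIndex[mid - 1] == f$fixationIndex[mid] - 1L &
    f$fixationIndex[mid + 1] == f$fixationIndex[mid] + 1L
  ampPrev <- c(NA, sqrt(diff(f$x)^2 + diff(f$y)^2)) / pxPerDeg
  ampNext <- c(ampPrev[-1], NA)
  dAng <- rep(NA_real_, n)
  mid <- which(okWindow)
  dAng[mid] <- deltaAngleVec(f$x[mid] - f$x[mid - 1], f$y[mid] - f$y[mid - 1],
                             f$x[mid + 1] - f$x[mid], f$y[mid + 1] - f$y[mid])
  keep <- which(okWindow & f$valid & !is.na(dAng))
  audit <- c(window = sum(!okWindow),
             invalid_fixation = sum(okWindow & !f$valid),
             degenerate_saccade = sum(okWindow & f$valid & is.na(dAng)))
  featN <- f[keep, names(featureCols), drop = FALSE]
  names(featN) <- paste0(tripletFeatureNames[names(featureCols)], "N")
  cx <- (imageDim[2] - 1) / 2; cy <- (imageDim[1] - 1) / 2
  res <- cbind(
    f[keep, idCols(f), drop = FALSE],
    data.frame(fixationIndex = f$fixationIndex[keep],
               x = f$x[keep], y = f$y[keep],
               durationMs = f$durationMs[keep],
               logDuration = log(f$durationMs[keep])),
    featN,
    data.frame(prevSaccade = ampPrev[keep], nextSaccade = ampNext[keep],
               deltaAngle = dAng[keep],
               viewingTime = viewingTime(f$onsetMs[keep], f$durationMs[keep]),
               centralDistance = sqrt((f$x[keep] - cx)^2 +
                                      (f$y[keep] - cy)^2) / pxPerDeg))
  rownames(res) <- NULL
  attr(res, "audit") <- audit
  res
}
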