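# Shared fixtures, all generated in code.

# fixation table for one trial from a matrix of (x, y) positions
trialFixations <- function(xy, durations = rep(250, nrow(xy)),
                           subjectId = 1L, sceneId = 1L,
                           task = "memorization", trialIndex = 1L,
                           blink = rep(FALSE, nrow(xy)),
                           responseTimeMs = NA_real_) {
  onsets <- cumsum(c(0, head(durations, -1) + 40))
  data.frame(subjectId = subjectId, sceneId = sceneId, task = task,
             trialIndex = trialIndex, fixationIndex = seq_len(nrow(xy)),
             x = xy[, 1], y = xy[, 2], durationMs = durations,
             onsetMs = onsets, blink = blink,
             responseTimeMs = responseTimeMs)
}

# positions along a line with constant spacing (px), well inside a 300x400
# image so patches never clip
lineTrial <- function(k, spacingPx = 40, ...) {
  xy <- cbind(20 + spacingPx * seq_len(k), rep(150, k))
  trialFixations(xy, ...)
}

# constant per-fixation feature columns so triplet feature picking is easy
# to verify
withPatchColumns <- function(fix) {
  n <- nrow(fix)
  fix$luminance <- seq_len(n) / n
  fix$contrast <- 0.1 + seq_len(n) / (2 * n)
  fix$edgeDensityRaw <- (seq_len(n) %% 4) / 10
  fix$clutterValue <- rev(seq_len(n)) / n
  fix$nSegmentsPatch <- 1L + (seq_len(n) %% 5)
  fix
}

# brute-force masked statistics used as oracles against the patch module
bruteMaskStats <- function(map, mask) {
  v <- c()
  for (i in seq_len(nrow(map)))
    for (j in seq_len(ncol(map)))
      if (mask[i, j]) v <- c(v, map[i, j])
  list(mean = mean(v), popSd = sqrt(mean((v - mean(v))^2)),
       distinct = length(unique(v)))
}

bruteCircleMask <- function(center, radiusPx, dimHW) {
  m <- matrix(FALSE, dimHW[1], dimHW[2])
  for (i in seq_len(dimHW[1]))
    for (j in seq_len(dimHW[2]))
      m[i, j] <- (j - 1 - center[1])^2 + (i - 1 - center[2])^2 <= radiusPx^2
  m
}

# small simulated triplet dataset + REML fit shared across test files
.simCache <- new.env(parent = emptyenv())
cachedSim <- function() {
  if (is.null(.simCache$sim)) {
    .simCache$sim <- simulateTripletData(nSubjects = 8, nScenes = 10,
                                         seed = 401,
                                         sceneSize = c(120L, 160L))
  }
  .simCache$sim
}
cachedFit <- function() {
  if (is.null(.simCache$fit)) {
    sim <- cachedSim()
    .simCache$fit <- suppressMessages(
      fitDurationLMM(sim$data, sim$spec, REML = TRUE))
  }
  .simCache$fit
}
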