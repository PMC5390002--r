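test_that("saccade amplitude converts pixel distances to degrees", {
  expect_equal(saccadeAmplitude(list(x = 5, y = 5), list(x = 5, y = 5), 31), 0)
  expect_equal(saccadeAmplitude(list(x = 0, y = 0), list(x = 31, y = 0), 31), 1)
  expect_equal(saccadeAmplitude(list(x = 0, y = 0), list(x = 93, y = 124), 31),
               5)  # 3-4-5 triangle scaled by 31 px
  expect_error(
    saccadeAmplitude(list(x = 0, y = 0, fixationIndex = 1),
                     list(x = 1, y = 1, fixationIndex = 3), 31),
    "consecutive")
})

test_that("direction change is folded into [0, 180] with the right anchors", {
  a <- list(x = 0, y = 0); b <- list(x = 10, y = 0)
  expect_equal(deltaAngle(a, b, list(x = 20, y = 0)), 0)    # continuation
  expect_equal(deltaAngle(a, b, list(x = 0, y = 0)), 180)   # return saccade
  expect_equal(deltaAngle(a, b, list(x = 10, y = 7)), 90)   # perpendicular
  expect_error(deltaAngle(a, a, b), "zero-length")
})

test_that("direction change is invariant under rotation and reflection", {
  set.seed(71)
  for (i in 1:20) {
    p <- matrix(rnorm(6, sd = 50), 3, 2)
    base <- deltaAngle(list(x = p[1, 1], y = p[1, 2]),
                       list(x = p[2, 1], y = p[2, 2]),
                       list(x = p[3, 1], y = p[3, 2]))
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    q <- p %*% R
    q[, 2] <- -q[, 2]  # reflect too
    rot <- deltaAngle(list(x = q[1, 1], y = q[1, 2]),
                      list(x = q[2, 1], y = q[2, 2]),
                      list(x = q[3, 1], y = q[3, 2]))
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("central distance and viewing time follow their definitions", {
  expect_equal(centralDistance(list(x = 399.5, y = 299.5), c(600, 800), 31), 0)
  expect_equal(centralDistance(list(x = 399.5 + 31, y = 299.5),
                               c(600, 800), 31), 1)
  set.seed(72)
  fx <- list(x = runif(1, 0, 799), y = runif(1, 0, 599))
  expect_equal(centralDistance(fx, c(600, 800), 31),
               sqrt((fx$x - 399.5)^2 + (fx$y - 299.5)^2) / 31)
  expect_equal(viewingTime(0, 250), 250)
  expect_equal(viewingTime(1000, 200), 1200)
})

test_that("fixation validity reasons cover every exclusion rule", {
  fix <- trialFixations(cbind(1:6 * 30, rep(100, 6)),
                        durations = c(250, 45, 1200, 250, 250, 250),
                        blink = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  v <- validateFixations(fix)
  expect_equal(v$reason,
               c("boundary", "too_short", "too_long", "blink", "ok",
                 "boundary"))
  # search: fixations from the button press onward are excluded
  sfix <- trialFixations(cbind(1:5 * 30, rep(100, 5)), task = "search",
                         responseTimeMs = 700)
  vs <- validateFixations(sfix)
  expect_equal(vs$reason[vs$onsetMs >= 700 & vs$fixationIndex < 5],
               rep("after_response",
                   sum(vs$onsetMs >= 700 & vs$fixationIndex < 5)))
})

test_that("an all-valid sequence of k fixations yields k - 2 triplets", {
  ppd <- 10
  for (k in 3:8) {
    # pad with first/last so k *valid* interior fixations exist
    pad <- withPatchColumns(lineTrial(k + 2, spacingPx = 40))
    trip <- buildTriplets(pad, ppd, c(300, 400), radiusPx = 10)
    expect_identical(nrow(trip), k - 2L)  # sliding-window oracle
  }
  # five successive valid fixations inside a longer trial -> three triplets
  pad7 <- withPatchColumns(lineTrial(7, spacingPx = 40))
  expect_identical(nrow(buildTriplets(pad7, ppd, c(300, 400), 10)), 3L)
  # a five-fixation trial is the minimum that yields any triplet
  expect_identical(nrow(buildTriplets(withPatchColumns(lineTrial(5, 40)),
                                      ppd, c(300, 400), 10)), 1L)
  expect_identical(nrow(buildTriplets(withPatchColumns(lineTrial(4, 40)),
                                      ppd, c(300, 400), 10)), 0L)
  expect_identical(nrow(buildTriplets(withPatchColumns(lineTrial(2, 40)),
                                      ppd, c(300, 400), 10)), 0L)
})

test_that("triplet rows carry the right features, covariates and response", {
  ppd <- 10
  fix <- withPatchColumns(lineTrial(5, spacingPx = 40))
  trip <- buildTriplets(fix, ppd, c(300, 400), 10)
  expect_identical(nrow(trip), 1L)
  expect_equal(trip$fixationIndex, 3L)
  expect_equal(trip$logDuration, log(trip$durationMs))
  expect_equal(trip$luminancePrev, fix$luminance[2])
  expect_equal(trip$luminanceN, fix$luminance[3])
  expect_equal(trip$luminanceNext, fix$luminance[4])
  expect_equal(trip$nSegmentsNext, fix$nSegmentsPatch[4])
  expect_equal(trip$prevSaccade, 4)  # 40 px at 10 px/deg
  expect_equal(trip$nextSaccade, 4)
  expect_equal(trip$deltaAngle, 0)   # collinear scanpath
  expect_equal(trip$viewingTime,
               fix$onsetMs[3] + fix$durationMs[3])
})

test_that("the 2-degree rule keeps triplet patches pairwise disjoint", {
  ppd <- 10
  xy <- cbind(c(20, 60, 75, 115, 155), rep(150, 5))  # one 1.5-deg saccade
  fix <- withPatchColumns(trialFixations(xy))
  trip <- buildTriplets(fix, ppd, c(300, 400), 10)
  expect_identical(nrow(trip), 0L)  # every window touches the short saccade
  ctrl <- buildControlTable(fix, ppd, c(300, 400))
  expect_identical(nrow(ctrl), 3L)  # short-saccade fixations stay in control
  # retained triplets always have non-overlapping masks
  full <- withPatchColumns(lineTrial(8, spacingPx = 25))
  tripFull <- buildTriplets(full, ppd, c(300, 400), 10)
  for (i in seq_len(nrow(tripFull))) {
    n <- tripFull$fixationIndex[i]
    centers <- lapply(c(n - 1, n, n + 1), function(k)
      c(full$x[k], full$y[k]))
    expect_equal(patchOverlapFraction(centers[[1]], centers[[2]], 10), 0)
    expect_equal(patchOverlapFraction(centers[[2]], centers[[3]], 10), 0)
  }
})

test_that("control rows are a superset window of triplet rows", {
  ppd <- 10
  fix <- withPatchColumns(lineTrial(5, spacingPx = 40))
  trip <- buildTriplets(fix, ppd, c(300, 400), 10)
  ctrl <- buildControlTable(fix, ppd, c(300, 400))
  expect_identical(nrow(ctrl), 3L)   # interior valid fixations
  expect_gte(nrow(ctrl), nrow(trip))
  expect_true(all(c("luminanceN", "prevSaccade", "deltaAngle",
                    "viewingTime") %in% names(ctrl)))
  expect_false("luminancePrev" %in% names(ctrl))
  aud <- attr(ctrl, "audit")
  expect_true(is.numeric(aud) && all(aud >= 0))
})

test_that("exclusion filtering is order-independent", {
  # a trial mixing every violation; surviving windows must be identical
  # regardless of how the rules are composed, so check against a manual
  # enumeration of the conjunction
  ppd <- 10
  xy <- cbind(seq(20, by = 35, length.out = 9), rep(150, 9))
  dur <- c(250, 250, 40, 250, 250, 1500, 250, 250, 250)
  blink <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  fix <- withPatchColumns(trialFixations(xy, durations = dur, blink = blink))
  trip <- buildTriplets(fix, ppd, c(300, 400), 10)
  v <- validateFixations(fix)$valid
  manual <- vapply(2:8, function(n) all(v[(n - 1):(n + 1)]), logical(1))
  expect_identical(sort(trip$fixationIndex), (2:8)[manual])
})
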