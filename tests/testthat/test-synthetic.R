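test_that("the dual Latin square balances lists, tasks and orders", {
  des <- makeDesign(1)
  s <- des$subjects
  expect_identical(nrow(s), 72L)
  expect_identical(as.integer(table(s$subjectGroup)), rep(8L, 9))
  expect_identical(nrow(des$scenes), 135L)
  expect_identical(as.integer(table(des$scenes$sceneList)), rep(45L, 3))
  tasks <- c("memorization", "preference", "search")
  # every subject sees each list exactly once across its three tasks
  listsPerSubject <- s[, paste0("list_", tasks)]
  expect_true(all(apply(listsPerSubject, 1, function(r)
    identical(sort(as.integer(r)), 1:3))))
  # 24 subjects share any list-by-task combination
  for (tk in tasks)
    expect_identical(as.integer(table(s[[paste0("list_", tk)]])),
                     rep(24L, 3))
  # 8 subjects share list, task and task order
  for (tk in tasks) {
    tab <- table(s[[paste0("list_", tk)]], s$taskOrder)
    expect_true(all(tab == 8L))
  }
  # every task order appears, as stated, and every order x rotation exists
  expect_identical(sort(unique(s$taskOrder)),
                   sort(c("search-memorization-preference",
                          "preference-search-memorization",
                          "memorization-preference-search")))
})

test_that("scene synthesis is deterministic and spans the feature space", {
  s1 <- makeScene(99, size = c(40L, 50L))
  s2 <- makeScene(99, size = c(40L, 50L))
  expect_identical(pixels(s1), pixels(s2))
  flat <- makeScene(1, size = c(30L, 30L), textureSpec = "flat")
  expect_equal(length(unique(as.vector(pixels(flat)))), 1L)
  halves <- makeScene(1, size = c(30L, 40L), textureSpec = "halves")
  expect_gt(mean(pixels(halves)[, 21:40, 1]), mean(pixels(halves)[, 1:20, 1]))
})

test_that("scanpaths respect momentum, central bias and determinism", {
  sc <- makeScene(3, size = c(150L, 200L), pxPerDeg = 200 / 25.78)
  p1 <- simulateScanpath(sc, scanpathParams(), seed = 5)
  p2 <- simulateScanpath(sc, scanpathParams(), seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$x >= 0 & p1$x <= 199 & p1$y >= 0 & p1$y <= 149))
  expect_true(all(diff(p1$onsetMs) > 0))
  # strong momentum concentrates direction changes near zero
  anglesFor <- function(params, seeds) {
    out <- c()
    for (sd in seeds) {
      p <- simulateScanpath(sc, params, seed = sd)
      if (nrow(p) < 3) next
      n <- 2:(nrow(p) - 1)
      out <- c(out, deltaAngleVec(p$x[n] - p$x[n - 1], p$y[n] - p$y[n - 1],
                                  p$x[n + 1] - p$x[n], p$y[n + 1] - p$y[n]))
    }
    out[!is.na(out)]
  }
  aMom <- anglesFor(scanpathParams(momentum = 0.95, centralBias = 0), 1:40)
  aFree <- anglesFor(scanpathParams(momentum = 0, centralBias = 0), 1:40)
  expect_lt(median(aMom), 45)
  expect_gt(median(aFree), median(aMom))
  # no central bias: fixation density roughly uniform over a coarse grid
  pos <- do.call(rbind, lapply(1:150, function(sd) {
    p <- simulateScanpath(sc, scanpathParams(momentum = 0, centralBias = 0),
                          seed = 1000 + sd)
    p[, c("x", "y")]
  }))
  gx <- cut(pos$x, breaks = seq(0, 200, length.out = 4))
  gy <- cut(pos$y, breaks = seq(0, 150, length.out = 4))
  prop <- as.vector(table(gx, gy)) / nrow(pos)
  expect_true(all(abs(prop - 1 / 9) < 0.35 / 9))
  # central bias pulls mass towards the middle cell
  posC <- do.call(rbind, lapply(1:80, function(sd) {
    p <- simulateScanpath(sc, scanpathParams(momentum = 0, centralBias = 2),
                          seed = 2000 + sd)
    p[, c("x", "y")]
  }))
  centreShare <- function(ps)
    mean(ps$x > 200 / 3 & ps$x < 400 / 3 & ps$y > 50 & ps$y < 100)
  expect_gt(centreShare(posC), centreShare(pos))
})

test_that("the generative duration model reproduces its moments", {
  # a zero design row with no noise returns exp(intercept), about 253 ms
  des0 <- list(X = matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")),
               groups = list())
  p0 <- generativeParams(residualSd = 1e-12, random = list())
  expect_equal(simulateDurations(des0, p0)$durationMs, exp(5.534),
               tolerance = 1e-6)
  # doubling the residual SD doubles the log-duration spread exactly
  # (same seed, same standard-normal draws)
  desN <- list(X = matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)")),
               groups = list())
  d1 <- withr::with_seed(31, simulateDurations(
    desN, generativeParams(residualSd = 0.2, random = list())))
  d2 <- withr::with_seed(31, simulateDurations(
    desN, generativeParams(residualSd = 0.4, random = list())))
  expect_equal(sd(d2$logDuration) / sd(d1$logDuration), 2, tolerance = 1e-9)
  # the Monte-Carlo mean of log d matches the linear predictor
  set.seed(32)
  X <- cbind("(Intercept)" = 1, luminanceN = rnorm(1e5))
  des <- list(X = X, groups = list())
  pp <- generativeParams(random = list())
  sim <- simulateDurations(des, pp)
  mu <- mean(X %*% pp$b[colnames(X)])
  expect_lt(abs(mean(sim$logDuration) - mu),
            3 * pp$residualSd / sqrt(1e5) + 3 * sd(X[, 2]) * 0.014 / sqrt(1e5))
  expect_error(simulateDurations(list(X = cbind(zz = 1), groups = list()),
                                 pp), "zz")
})

test_that("random-effect draws enter through the declared structure", {
  set.seed(33)
  n <- 600
  fac <- factor(rep(1:30, each = 20))
  X <- cbind("(Intercept)" = rep(1, n), deltaAngle = rnorm(n))
  des <- list(X = X, groups = list(subject = fac))
  pp <- generativeParams(residualSd = 1e-6,
                         random = list(subject = c("(Intercept)" = 0.5)))
  sim <- simulateDurations(des, pp)
  # within a subject, log d minus the fixed part is constant
  off <- sim$logDuration - as.numeric(X %*% pp$b[colnames(X)])
  expect_lt(max(tapply(off, fac, function(v) diff(range(v)))), 1e-4)
  expect_gt(sd(tapply(off, fac, mean)), 0.2)
})

test_that("the simulator exercises the full triplet pipeline", {
  sim <- cachedSim()
  expect_gt(nrow(sim$data), 200)           # filters pass at a healthy rate
  expect_identical(ncol(sim$design$X), 23L)
  expect_true(all(c("subjectId", "sceneId") %in% names(sim$data)))
  expect_true(all(sim$data$durationMs > 0))
  aud <- attr(sim$tripletTable, "audit")
  expect_true(all(aud >= 0))
  # determinism end to end at a tiny scale
  a <- simulateTripletData(3, 3, seed = 7, sceneSize = c(90L, 120L))
  b <- simulateTripletData(3, 3, seed = 7, sceneSize = c(90L, 120L))
  expect_equal(a$data, b$data)
  expect_identical(a$truth$logDuration, b$truth$logDuration)
})
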