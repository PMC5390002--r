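# small crossed dataset with named predictor columns for direct LMM tests
toyCrossed <- function(nSubj, nItem, sdSubj = 0, sdItem = 0, sdRes = 1,
                       b = c(1, 0.5, -0.25), seed = 1) {
  set.seed(seed)
  d <- expand.grid(subjectId = seq_len(nSubj), sceneId = seq_len(nItem))
  d <- d[rep(seq_len(nrow(d)), each = 3), ]
  n <- nrow(d)
  d$x1 <- rnorm(n); d$x2 <- rnorm(n)
  us <- rnorm(nSubj, 0, sdSubj); ui <- rnorm(nItem, 0, sdItem)
  d$logDuration <- b[1] + b[2] * d$x1 + b[3] * d$x2 +
    us[d$subjectId] + ui[d$sceneId] + rnorm(n, 0, sdRes)
  d$subjectId <- factor(d$subjectId); d$sceneId <- factor(d$sceneId)
  d
}

toySpec <- modelSpec(c("(Intercept)", "x1", "x2"),
                     random = list(subject = "(Intercept)",
                                   item = "(Intercept)"))

test_that("log response and standardisation behave as defined", {
  expect_equal(logDuration(1), 0)
  expect_equal(logDuration(exp(1)), 1)
  expect_equal(exp(logDuration(253.4)), 253.4)
  expect_error(logDuration(0), "positive")
  x <- c(4, 7, 9, 12, 30)
  z <- standardizeVariable(x, "demo")
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(as.numeric(z), (x - mean(x)) / sd(x), tolerance = 1e-12)
  z2 <- standardizeVariable(as.numeric(z), "demo")
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  expect_error(standardizeVariable(rep(3, 5), "flatPredictor"),
               "flatPredictor")
})

test_that("model specifications carry the documented term counts", {
  full <- fullModelSpec()
  expect_length(full$fixed, 23)
  expect_equal(sum(lengths(full$random)), 48)  # 23 + 23 + 1 + 1
  red <- reduceRandomStructure(full)
  expect_equal(sum(lengths(red$random)), 31)
  expect_equal(sum(lengths(full$random)) - sum(lengths(red$random)), 17)
  expect_identical(reduceRandomStructure(red), red)  # idempotent
  nf <- nonfeatureModelSpec()
  expect_length(nf$fixed, 8)  # intercept + 7 oculomotor/spatiotemporal
  # parameter accounting for the maximal and zero-correlation structures
  expect_equal(countRandomParams(23, "maximal"), 276)
  expect_equal(countRandomParams(23, "maximal") - 23, 253)  # correlations
  expect_equal(countRandomParams(1, "maximal"), 1)
  expect_equal(countRandomParams(23, "zero_correlation"), 23)
  # by-subject + by-item maximal blocks + two extra intercepts
  expect_equal(2 * countRandomParams(23, "maximal") + 2, 554)
})

test_that("design matrices follow the specification order and quadratics", {
  sim <- cachedSim()
  spec23 <- modelSpec(fullModelSpec()$fixed,
                      random = list(subject = "(Intercept)",
                                    item = "(Intercept)"))
  des <- buildDesign(sim$data, spec23)
  expect_identical(ncol(des$X), 23L)
  expect_identical(colnames(des$X)[1], "(Intercept)")
  expect_equal(des$X[, "prevSaccadeSq"], des$X[, "prevSaccade"]^2)
  expect_equal(des$X[, "viewingTimeSq"], des$X[, "viewingTime"]^2)
  # standardized inputs have mean 0 and SD 1 on the analysis sample
  expect_lt(max(abs(colMeans(des$X[, c("luminanceN", "deltaAngle",
                                       "viewingTime")]))), 1e-10)
  expect_equal(sd(des$X[, "contrastN"]), 1, tolerance = 1e-10)
  one <- modelSpec(c("(Intercept)", "contrastN"),
                   random = list(subject = "(Intercept)"))
  expect_identical(ncol(buildDesign(sim$data, one)$X), 2L)
  bad <- modelSpec(c("(Intercept)", "contrastN"))
  bad$fixed <- c("(Intercept)", "noSuchTerm")
  expect_error(buildDesign(sim$data, bad), "noSuchTerm")
})

test_that("the noiseless limit reproduces ordinary least squares", {
  d <- toyCrossed(6, 8, sdSubj = 0, sdItem = 0, sdRes = 1e-9, seed = 3)
  fit <- suppressMessages(fitDurationLMM(d, toySpec, REML = TRUE))
  ols <- lm(logDuration ~ x1 + x2, data = d)
  expect_lt(max(abs(coefTable(fit)$b - coef(ols))), 1e-6)
})

test_that("balanced one-way variance components match method of moments", {
  set.seed(9)
  g <- 15; m <- 8
  d <- data.frame(subjectId = factor(rep(seq_len(g), each = m)),
                  sceneId = factor(rep(1, g * m)))
  a <- rnorm(g, 0, 1.2)
  d$logDuration <- 5 + a[as.integer(d$subjectId)] + rnorm(g * m, 0, 0.6)
  spec <- modelSpec("(Intercept)", random = list(subject = "(Intercept)"))
  fit <- suppressMessages(fitDurationLMM(d, spec, REML = TRUE))
  # closed-form ANOVA estimators for the balanced design
  gm <- tapply(d$logDuration, d$subjectId, mean)
  msb <- m * var(gm)
  ssw <- sum((d$logDuration - gm[as.integer(d$subjectId)])^2)
  msw <- ssw / (g * (m - 1))
  vc <- varComp(fit)
  expect_equal(vc$var[vc$group == "subject"], (msb - msw) / m,
               tolerance = 1e-4)
  expect_equal(vc$var[vc$group == "Residual"], msw, tolerance = 1e-4)
})

test_that("REML and ML agree on fixed effects for a balanced design", {
  # balanced orthogonal toy: the same within-cell contrasts in every
  # subject-by-item cell, so the fixed effects are orthogonal to the
  # grouping structure and GLS weighting cannot move them
  set.seed(5)
  d <- expand.grid(rep = 1:3, subjectId = factor(1:6), sceneId = factor(1:6))
  d$x1 <- c(-1, 0, 1)[d$rep]
  d$x2 <- c(1, -2, 1)[d$rep]
  us <- rnorm(6, 0, 0.5); ui <- rnorm(6, 0, 0.3)
  d$logDuration <- 1 + 0.5 * d$x1 - 0.25 * d$x2 +
    us[d$subjectId] + ui[d$sceneId] + rnorm(nrow(d), 0, 0.4)
  f1 <- suppressMessages(fitDurationLMM(d, toySpec, REML = TRUE))
  f2 <- suppressMessages(fitDurationLMM(d, toySpec, REML = FALSE))
  expect_equal(coefTable(f1)$b, coefTable(f2)$b, tolerance = 1e-8)
  expect_true(all(varComp(f1)$var >= 0))
  expect_true(all(varComp(f2)$var >= 0))
})

test_that("significance labelling uses the normal-theory |t| criteria", {
  tt <- data.frame(term = c("a", "b", "c", "d"),
                   b = c(2, -1.7, 1, -3), se = rep(1, 4),
                   t = c(2, -1.7, 1, -3))
  fake <- new("DurationFit", coefTable = tt,
              varComp = data.frame(group = "Residual", term = "sd",
                                   sd = 1, var = 1),
              criterion = 0, REML = TRUE, nObs = 10L, spec = list(),
              fit = NULL, data = data.frame())
  lab <- fixedEffectTests(fake)$label
  expect_equal(lab, c("significant", "marginal", "nonsignificant",
                      "significant"))
})

test_that("marginal and conditional R2 behave across random structures", {
  # no random variance: marginal equals conditional
  d0 <- toyCrossed(8, 8, sdSubj = 0, sdItem = 0, sdRes = 0.5, seed = 7)
  f0 <- suppressMessages(fitDurationLMM(d0, toySpec))
  r0 <- r2LMM(f0)
  expect_equal(r0$marginal, r0$conditional, tolerance = 1e-3)
  # intercept-only fixed part: marginal 0
  dInt <- d0
  spec0 <- modelSpec("(Intercept)", random = list(subject = "(Intercept)",
                                                  item = "(Intercept)"))
  fInt <- suppressMessages(fitDurationLMM(dInt, spec0))
  expect_equal(r2LMM(fInt)$marginal, 0, tolerance = 1e-10)
  # random-intercept model matches the intercept-only closed form computed
  # by hand from the fit's own components
  d1 <- toyCrossed(10, 10, sdSubj = 0.8, sdItem = 0.4, sdRes = 0.5, seed = 8)
  f1 <- suppressMessages(fitDurationLMM(d1, toySpec))
  vc <- varComp(f1)
  sig2 <- vc$var[vc$group == "Residual"]
  ranVar <- sum(vc$var[vc$group != "Residual"])
  X <- cbind(1, d1$x1, d1$x2)
  eta <- X %*% coefTable(f1)$b
  vF <- mean((eta - mean(eta))^2)
  hand <- list(marginal = vF / (vF + ranVar + sig2),
               conditional = (vF + ranVar) / (vF + ranVar + sig2))
  got <- r2LMM(f1)
  expect_equal(got$marginal, hand$marginal, tolerance = 1e-10)
  expect_equal(got$conditional, hand$conditional, tolerance = 1e-10)
  expect_lte(got$marginal, got$conditional)
  expect_lte(got$conditional, 1)
})

test_that("nested model comparison counts parameters and calibrates", {
  d <- toyCrossed(8, 8, sdSubj = 0.4, sdItem = 0.3, sdRes = 0.5, seed = 13)
  full <- suppressMessages(fitDurationLMM(d, toySpec, REML = FALSE))
  redSpec <- modelSpec("(Intercept)",
                       random = list(subject = "(Intercept)",
                                     item = "(Intercept)"))
  red <- suppressMessages(fitDurationLMM(d, redSpec, REML = FALSE))
  cmp <- compareModels(full, red)
  expect_gte(cmp$chi2, 0)
  expect_identical(cmp$df, 2L)  # the two dropped fixed effects
  expect_lt(cmp$p, 0.001)      # x1, x2 truly matter here
  same <- compareModels(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$df, 0)
  expect_error(compareModels(suppressMessages(
    fitDurationLMM(d, toySpec, REML = TRUE)), red), "REML")
  # full-vs-nonfeature parameter difference: 15 fixed + 15 by-item slopes
  fullSpec <- reduceRandomStructure(fullModelSpec())
  nf <- nonfeatureModelSpec()
  dFix <- length(fullSpec$fixed) - length(nf$fixed)
  dRan <- sum(lengths(fullSpec$random)) - sum(lengths(nf$random))
  expect_identical(dFix + dRan, 30L)
})

test_that("the likelihood-ratio test holds its size under the null", {
  # null: no effect of x1/x2; LRT of (intercept vs +x1+x2) should reject
  # about 5 percent of the time and have mean chi2 close to df
  set.seed(17)
  nSim <- 120
  chi2 <- numeric(nSim)
  redSpec <- modelSpec("(Intercept)",
                       random = list(subject = "(Intercept)",
                                     item = "(Intercept)"))
  for (i in seq_len(nSim)) {
    d <- toyCrossed(6, 6, sdSubj = 0.3, sdItem = 0.3, sdRes = 0.5,
                    b = c(1, 0, 0), seed = 1000 + i)
    full <- suppressMessages(fitDurationLMM(d, toySpec, REML = FALSE))
    red <- suppressMessages(fitDurationLMM(d, redSpec, REML = FALSE))
    chi2[i] <- max(0, compareModels(full, red)$chi2)
  }
  rej <- mean(chi2 > qchisq(0.95, df = 2))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
  expect_lt(abs(mean(chi2) - 2), 0.75)
})

test_that("degenerate fitting inputs raise informative errors", {
  d <- toyCrossed(4, 4, seed = 19)
  tiny <- d[1:3, ]
  expect_error(fitDurationLMM(tiny, toySpec), "fewer observations")
  d1 <- d; d1$subjectId <- factor(1)
  expect_error(fitDurationLMM(d1, toySpec), "degenerate")
})
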