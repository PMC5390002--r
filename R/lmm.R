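# Model terms. The full fixed-effects structure has 23 terms: the intercept,
# the five local image features at the previous/current/next patch (15), and
# the oculomotor/spatiotemporal covariates with quadratic terms for the
# previous-saccade amplitude and viewing time (7).

featureTerms <- function() {
  as.vector(outer(c("luminance", "contrast", "edgeDensity", "clutter",
                    "nSegments"), c("N", "Prev", "Next"), paste0))
}

oculomotorTerms <- function() {
  c("prevSaccade", "prevSaccadeSq", "nextSaccade", "deltaAngle",
    "viewingTime", "viewingTimeSq", "centralDistance")
}

groupCols <- c(subject = "subjectId", item = "sceneId",
               list = "sceneList", group = "subjectGroup")

#' Natural log of a fixation duration
#'
#' Log-transforming durations (in ms) gives a near-normal response and
#' stabilises the variance.
#'
#' @param durationMs duration(s) in ms, strictly positive.
#' @return natural log of the duration.
#' @export
logDuration <- function(durationMs) {
  if (any(durationMs <= 0)) stop("durations must be positive")
  log(durationMs)
}

#' Standardise an input variable
#'
#' Centre by the sample mean and scale by the sample standard deviation, so
#' every predictor enters the model in standard-deviation units and the
#' slopes are comparable in magnitude within and between models.
#'
#' @param x numeric vector.
#' @param name predictor name used in the zero-variance error message.
#' @return z-scored vector with attributes \code{center} and \code{scale}
#'   retained for back-mapping.
#' @export
standardizeVariable <- function(x, name = deparse(substitute(x))) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("predictor '%s' has zero variance and cannot be standardized",
                 name))
  z <- (x - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

#' Model specification for a zero-correlation-parameter LMM
#'
#' Declares the ordered fixed effects and, per grouping factor, the list of
#' mutually independent random intercept/slope terms. Correlations between
#' random effects are fixed at zero (the zcpLMM assumption).
#'
#' @param fixed character vector of fixed-effect terms; must start with
#'   \code{"(Intercept)"}.
#' @param random named list over grouping factors (\code{subject},
#'   \code{item}, \code{list}, \code{group}) of term vectors; intercepts are
#'   written \code{"(Intercept)"}. Scene list and subject group carry
#'   intercepts only.
#' @return list of class \code{fixdurModelSpec}.
#' @export
modelSpec <- function(fixed, random = list()) {
  stopifnot(fixed[1] == "(Intercept)", !anyDuplicated(fixed))
  stopifnot(all(names(random) %in% names(groupCols)))
  for (g in names(random))
    if (!all(setdiff(random[[g]], "(Intercept)") %in% fixed))
      stop(sprintf("random slopes for '%s' must be fixed-effect terms", g))
  structure(list(fixed = fixed, random = random, correlationFree = TRUE),
            class = "fixdurModelSpec")
}

#' @rdname modelSpec
#' @details \code{fullModelSpec} returns the full zcpLMM: 23 fixed effects,
#'   by-subject and by-item random intercepts and all 22 slopes each, and
#'   intercepts for scene list and subject group (48 variance components).
#' @export
fullModelSpec <- function() {
  terms22 <- c(featureTerms(), oculomotorTerms())
  modelSpec(fixed = c("(Intercept)", terms22),
            random = list(subject = c("(Intercept)", terms22),
                          item = c("(Intercept)", terms22),
                          list = "(Intercept)",
                          group = "(Intercept)"))
}

#' Reduce the random-effects structure of the full zcpLMM
#'
#' Removes the 15 by-subject random slopes for the local image features and
#' restricts the previous-saccade random slopes to the linear term (the
#' by-subject and by-item quadratic slopes are dropped), taking the 48
#' variance components of the full zcpLMM down to 31. Applying the reduction
#' to an already-reduced specification is a no-op.
#'
#' @param spec a \code{fixdurModelSpec} with \code{subject} and \code{item}
#'   random structures.
#' @return the reduced \code{fixdurModelSpec}.
#' @export
reduceRandomStructure <- function(spec) {
  stopifnot(inherits(spec, "fixdurModelSpec"))
  if (!all(c("subject", "item") %in% names(spec$random)))
    stop("specification lacks by-subject or by-item random terms")
  spec$random$subject <- setdiff(spec$random$subject,
                                 c(featureTerms(), "prevSaccadeSq"))
  spec$random$item <- setdiff(spec$random$item, "prevSaccadeSq")
  spec
}

#' @rdname modelSpec
#' @details \code{nonfeatureModelSpec} drops the 15 image-feature fixed
#'   effects and their by-item random slopes from the reduced model;
#'   \code{fiveFeatureModelSpec} keeps only the image-feature terms.
#' @export
nonfeatureModelSpec <- function() {
  spec <- reduceRandomStructure(fullModelSpec())
  spec$fixed <- setdiff(spec$fixed, featureTerms())
  spec$random$subject <- setdiff(spec$random$subject, featureTerms())
  spec$random$item <- setdiff(spec$random$item, featureTerms())
  spec
}

#' @rdname modelSpec
#' @export
fiveFeatureModelSpec <- function() {
  spec <- reduceRandomStructure(fullModelSpec())
  spec$fixed <- c("(Intercept)", featureTerms())
  spec$random$subject <- "(Intercept)"
  spec$random$item <- intersect(spec$random$item,
                                c("(Intercept)", featureTerms()))
  spec
}

#' Count random-effect parameters per grouping factor
#'
#' For n variance components the maximal (fully correlated) structure has
#' n(n + 1)/2 parameters (n variances plus n(n - 1)/2 correlations); the
#' zero-correlation structure has n.
#'
#' @param nTerms number of random terms for the grouping factor.
#' @param structure \code{"maximal"} or \code{"zero_correlation"}.
#' @return parameter count.
#' @examples
#' countRandomParams(23, "maximal")  # 276 = 23 variances + 253 correlations
#' @export
countRandomParams <- function(nTerms,
                              structure = c("maximal", "zero_correlation")) {
  stopifnot(nTerms >= 1)
  structure <- match.arg(structure)
  if (structure == "maximal") nTerms * (nTerms + 1) / 2 else nTerms
}

#' Prepare the analysis table for model fitting
#'
#' Applies, separately per task (models are fit per task, so scaling is per
#' task): the logit transform of raw edge densities with the task's smallest
#' nonzero proportion as floor, z-standardisation of all 20 input variables,
#' and the quadratic terms for previous-saccade amplitude and viewing time
#' (squares of the centred-and-scaled variable, not re-standardised).
#'
#' @param table triplet or control table from \code{\link{buildTriplets}} /
#'   \code{\link{buildControlTable}}.
#' @param pFloor optional override for the edge-density regularisation floor.
#' @return data.frame with standardized predictor columns, grouping factors
#'   coerced to factor, and attribute \code{"scaling"} (per-task centres and
#'   scales).
#' @export
prepareModelData <- function(table, pFloor = NULL) {
  rawEdge <- grep("^edgeDensityRaw", names(table), value = TRUE)
  inputs <- intersect(c(featureTerms(), "prevSaccade", "nextSaccade",
                        "deltaAngle", "viewingTime", "centralDistance"),
                      c(names(table),
                        sub("edgeDensityRaw", "edgeDensity", rawEdge)))
  out <- NULL
  scaling <- list()
  for (tk in unique(table$task)) {
    d <- table[table$task == tk, , drop = FALSE]
    for (col in rawEdge) {
      nz <- d[[col]][d[[col]] > 0]
      floorTk <- pFloor %||% if (length(nz)) min(nz) else 0.5
      d[[sub("edgeDensityRaw", "edgeDensity", col)]] <-
        logitTransform(d[[col]], floorTk)
    }
    sc <- list()
    for (v in inputs) {
      z <- standardizeVariable(d[[v]], v)
      sc[[v]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
      d[[v]] <- as.numeric(z)
    }
    d$prevSaccadeSq <- d$prevSaccade^2
    d$viewingTimeSq <- d$viewingTime^2
    scaling[[as.character(tk)]] <- sc
    out <- rbind(out, d)
  }
  for (col in intersect(unname(groupCols), names(out)))
    out[[col]] <- factor(out[[col]])
  attr(out, "scaling") <- scaling
  out
}

#' Build the design for a model specification
#'
#' @param data prepared table from \code{\link{prepareModelData}}.
#' @param spec a \code{fixdurModelSpec}.
#' @return list with the response \code{y}, the fixed-effects matrix \code{X}
#'   (columns in specification order), and \code{groups}, the grouping
#'   factors used by the random structure.
#' @export
buildDesign <- function(data, spec) {
  stopifnot(inherits(spec, "fixdurModelSpec"))
  terms <- setdiff(spec$fixed, "(Intercept)")
  missing <- setdiff(terms, names(data))
  if (length(missing))
    stop("unknown predictor(s): ", paste(missing, collapse = ", "))
  X <- cbind("(Intercept)" = rep(1, nrow(data)),
             as.matrix(data[, terms, drop = FALSE]))
  groups <- lapply(groupCols[names(spec$random)], function(col) {
    if (!col %in% names(data))
      stop("grouping column '", col, "' not present in the data")
    factor(data[[col]])
  })
  list(y = data$logDuration, X = X, groups = groups)
}

lmerFormula <- function(spec) {
  terms <- setdiff(spec$fixed, "(Intercept)")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  for (g in names(spec$random)) {
    col <- groupCols[[g]]
    for (tm in spec$random[[g]]) {
      rhs <- paste0(rhs, " + ",
                    if (tm == "(Intercept)") sprintf("(1 | %s)", col)
                    else sprintf("(0 + %s | %s)", tm, col))
    }
  }
  as.formula(paste("logDuration ~", rhs))
}

#' Fit a zero-correlation-parameter linear mixed model
#'
#' Fits the Gaussian LMM declared by \code{spec} with mutually independent
#' random effects, using \code{lme4::lmer} (each random term enters as its
#' own \code{(0 + term | factor)} block, which imposes the zero-correlation
#' constraint). Variance components may be estimated as zero; singular fits
#' are therefore expected and not an error.
#'
#' @param data prepared table from \code{\link{prepareModelData}}.
#' @param spec a \code{fixdurModelSpec}.
#' @param REML fit by restricted maximum likelihood (default); use
#'   \code{FALSE} (maximum likelihood) for nested model comparison.
#' @param control an optional \code{lme4::lmerControl}.
#' @return A \linkS4class{DurationFit}.
#' @export
fitDurationLMM <- function(data, spec, REML = TRUE, control = NULL) {
  stopifnot(inherits(spec, "fixdurModelSpec"))
  if (nrow(data) <= length(spec$fixed))
    stop("fewer observations than fixed effects")
  for (g in names(spec$random)) {
    col <- groupCols[[g]]
    if (!col %in% names(data))
      stop("grouping column '", col, "' not present in the data")
    if (length(unique(data[[col]])) < 2)
      stop("grouping factor '", col, "' is degenerate (single level)")
  }
  control <- control %||%
    lme4::lmerControl(check.conv.singular = "ignore",
                      calc.derivs = FALSE)
  fit <- lme4::lmer(lmerFormula(spec), data = data, REML = REML,
                    control = control)
  as.DurationFit(fit, spec, data, REML)
}

as.DurationFit <- function(fit, spec, data, REML) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  coefTable <- data.frame(term = names(b), b = unname(b), se = unname(se),
                          t = unname(b / se), stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  colMap <- setNames(names(groupCols), groupCols)
  rows <- lapply(seq_along(vc), function(i) {
    grpCol <- sub("\\.\\d+$", "", names(vc)[i])
    term <- rownames(vc[[i]])[1]
    data.frame(group = colMap[[grpCol]] %||% grpCol, term = term,
               sd = attr(vc[[i]], "stddev")[[1]],
               var = vc[[i]][1, 1], stringsAsFactors = FALSE)
  })
  varComp <- do.call(rbind, rows)
  sigma <- attr(vc, "sc")
  varComp <- rbind(varComp,
                   data.frame(group = "Residual", term = "sd",
                              sd = sigma, var = sigma^2))
  rownames(varComp) <- NULL
  crit <- if (REML) lme4::REMLcrit(fit) else as.numeric(-2 * logLik(fit))
  new("DurationFit", coefTable = coefTable, varComp = varComp,
      criterion = crit, REML = REML, nObs = as.integer(stats::nobs(fit)),
      spec = unclass(spec), fit = fit, data = data)
}

#' Significance labels for fixed effects
#'
#' With many observations the t distribution is effectively normal, so a
#' two-tailed |t| > 1.96 criterion marks significance and 1.645 < |t| <= 1.96
#' marginal significance.
#'
#' @param fit a \linkS4class{DurationFit}.
#' @return the coefficient table with a \code{label} column
#'   (\code{"significant"}, \code{"marginal"}, \code{"nonsignificant"}).
#' @export
fixedEffectTests <- function(fit) {
  tt <- coefTable(fit)
  a <- abs(tt$t)
  tt$label <- ifelse(a > 1.96, "significant",
                     ifelse(a > 1.645, "marginal", "nonsignificant"))
  tt
}

# number of estimated parameters of a fit: fixed + variance components + sigma
countModelParams <- function(fit) {
  nrow(coefTable(fit)) + nrow(varComp(fit))  # varComp includes the residual
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained statistics for LMMs, with the random-slope extension:
#' the variance attributed to a grouping factor is the mean over observations
#' of the random-effect covariance projected through the design, which for a
#' zero-correlation model is the sum over terms of the term's variance times
#' the mean squared covariate. Marginal R2 uses the fixed effects only;
#' conditional R2 adds the random-effect variance.
#'
#' @param fit a \linkS4class{DurationFit}.
#' @return list with elements \code{marginal} and \code{conditional}, each in
#'   [0, 1] with marginal <= conditional.
#' @export
r2LMM <- function(fit) {
  spec <- structure(fit@spec, class = "fixdurModelSpec")
  des <- buildDesign(modelData(fit), spec)
  b <- coefTable(fit)$b
  varFixed <- mean((des$X %*% b - mean(des$X %*% b))^2)
  vc <- varComp(fit)
  resVar <- vc$var[vc$group == "Residual"]
  vcRan <- vc[vc$group != "Residual", , drop = FALSE]
  varRandom <- 0
  for (i in seq_len(nrow(vcRan))) {
    x <- if (vcRan$term[i] == "(Intercept)") 1
         else des$X[, vcRan$term[i]]
    varRandom <- varRandom + vcRan$var[i] * mean(x^2)
  }
  tot <- varFixed + varRandom + resVar
  list(marginal = varFixed / tot,
       conditional = (varFixed + varRandom) / tot)
}

#' Likelihood-ratio and BIC comparison of nested models
#'
#' Both fits must be maximum-likelihood fits on the same observations, with
#' the reduced model's fixed and random terms nested in the full model's.
#' The test statistic is the deviance difference on a chi-squared reference
#' with df equal to the parameter-count difference; BIC = deviance +
#' k log(n) decreases with goodness of fit.
#'
#' @param full,reduced \linkS4class{DurationFit} objects fitted with
#'   \code{REML = FALSE}.
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{bicFull},
#'   \code{bicReduced}.
#' @export
compareModels <- function(full, reduced) {
  if (full@REML || reduced@REML)
    stop("model comparison requires maximum-likelihood fits (REML = FALSE)")
  if (nObs(full) != nObs(reduced))
    stop("models were not fitted to the same observations")
  fullSpec <- full@spec; redSpec <- reduced@spec
  if (!all(redSpec$fixed %in% fullSpec$fixed))
    stop("models are not nested: reduced fixed effects not in full model")
  for (g in names(redSpec$random))
    if (!all(redSpec$random[[g]] %in% (fullSpec$random[[g]] %||% character())))
      stop("models are not nested: reduced random terms not in full model")
  kFull <- countModelParams(full); kRed <- countModelParams(reduced)
  chi2 <- fitCriterion(reduced) - fitCriterion(full)
  df <- kFull - kRed
  list(chi2 = chi2, df = df,
       p = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
       bicFull = fitCriterion(full) + kFull * log(nObs(full)),
       bicReduced = fitCriterion(reduced) + kRed * log(nObs(reduced)))
}
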