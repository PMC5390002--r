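#' Quantile binning of a continuous variable
#'
#' Assigns observations to \code{nBins} approximately equal-sized categories
#' by rank (ties broken by stable first-come order), the sort-and-slice
#' construction of quantile categories. The bin centre is the mean of its
#' members, so bin means are non-decreasing.
#'
#' @param values numeric vector.
#' @param nBins number of bins (default 10, deciles).
#' @return list with \code{assignment} (integer bin per observation, 1-based)
#'   and \code{binMeans}.
#' @export
quantileBins <- function(values, nBins = 10) {
  stopifnot(nBins >= 2)
  if (length(unique(values)) < nBins)
    stop("fewer distinct values than bins")
  n <- length(values)
  rk <- rank(values, ties.method = "first")
  edges <- round(seq(0, n, length.out = nBins + 1))
  assignment <- .bincode(rk, breaks = edges, right = TRUE,
                         include.lowest = TRUE)
  binMeans <- as.numeric(tapply(values, assignment, mean))
  list(assignment = assignment, binMeans = binMeans)
}

#' Within-subject standard errors (Cousineau normalisation)
#'
#' Removes between-subject offsets before computing condition-wise standard
#' errors: each observation is replaced by
#' \code{y - subjectMean + grandMean}, then the SE per bin is the standard
#' deviation of the normalised values across subjects divided by the square
#' root of the number of subjects contributing to the bin. Per-subject
#' additive shifts therefore leave every SE unchanged.
#'
#' @param data data.frame with columns named by \code{subject}, \code{bin},
#'   \code{y}.
#' @param subject,bin,y column names.
#' @return data.frame with one row per bin: \code{bin}, \code{mean},
#'   \code{se}, \code{n} (observations) and \code{nSubjects}.
#' @export
withinSubjectSE <- function(data, subject = "subjectId", bin = "bin",
                            y = "durationMs") {
  s <- factor(data[[subject]]); v <- data[[y]]
  b <- factor(data[[bin]], levels = sort(unique(data[[bin]])))
  if (nlevels(s) < 2)
    warning("single subject: within-subject SEs are zero")
  grand <- mean(v)
  norm <- v - ave(v, s) + grand
  # per-bin: first average within subject, then SD across subject means
  key <- interaction(s, b, drop = TRUE)
  subjMean <- as.numeric(tapply(norm, key, mean))
  binOf <- tapply(as.character(b), key, `[`, 1)
  bins <- levels(b)
  res <- data.frame(bin = bins,
                    mean = as.numeric(tapply(v, b, mean)),
                    se = NA_real_,
                    n = as.integer(table(b)),
                    nSubjects = NA_integer_)
  for (i in seq_along(bins)) {
    m <- subjMean[binOf == bins[i]]
    res$nSubjects[i] <- length(m)
    res$se[i] <- if (length(m) > 1) sd(m) / sqrt(length(m)) else 0
  }
  res
}

#' Quantile-binned means with within-subject standard errors
#'
#' The descriptive companion to the model: for each task, bins a predictor
#' into quantile categories and reports the mean response per bin with
#' Cousineau within-subject SEs.
#'
#' @param table analysis table (triplet or control).
#' @param predictor,response column names.
#' @param nBins number of quantile bins (default 10).
#' @return data.frame with columns \code{task}, \code{bin},
#'   \code{binCenter} (mean predictor value in the bin), \code{mean},
#'   \code{se}, \code{n}, \code{nSubjects}.
#' @export
binnedSummary <- function(table, predictor, response = "durationMs",
                          nBins = 10) {
  out <- NULL
  for (tk in unique(table$task)) {
    d <- table[table$task == tk, , drop = FALSE]
    qb <- quantileBins(d[[predictor]], nBins)
    d$bin <- qb$assignment
    ws <- withinSubjectSE(d, subject = "subjectId", bin = "bin", y = response)
    ws$binCenter <- qb$binMeans[as.integer(ws$bin)]
    ws$task <- tk
    out <- rbind(out, ws[, c("task", "bin", "binCenter", "mean", "se", "n",
                             "nSubjects")])
  }
  rownames(out) <- NULL
  out
}

#' Predicted partial effect of kept fixed effects
#'
#' Evaluates the prediction from the intercept plus a kept subset of fixed
#' effects over a grid of one predictor (all other kept terms at their mean,
#' i.e. zero on the standardized scale), with a 95 percent normal-theory
#' band from the fixed-effect covariance of the kept terms. Random effects
#' (between-subject and between-item variance) are removed.
#'
#' @param fit a \linkS4class{DurationFit}.
#' @param predictor the kept predictor varied over the grid.
#' @param keep character vector of kept fixed-effect terms; defaults to the
#'   intercept plus \code{predictor}.
#' @param grid numeric grid in standardized units.
#' @return data.frame with \code{grid}, \code{fit}, \code{lower},
#'   \code{upper}.
#' @export
partialEffects <- function(fit, predictor,
                           keep = c("(Intercept)", predictor),
                           grid = seq(-2, 2, length.out = 41)) {
  tt <- coefTable(fit)
  unknown <- setdiff(c(keep, predictor), tt$term)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  G <- matrix(0, length(grid), length(keep), dimnames = list(NULL, keep))
  if ("(Intercept)" %in% keep) G[, "(Intercept)"] <- 1
  # a predictor outside 'keep' contributes nothing: the curve is flat
  if (predictor %in% keep) G[, predictor] <- grid
  # quadratic companion terms follow the varied predictor
  for (sq in intersect(paste0(predictor, "Sq"), keep)) G[, sq] <- grid^2
  b <- setNames(tt$b, tt$term)[keep]
  V <- as.matrix(vcov(lmerFit(fit)))
  dimnames(V) <- list(tt$term, tt$term)
  V <- V[keep, keep, drop = FALSE]
  pred <- as.numeric(G %*% b)
  seBand <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  data.frame(grid = grid, fit = pred,
             lower = pred - 1.96 * seBand, upper = pred + 1.96 * seBand)
}

#' Decompose fitted values into kept and removed components
#'
#' Splits every observation's prediction into the part carried by the kept
#' fixed effects and the removed remainder (other fixed effects plus the
#' conditional random effects). The identity
#' \code{kept + removed + residual = response} holds exactly.
#'
#' @param fit a \linkS4class{DurationFit}.
#' @param keep character vector of kept fixed-effect terms.
#' @return data.frame with per-observation \code{kept}, \code{removed},
#'   \code{fitted}, \code{residual}, \code{response}.
#' @export
partialDecomposition <- function(fit, keep) {
  tt <- coefTable(fit)
  unknown <- setdiff(keep, tt$term)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  spec <- structure(fit@spec, class = "fixdurModelSpec")
  des <- buildDesign(modelData(fit), spec)
  b <- setNames(tt$b, tt$term)
  keptPart <- as.numeric(des$X[, keep, drop = FALSE] %*% b[keep])
  mod <- lmerFit(fit)
  fitted <- as.numeric(fitted(mod))
  resid <- as.numeric(residuals(mod))
  data.frame(kept = keptPart, removed = fitted - keptPart,
             fitted = fitted, residual = resid, response = des$y)
}
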