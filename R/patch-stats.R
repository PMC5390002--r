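#' Circular patch mask
#'
#' Logical H x W mask of the pixels whose centres lie within \code{radiusPx}
#' (Euclidean) of the given centre, clipped to the image bounds. Coordinates
#' are 0-based pixel centres with the origin at the top-left corner and y
#' increasing downwards (x = column, y = row).
#'
#' @param center numeric (x, y) in pixels.
#' @param radiusPx patch radius in pixels (> 0).
#' @param dim image shape c(H, W).
#' @return logical matrix; error if no pixel falls inside (invalid fixation
#'   location).
#' @examples
#' sum(circularMask(c(10, 10), 1, c(21, 21)))  # centre + 4-neighbourhood = 5
#' @export
circularMask <- function(center, radiusPx, dim) {
  stopifnot(length(center) == 2, all(is.finite(center)), radiusPx > 0,
            length(dim) == 2)
  H <- dim[1]; W <- dim[2]
  x <- center[1]; y <- center[2]
  if (x + radiusPx < 0 || x - radiusPx > W - 1 ||
      y + radiusPx < 0 || y - radiusPx > H - 1)
    stop("invalid fixation location: patch lies entirely outside the image")
  cols <- max(0, floor(x - radiusPx)):min(W - 1, ceiling(x + radiusPx))
  rows <- max(0, floor(y - radiusPx)):min(H - 1, ceiling(y + radiusPx))
  d2 <- outer((rows - y)^2, (cols - x)^2, `+`)
  inside <- d2 <= radiusPx^2
  if (!any(inside))
    stop("invalid fixation location: patch lies entirely outside the image")
  mask <- matrix(FALSE, H, W)
  mask[rows + 1, cols + 1] <- inside
  mask
}

#' Pixel radius for a visual angle
#'
#' @param deg visual angle in degrees (> 0).
#' @param pxPerDeg pixels per degree.
#' @return integer pixel radius, \code{round(deg * pxPerDeg)}. At the 800 px /
#'   25.78 deg display geometry, 1 degree is 31 pixels.
#' @examples
#' pxRadiusForDegrees(1, 800 / 25.78)  # 31
#' @export
pxRadiusForDegrees <- function(deg, pxPerDeg) {
  stopifnot(deg > 0, pxPerDeg > 0)
  as.integer(round(deg * pxPerDeg))
}

#' Patch statistics
#'
#' Local image statistics under a circular mask: \code{patchLuminance} and
#' \code{patchClutter} are the masked means, \code{patchContrast} the RMS
#' contrast (population SD of the masked luminance divided by the mean
#' luminance of the whole image), \code{patchEdgeDensity} the proportion of
#' edge pixels, and \code{patchSegmentCount} the number of distinct segment
#' labels intersecting the patch.
#'
#' @param map,edgeMap,segmentMap H x W feature maps.
#' @param mask logical mask from \code{\link{circularMask}}.
#' @param imageMeanLuminance mean of the full luminance map (> 0).
#' @return A scalar statistic.
#' @name patchStats
NULL

assertMask <- function(map, mask) {
  stopifnot(is.matrix(map), identical(dim(map), dim(mask)))
  if (!any(mask)) stop("empty patch mask")
}

#' @rdname patchStats
#' @export
patchLuminance <- function(map, mask) {
  assertMask(map, mask)
  mean(map[mask])
}

#' @rdname patchStats
#' @export
patchContrast <- function(map, mask, imageMeanLuminance) {
  assertMask(map, mask)
  if (!is.finite(imageMeanLuminance) || imageMeanLuminance <= 0)
    stop("image mean luminance must be positive (degenerate all-black image)")
  v <- map[mask]
  sqrt(mean((v - mean(v))^2)) / imageMeanLuminance  # population SD
}

#' @rdname patchStats
#' @export
patchEdgeDensity <- function(edgeMap, mask) {
  assertMask(edgeMap, mask)
  mean(edgeMap[mask])
}

#' @rdname patchStats
#' @export
patchClutter <- function(map, mask) {
  assertMask(map, mask)
  mean(map[mask])
}

#' @rdname patchStats
#' @export
patchSegmentCount <- function(segmentMap, mask) {
  assertMask(segmentMap, mask)
  length(unique(as.integer(segmentMap[mask])))
}

#' Logit transform for edge-density proportions
#'
#' \code{0.5 * log(p / (1 - p))}, stretching out proportions close to zero.
#' Exact zeros are regularised to \code{pFloor}, the smallest nonzero value
#' in the analysis dataset.
#'
#' @param p proportion(s) in [0, 1).
#' @param pFloor replacement for p = 0, in (0, 1).
#' @return numeric vector of half-logits.
#' @examples
#' logitTransform(0.5, 0.01)  # 0
#' @export
logitTransform <- function(p, pFloor) {
  stopifnot(pFloor > 0, pFloor < 1)
  if (any(p < 0) || any(p >= 1))
    stop("proportions must lie in [0, 1)")
  p[p == 0] <- pFloor
  0.5 * log(p / (1 - p))
}

#' Overlap fraction of two equal circles
#'
#' Area of the intersection of two circles of equal radius divided by the
#' area of one circle (the circular-lens closed form). Two 1-degree patches
#' whose centres are one radius apart overlap by 39 percent, which motivates
#' excluding triplets with saccades of 2 degrees or less.
#'
#' @param centerA,centerB numeric (x, y) centres (same units as radius).
#' @param radius circle radius (> 0).
#' @return overlap fraction in [0, 1].
#' @examples
#' round(patchOverlapFraction(c(0, 0), c(1, 0), 1), 2)  # 0.39
#' @export
patchOverlapFraction <- function(centerA, centerB, radius) {
  stopifnot(radius > 0)
  d <- sqrt(sum((centerA - centerB)^2))
  if (d >= 2 * radius) return(0)
  lens <- 2 * radius^2 * acos(d / (2 * radius)) -
    (d / 2) * sqrt(4 * radius^2 - d^2)
  lens / (pi * radius^2)
}

#' Patch features for a table of fixation locations
#'
#' Evaluates the five local statistics for every fixation, using a circular
#' patch of \code{radiusPx} around each (x, y). Patches that extend past the
#' image border are clipped to in-bounds pixels and flagged.
#'
#' @param maps a \linkS4class{FeatureMapSet}.
#' @param fixations data.frame with numeric columns \code{x}, \code{y}
#'   (0-based pixel coordinates).
#' @param radiusPx patch radius in pixels.
#' @return \code{fixations} with appended columns \code{luminance},
#'   \code{contrast}, \code{edgeDensityRaw}, \code{clutterValue},
#'   \code{nSegmentsPatch}, \code{clipped}. Edge densities are raw
#'   proportions; the logit transform is applied at standardisation time
#'   when the dataset-wide floor is known.
#' @export
patchFeatures <- function(maps, fixations, radiusPx) {
  stopifnot(is(maps, "FeatureMapSet"), all(c("x", "y") %in% names(fixations)))
  lum <- luminance(maps); edg <- edges(maps)
  clu <- clutter(maps); seg <- segments(maps)
  dimHW <- dim(lum)
  meanLum <- mean(lum)
  n <- nrow(fixations)
  out <- data.frame(luminance = numeric(n), contrast = numeric(n),
                    edgeDensityRaw = numeric(n), clutterValue = numeric(n),
                    nSegmentsPatch = integer(n), clipped = logical(n))
  for (i in seq_len(n)) {
    ctr <- c(fixations$x[i], fixations$y[i])
    mask <- circularMask(ctr, radiusPx, dimHW)
    out$luminance[i] <- patchLuminance(lum, mask)
    out$contrast[i] <- patchContrast(lum, mask, meanLum)
    out$edgeDensityRaw[i] <- patchEdgeDensity(edg, mask)
    out$clutterValue[i] <- patchClutter(clu, mask)
    out$nSegmentsPatch[i] <- patchSegmentCount(seg, mask)
    out$clipped[i] <- ctr[1] - radiusPx < 0 || ctr[1] + radiusPx > dimHW[2] - 1 ||
      ctr[2] - radiusPx < 0 || ctr[2] + radiusPx > dimHW[1] - 1
  }
  cbind(fixations, out)
}
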