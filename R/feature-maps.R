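#' Configuration for the feature-map computations
#'
#' Collects every tunable of the per-scene feature maps: the adaptive Sobel
#' threshold factor, the feature-congestion pyramid depth, channel weights and
#' pooling scale, and the mean-shift segmentation bandwidths.
#'
#' @param sobelThresholdFactor the binarisation threshold is this multiple of
#'   the mean gradient magnitude (an automatic edge-threshold heuristic).
#' @param clutterLevels number of Gaussian-pyramid levels for clutter.
#' @param clutterWeights named weights for the colour, contrast and
#'   orientation clutter channels (each channel is min-max normalised before
#'   weighting).
#' @param clutterSigma spatial scale (px) of the local pooling windows.
#' @param msSpatialBandwidth mean-shift spatial bandwidth in pixels.
#' @param msRangeBandwidth mean-shift range bandwidth in CIELab units.
#' @param msMinRegion minimum segment size in pixels; smaller regions are
#'   fused into their most similar neighbour.
#' @param msMaxIter,msTol mean-shift iteration cap and convergence tolerance.
#' @return A list of class \code{fixdurFeatureConfig}.
#' @export
featureConfig <- function(sobelThresholdFactor = 4,
                          clutterLevels = 3L,
                          clutterWeights = c(color = 0.24, contrast = 0.06,
                                             orientation = 0.70),
                          clutterSigma = 2,
                          msSpatialBandwidth = 7L,
                          msRangeBandwidth = 6.5,
                          msMinRegion = 20L,
                          msMaxIter = 10L,
                          msTol = 0.1) {
  clutterWeights <- unlist(clutterWeights)
  stopifnot(sobelThresholdFactor > 0, clutterLevels >= 1,
            all(clutterWeights >= 0),
            all(c("color", "contrast", "orientation") %in%
                  names(clutterWeights)),
            msSpatialBandwidth >= 1,
            msRangeBandwidth > 0, msMinRegion >= 1)
  structure(list(sobelThresholdFactor = sobelThresholdFactor,
                 clutterLevels = as.integer(clutterLevels),
                 clutterWeights = clutterWeights,
                 clutterSigma = clutterSigma,
                 msSpatialBandwidth = as.integer(msSpatialBandwidth),
                 msRangeBandwidth = msRangeBandwidth,
                 msMinRegion = as.integer(msMinRegion),
                 msMaxIter = as.integer(msMaxIter),
                 msTol = msTol),
            class = "fixdurFeatureConfig")
}

# sRGB (0..255, IEC 61966-2-1) -> CIELab via grDevices::convertColor.
# Returns H x W matrices L (0..100), a, b.
sceneLab <- function(scene) {
  px <- pixels(scene)
  d <- dim(px)
  rgb <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3])) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

#' Normalised CIELab luminance map
#'
#' Converts the scene's sRGB pixels to CIE L*a*b* (IEC 61966-2-1 sRGB
#' assumptions), keeps the L* channel and min-max rescales it to [0, 1]
#' per image. A constant image has no luminance range; it maps to an
#' all-zero matrix and a warning is issued.
#'
#' @param scene a \linkS4class{SceneImage}.
#' @return H x W numeric matrix in [0, 1]; attribute \code{"constant"} is
#'   TRUE when the degenerate fallback was taken.
#' @examples
#' img <- SceneImage(array(runif(600 * 3, 0, 255), c(20, 30, 3)), 31)
#' range(luminanceMap(img))
#' @export
luminanceMap <- function(scene) {
  stopifnot(is(scene, "SceneImage"))
  L <- sceneLab(scene)$L
  rng <- range(L)
  if (rng[2] - rng[1] <= 1e-12) {
    warning("constant image: luminance map set to all zeros")
    out <- matrix(0, nrow(L), ncol(L))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (L - rng[1]) / (rng[2] - rng[1])
  attr(out, "constant") <- FALSE
  out
}

sobelGradient <- function(lum) {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy <- t(gx)
  sqrt(conv2Reflect(lum, gx)^2 + conv2Reflect(lum, gy)^2)
}

#' Binary Sobel edge map
#'
#' Applies 3x3 horizontal and vertical Sobel kernels (reflect-padded) to a
#' luminance map and binarises the gradient magnitude at an automatically
#' chosen threshold: \code{thresholdFactor} times the mean gradient
#' magnitude. A constant map yields an all-zero edge map.
#'
#' @param lum H x W luminance map in [0, 1].
#' @param thresholdFactor multiple of the mean gradient magnitude used as
#'   threshold (default 4).
#' @return H x W binary matrix (1 = edge pixel).
#' @export
edgeMap <- function(lum, thresholdFactor = 4) {
  stopifnot(is.matrix(lum), thresholdFactor > 0)
  g <- sobelGradient(lum)
  thr <- thresholdFactor * mean(g)
  if (thr <= 0) return(matrix(0, nrow(lum), ncol(lum)))
  (g > thr) + 0
}

# one pyramid level's three clutter channels at native resolution
clutterChannels <- function(L, a, b, sigma) {
  # colour clutter: pooled covariance volume of the a*, b* chromaticity plane
  va <- localVar(a, sigma); vb <- localVar(b, sigma)
  cab <- gaussBlur(a * b, sigma) - gaussBlur(a, sigma) * gaussBlur(b, sigma)
  colorCl <- sqrt(pmax(va * vb - cab^2, 0))
  # contrast clutter: local std of centre-surround (DoG) luminance energy
  cs <- gaussBlur(L, 1) - gaussBlur(L, 2)
  contrastCl <- sqrt(localVar(cs^2, sigma))
  # orientation clutter: local std of oriented derivative energy, 4 orientations
  dx <- conv2Reflect(L, matrix(c(-1, 0, 1), nrow = 1)) / 2
  dy <- conv2Reflect(L, matrix(c(-1, 0, 1), ncol = 1)) / 2
  d45 <- (dx + dy) / sqrt(2)
  d135 <- (dx - dy) / sqrt(2)
  orientCl <- sqrt(localVar(dx^2, sigma) + localVar(dy^2, sigma) +
                   localVar(d45^2, sigma) + localVar(d135^2, sigma))
  list(color = colorCl, contrast = contrastCl, orientation = orientCl)
}

#' Feature-congestion visual clutter map
#'
#' Multi-scale feature-congestion clutter: local variability of colour
#' (covariance volume of a*, b*), of centre-surround luminance-contrast
#' energy, and of oriented-derivative energy at four orientations, pooled
#' over a Gaussian pyramid, upsampled to the image size, channel-normalised,
#' combined by fixed weights and min-max rescaled to [0, 1]. A constant image
#' yields an all-zero map.
#'
#' @param scene a \linkS4class{SceneImage}.
#' @param config a \code{\link{featureConfig}}.
#' @return H x W numeric matrix in [0, 1].
#' @export
clutterMap <- function(scene, config = featureConfig()) {
  stopifnot(is(scene, "SceneImage"))
  lab <- sceneLab(scene)
  nr <- nrow(lab$L); nc <- ncol(lab$L)
  chans <- list(color = matrix(0, nr, nc), contrast = matrix(0, nr, nc),
                orientation = matrix(0, nr, nc))
  L <- lab$L; a <- lab$a; b <- lab$b
  nlev <- 0L
  for (lev in seq_len(config$clutterLevels)) {
    if (nrow(L) < 4 || ncol(L) < 4) break
    cl <- clutterChannels(L, a, b, config$clutterSigma)
    for (nm in names(chans))
      chans[[nm]] <- chans[[nm]] + upsampleTo(cl[[nm]], nr, nc)
    nlev <- nlev + 1L
    L <- downsample2(L); a <- downsample2(a); b <- downsample2(b)
  }
  if (nlev == 0L) return(matrix(0, nr, nc))
  w <- config$clutterWeights
  out <- matrix(0, nr, nc)
  for (nm in names(chans))
    out <- out + (w[[nm]] %||% 0) * rescale01(chans[[nm]] / nlev)
  rescale01(out)
}

#' Mean-shift image segmentation
#'
#' Partitions the scene into perceptually homogeneous regions: mean-shift
#' filtering in the joint spatial and CIELab range domain, connected-component
#' labelling of the filtered image, and fusion of regions smaller than the
#' minimum size into their most similar neighbour. Segment counts per patch
#' serve as a local object-density surrogate.
#'
#' @param scene a \linkS4class{SceneImage}.
#' @param config a \code{\link{featureConfig}}; bandwidths
#'   \code{msSpatialBandwidth} (px), \code{msRangeBandwidth} (Lab units) and
#'   \code{msMinRegion} (px) control the partition granularity.
#' @return list with \code{labels} (H x W integer matrix, labels 1..K covering
#'   every pixel) and \code{nSegments} (K).
#' @export
segmentMap <- function(scene, config = featureConfig()) {
  stopifnot(is(scene, "SceneImage"))
  lab <- sceneLab(scene)
  f <- .msFilterCpp(lab$L, lab$a, lab$b, config$msSpatialBandwidth,
                    config$msRangeBandwidth, config$msMaxIter, config$msTol)
  labels <- .msLabelCpp(f$L, f$a, f$b, config$msRangeBandwidth,
                        config$msMinRegion)
  list(labels = labels, nSegments = length(unique(as.integer(labels))))
}

#' Compute all five feature maps for a scene
#'
#' Runs \code{\link{luminanceMap}}, \code{\link{edgeMap}},
#' \code{\link{clutterMap}} and \code{\link{segmentMap}} and bundles them in
#' a \linkS4class{FeatureMapSet}.
#'
#' @param scene a \linkS4class{SceneImage}.
#' @param config a \code{\link{featureConfig}}.
#' @return A \linkS4class{FeatureMapSet}.
#' @examples
#' img <- SceneImage(array(runif(20 * 30 * 3, 0, 255), c(20, 30, 3)), 6)
#' fm <- computeFeatureMaps(img)
#' nSegments(fm)
#' @export
computeFeatureMaps <- function(scene, config = featureConfig()) {
  lum <- suppressWarnings(luminanceMap(scene))
  constant <- isTRUE(attr(lum, "constant"))
  attr(lum, "constant") <- NULL
  seg <- segmentMap(scene, config)
  new("FeatureMapSet",
      luminance = lum,
      edges = edgeMap(lum, config$sobelThresholdFactor),
      clutter = clutterMap(scene, config),
      segments = seg$labels,
      nSegments = as.integer(seg$nSegments),
      sceneId = sceneId(scene),
      constantImage = constant)
}
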