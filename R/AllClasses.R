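#' SceneImage: a raster scene with a degrees-to-pixels calibration
#'
#' Container for one RGB scene image together with the display calibration
#' that converts pixels to degrees of visual angle. All feature maps and
#' patch statistics are derived from this object.
#'
#' @slot pixels numeric array H x W x 3, sRGB channel values in [0, 255].
#' @slot pxPerDeg pixels per degree of visual angle (scalar > 0).
#' @slot sceneId character scalar identifier.
#' @export
setClass("SceneImage",
  representation(pixels = "array", pxPerDeg = "numeric", sceneId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 1L || d[2] < 1L)
      return("image must have at least one row and one column")
    if (anyNA(object@pixels) || any(!is.finite(object@pixels)))
      return("pixels must be finite")
    if (min(object@pixels) < 0 || max(object@pixels) > 255)
      return("channel values must lie in [0, 255]")
    if (length(object@pxPerDeg) != 1L || !is.finite(object@pxPerDeg) ||
        object@pxPerDeg <= 0)
      return("pxPerDeg must be a positive scalar")
    if (length(object@sceneId) != 1L)
      return("sceneId must be a single identifier")
    TRUE
  })

#' Construct a SceneImage
#'
#' @param pixels H x W x 3 array of sRGB values in [0, 255].
#' @param pxPerDeg pixels per degree of visual angle.
#' @param sceneId scene identifier.
#' @return A \linkS4class{SceneImage}.
#' @examples
#' img <- SceneImage(array(runif(30 * 40 * 3, 0, 255), c(30, 40, 3)), 31)
#' dim(pixels(img))
#' @export
SceneImage <- function(pixels, pxPerDeg, sceneId = "scene") {
  new("SceneImage", pixels = pixels, pxPerDeg = as.numeric(pxPerDeg),
      sceneId = as.character(sceneId))
}

#' FeatureMapSet: the five aligned per-scene feature maps
#'
#' Holds the per-pixel maps from which local patch statistics are computed:
#' normalised CIELab luminance, a binary Sobel edge map, a normalised
#' feature-congestion clutter map, and an integer segment-label map from
#' mean-shift segmentation. All maps share the parent scene's spatial shape.
#'
#' @slot luminance H x W numeric in [0, 1].
#' @slot edges H x W binary (0/1) matrix.
#' @slot clutter H x W numeric in [0, 1].
#' @slot segments H x W integer labels >= 1, a full partition of the image.
#' @slot nSegments total number of segments in the scene.
#' @slot sceneId scene identifier.
#' @slot constantImage TRUE when the source image was constant (degenerate
#'   min-max normalisations fall back to all-zero maps).
#' @export
setClass("FeatureMapSet",
  representation(luminance = "matrix", edges = "matrix", clutter = "matrix",
                 segments = "matrix", nSegments = "integer",
                 sceneId = "character", constantImage = "logical"),
  validity = function(object) {
    d <- dim(object@luminance)
    for (nm in c("edges", "clutter", "segments"))
      if (!identical(dim(slot(object, nm)), d))
        return(sprintf("map '%s' does not match the luminance map's shape", nm))
    if (anyNA(object@luminance) || min(object@luminance) < 0 ||
        max(object@luminance) > 1)
      return("luminance must lie in [0, 1]")
    if (!all(object@edges %in% c(0, 1)))
      return("edges must be binary")
    if (anyNA(object@clutter) || min(object@clutter) < 0 ||
        max(object@clutter) > 1)
      return("clutter must lie in [0, 1]")
    labs <- unique(as.integer(object@segments))
    if (min(labs) < 1L)
      return("segment labels must be >= 1")
    if (object@nSegments != length(labs))
      return("nSegments must equal the number of distinct labels")
    TRUE
  })

#' DurationFit: a fitted zero-correlation-parameter LMM
#'
#' Wraps an lme4 fit of log fixation durations with the model specification,
#' the fixed-effect table (b, SE, t), variance components, and fit criteria.
#' Accessors: \code{coefTable}, \code{varComp}, \code{fitCriterion},
#' \code{nObs}, \code{modelData}, \code{lmerFit}.
#'
#' @slot coefTable data.frame with columns term, b, se, t.
#' @slot varComp data.frame with columns group, term, sd, var (residual
#'   included with group "Residual").
#' @slot criterion the REML criterion or ML deviance (-2 logLik).
#' @slot REML logical, TRUE for a REML fit.
#' @slot nObs number of observations.
#' @slot spec the \code{modelSpec} used.
#' @slot fit the underlying \code{lmerMod} (class "ANY").
#' @slot data the model frame the fit was computed on.
#' @export
setClass("DurationFit",
  representation(coefTable = "data.frame", varComp = "data.frame",
                 criterion = "numeric", REML = "logical", nObs = "integer",
                 spec = "list", fit = "ANY", data = "data.frame"),
  validity = function(object) {
    if (!all(c("term", "b", "se", "t") %in% names(object@coefTable)))
      return("coefTable must have columns term, b, se, t")
    tt <- object@coefTable
    if (any(abs(tt$t - tt$b / tt$se) > 1e-8, na.rm = TRUE))
      return("t must equal b / se")
    if (any(object@varComp$var < 0))
      return("variance components must be non-negative")
    TRUE
  })

## ---- accessors -------------------------------------------------------------

#' @rdname SceneImage-class
#' @param object,x a SceneImage / FeatureMapSet / DurationFit.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname SceneImage-class
#' @export
setMethod("pixels", "SceneImage", function(x) x@pixels)

#' @rdname SceneImage-class
#' @export
setGeneric("pxPerDeg", function(x) standardGeneric("pxPerDeg"))
#' @rdname SceneImage-class
#' @export
setMethod("pxPerDeg", "SceneImage", function(x) x@pxPerDeg)

#' @rdname SceneImage-class
#' @export
setGeneric("sceneId", function(x) standardGeneric("sceneId"))
#' @rdname SceneImage-class
#' @export
setMethod("sceneId", "SceneImage", function(x) x@sceneId)
#' @rdname FeatureMapSet-class
#' @export
setMethod("sceneId", "FeatureMapSet", function(x) x@sceneId)

#' @rdname FeatureMapSet-class
#' @export
setGeneric("luminance", function(x) standardGeneric("luminance"))
#' @rdname FeatureMapSet-class
#' @export
setMethod("luminance", "FeatureMapSet", function(x) x@luminance)

#' @rdname FeatureMapSet-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname FeatureMapSet-class
#' @export
setMethod("edges", "FeatureMapSet", function(x) x@edges)

#' @rdname FeatureMapSet-class
#' @export
setGeneric("clutter", function(x) standardGeneric("clutter"))
#' @rdname FeatureMapSet-class
#' @export
setMethod("clutter", "FeatureMapSet", function(x) x@clutter)

#' @rdname FeatureMapSet-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname FeatureMapSet-class
#' @export
setMethod("segments", "FeatureMapSet", function(x) x@segments)

#' @rdname FeatureMapSet-class
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname FeatureMapSet-class
#' @export
setMethod("nSegments", "FeatureMapSet", function(x) x@nSegments)

#' @rdname DurationFit-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
#' @rdname DurationFit-class
#' @export
setMethod("coefTable", "DurationFit", function(x) x@coefTable)

#' @rdname DurationFit-class
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname DurationFit-class
#' @export
setMethod("varComp", "DurationFit", function(x) x@varComp)

#' @rdname DurationFit-class
#' @export
setGeneric("fitCriterion", function(x) standardGeneric("fitCriterion"))
#' @rdname DurationFit-class
#' @export
setMethod("fitCriterion", "DurationFit", function(x) x@criterion)

#' @rdname DurationFit-class
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname DurationFit-class
#' @export
setMethod("nObs", "DurationFit", function(x) x@nObs)

#' @rdname DurationFit-class
#' @export
setGeneric("modelData", function(x) standardGeneric("modelData"))
#' @rdname DurationFit-class
#' @export
setMethod("modelData", "DurationFit", function(x) x@data)

#' @rdname DurationFit-class
#' @export
setGeneric("lmerFit", function(x) standardGeneric("lmerFit"))
#' @rdname DurationFit-class
#' @export
setMethod("lmerFit", "DurationFit", function(x) x@fit)

## ---- show ------------------------------------------------------------------

setMethod("show", "SceneImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SceneImage '%s': %d x %d px (%.2f x %.2f deg at %.2f px/deg)\n",
              object@sceneId, d[1], d[2], d[1] / object@pxPerDeg,
              d[2] / object@pxPerDeg, object@pxPerDeg))
})

setMethod("show", "FeatureMapSet", function(object) {
  d <- dim(object@luminance)
  cat(sprintf(paste0("FeatureMapSet '%s': %d x %d px; edge density %.3f; ",
                     "%d segments%s\n"),
              object@sceneId, d[1], d[2], mean(object@edges),
              object@nSegments,
              if (object@constantImage) " (constant image)" else ""))
})

setMethod("show", "DurationFit", function(object) {
  cat(sprintf("DurationFit (%s): %d obs, %d fixed effects, %d variance components\n",
              if (object@REML) "REML" else "ML", object@nObs,
              nrow(object@coefTable), nrow(object@varComp) - 1L))
  cat(sprintf("criterion: %.2f\n", object@criterion))
  print(head(object@coefTable, 8), row.names = FALSE, digits = 3)
  if (nrow(object@coefTable) > 8) cat("...\n")
})
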