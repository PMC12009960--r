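# Generics and accessor methods.

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("barrierRange", function(x) standardGeneric("barrierRange"))
#' @export
setGeneric("forwardSide", function(x) standardGeneric("forwardSide"))
#' @export
setGeneric("channelLanes", function(x) standardGeneric("channelLanes"))
#' @export
setGeneric("leafPolygons", function(x) standardGeneric("leafPolygons"))
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @export
setGeneric("channelType", function(x) standardGeneric("channelType"))
#' @export
setGeneric("imageOffset", function(x) standardGeneric("imageOffset"))
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Accessors for device geometry
#'
#' @param x a [DeviceGeometry-class], [FieldImage-class] or
#'   [Kymograph-class] object.
#' @return `pixelSize` the um/px calibration; `barrierRange` the barrier
#'   x-interval in um; `forwardSide` `"left"` or `"right"`; `channelLanes`
#'   the list of lane y-intervals; `leafPolygons` the exclusion polygons.
#' @name geometry-accessors
#' @aliases pixelSize barrierRange forwardSide channelLanes leafPolygons
#' @examples
#' g <- deviceGeometry()
#' barrierRange(g)
#' pixelSize(g)
NULL

#' @rdname geometry-accessors
#' @export
setMethod("pixelSize", "DeviceGeometry", function(x) x@pixelSize)
#' @rdname geometry-accessors
#' @export
setMethod("barrierRange", "DeviceGeometry", function(x) x@barrier)
#' @rdname geometry-accessors
#' @export
setMethod("forwardSide", "DeviceGeometry", function(x) x@forwardSide)
#' @rdname geometry-accessors
#' @export
setMethod("channelLanes", "DeviceGeometry", function(x) x@lanes)
#' @rdname geometry-accessors
#' @export
setMethod("leafPolygons", "DeviceGeometry", function(x) x@leafPolygons)

#' Accessors for field images
#'
#' @param x a [FieldImage-class].
#' @return `imageData` the intensity matrix (rows = y, cols = x);
#'   `channelType` the channel label; `imageOffset` the (x, y) origin in um;
#'   `imageId` the identifier; `pixelSize` the calibration in um/px.
#' @name fieldimage-accessors
#' @aliases imageData channelType imageOffset imageId
NULL

#' @rdname fieldimage-accessors
#' @export
setMethod("imageData", "FieldImage", function(x) x@data)
#' @rdname fieldimage-accessors
#' @export
setMethod("channelType", "FieldImage", function(x) x@channel)
#' @rdname fieldimage-accessors
#' @export
setMethod("imageOffset", "FieldImage", function(x) x@offset)
#' @rdname fieldimage-accessors
#' @export
setMethod("imageId", "FieldImage", function(x) x@imageId)
#' @rdname fieldimage-accessors
#' @export
setMethod("pixelSize", "FieldImage", function(x) x@pixelSize)
#' @rdname fieldimage-accessors
#' @export
setMethod("dim", "FieldImage", function(x) dim(x@data))

#' Accessors for kymographs
#'
#' @param x a [Kymograph-class].
#' @return `imageData` the position-by-time matrix; `frameInterval` the
#'   seconds between frames; `pixelSize` the um/px along the channel axis;
#'   `barrierRange` the barrier x-interval in device coordinates.
#' @name kymograph-accessors
#' @aliases frameInterval
NULL

#' @rdname kymograph-accessors
#' @export
setMethod("imageData", "Kymograph", function(x) x@data)
#' @rdname kymograph-accessors
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@frameInterval)
#' @rdname kymograph-accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)
#' @rdname kymograph-accessors
#' @export
setMethod("barrierRange", "Kymograph", function(x) x@barrier)

setMethod("show", "DeviceGeometry", function(object) {
  cat("DeviceGeometry\n")
  cat(sprintf("  barrier x-range: [%g, %g] um (length %g um)\n",
              object@barrier[1L], object@barrier[2L], diff(object@barrier)))
  cat(sprintf("  forward chamber: %s of barrier\n", object@forwardSide))
  cat(sprintf("  lanes: %d; leaf polygons: %d; pixel size: %g um/px\n",
              length(object@lanes), length(object@leafPolygons),
              object@pixelSize))
})

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("FieldImage '%s' [%s]: %d x %d px (%.0f x %.0f um), offset (%g, %g) um\n",
              object@imageId, object@channel, d[2L], d[1L],
              d[2L] * object@pixelSize, d[1L] * object@pixelSize,
              object@offset[1L], object@offset[2L]))
})

setMethod("show", "RoiBand", function(object) {
  cat(sprintf("RoiBand: %s chamber, %g-%g um from barrier\n",
              object@chamber, object@range[1L], object@range[2L]))
})

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@data)
  cat(sprintf("Kymograph lane %d: %d positions x %d frames (%.2f um/px, %g s/frame)\n",
              object@laneId, d[1L], d[2L], object@pixelSize,
              object@frameInterval))
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("Linear trend: y = %.3fx %+.3f; F(%d,%d) = %.3f, p = %.3g, R2 = %.3f (n = %d)\n",
              object@slope, object@intercept, object@df[1L], object@df[2L],
              object@fstat, object@pvalue, object@r2, object@n))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("Mann-Whitney U comparison (n1 = %d, n2 = %d)\n",
              object@n[1L], object@n[2L]))
  cat(sprintf("  means: %.3f vs %.3f; mean difference = %.3f\n",
              object@meanA, object@meanB, object@meanDifference))
  cat(sprintf("  U = %g, two-sided p = %.4g (%s)\n", object@U,
              object@pvalue, if (object@exact) "exact" else "normal approx."))
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams\n")
  cat(sprintf("  threshold: %s; min area: %g um^2; connectivity: %d\n",
              object@thresholdMethod, object@minArea, object@connectivity))
  cat(sprintf("  coloc fraction: %g (dilation %d px); CFSE fraction: %g\n",
              object@colocFraction, object@dilationRadius,
              object@cfseFraction))
})
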