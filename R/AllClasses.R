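# S4 classes shared across the package.

#' Two-chamber microfluidic device geometry
#'
#' Describes the coordinate frame of a two-chamber device: the microchannel
#' barrier interval along the channel (x) axis, which side of the barrier is
#' the forward chamber, the y-stripes of the individual microchannel lanes,
#' leaf "dead-end" exclusion polygons inside the barrier, and the pixel
#' calibration. All coordinates are micrometres. By convention x increases
#' from the forward to the reverse chamber, so retrograde transport has
#' dx/dt < 0.
#'
#' @slot barrier numeric(2), the x-interval \[min, max\] occupied by the
#'   microchannel barrier (default length 1000 um).
#' @slot forwardSide `"left"` or `"right"`: which side of the barrier holds
#'   the forward chamber.
#' @slot lanes list of numeric(2) y-intervals, one per microchannel lane.
#' @slot leafPolygons list of two-column matrices (x, y in um), polygons to
#'   exclude from kymograph projection.
#' @slot pixelSize micrometres per pixel.
#' @exportClass DeviceGeometry
setClass("DeviceGeometry",
  representation(barrier = "numeric", forwardSide = "character",
                 lanes = "list", leafPolygons = "list",
                 pixelSize = "numeric"))

setValidity("DeviceGeometry", function(object) {
  msg <- character()
  if (length(object@barrier) != 2L || diff(object@barrier) <= 0)
    msg <- c(msg, "barrier must be an interval of positive length")
  if (!object@forwardSide %in% c("left", "right"))
    msg <- c(msg, "forwardSide must be 'left' or 'right'")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@lanes) > 1L) {
    iv <- do.call(rbind, object@lanes)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      msg <- c(msg, "channel lanes must be pairwise disjoint")
  }
  for (p in object@leafPolygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      msg <- c(msg, "leaf polygons must be matrices with >= 3 (x, y) rows")
      break
    }
    if (min(p[, 1L]) < object@barrier[1L] || max(p[, 1L]) > object@barrier[2L]) {
      msg <- c(msg, "leaf polygons must lie within the barrier x-range")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Region-of-interest distance band
#'
#' A chamber plus a closed interval of distances from the barrier edge.
#' The main pathology analysis uses \[400, 1600\] um; near-channel (CFSE)
#' analyses use \[0, 400\] um.
#'
#' @slot chamber `"forward"` or `"reverse"`.
#' @slot range numeric(2) closed distance interval \[d_min, d_max\] in um,
#'   0 <= d_min < d_max.
#' @exportClass RoiBand
setClass("RoiBand",
  representation(chamber = "character", range = "numeric"))

setValidity("RoiBand", function(object) {
  msg <- character()
  if (!object@chamber %in% c("forward", "reverse"))
    msg <- c(msg, "chamber must be 'forward' or 'reverse'")
  if (length(object@range) != 2L || object@range[1L] < 0 ||
      object@range[1L] >= object@range[2L])
    msg <- c(msg, "range must satisfy 0 <= d_min < d_max")
  if (length(msg)) msg else TRUE
})

#' A single-channel field image placed in device coordinates
#'
#' Wraps a 2D intensity matrix (rows = y, columns = x) together with its
#' channel label, pixel calibration and the device-coordinate offset of the
#' image origin (the outer corner of pixel \[1, 1\]). Pixel centres are at
#' `offset + (index - 0.5) * pixelSize`.
#'
#' @slot data numeric matrix of non-negative intensities.
#' @slot channel one of `"psyn"`, `"tubulin"`, `"cfse"`, `"movie_frame"`.
#' @slot pixelSize micrometres per pixel.
#' @slot offset numeric(2), (x, y) of the image origin in um.
#' @slot imageId character scalar identifier.
#' @exportClass FieldImage
setClass("FieldImage",
  representation(data = "matrix", channel = "character",
                 pixelSize = "numeric", offset = "numeric",
                 imageId = "character"))

setValidity("FieldImage", function(object) {
  msg <- character()
  if (nrow(object@data) < 1L || ncol(object@data) < 1L)
    msg <- c(msg, "image must be at least 1x1")
  if (!object@channel %in% c("psyn", "tubulin", "cfse", "movie_frame"))
    msg <- c(msg, "unknown channel label")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (length(object@offset) != 2L)
    msg <- c(msg, "offset must be length 2 (x, y) in um")
  if (any(object@data < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Segmentation parameters for the pathology-detection chain
#'
#' @slot thresholdMethod `"otsu"` or `"manual"` (per channel, named vector
#'   accepted by [thresholdMask()]).
#' @slot manualLevel named numeric of manual threshold levels per channel.
#' @slot minArea minimum fragment area in um^2 (objects below are excluded).
#' @slot colocFraction minimum fraction of fragment pixels overlapping the
#'   (dilated) neurite mask.
#' @slot dilationRadius dilation radius in px applied to the neurite mask
#'   before colocalisation.
#' @slot connectivity 4 or 8 pixel connectivity for components.
#' @slot cfseFraction minimum overlap fraction with the CFSE mask to call a
#'   fragment CFSE-positive.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(thresholdMethod = "character", manualLevel = "numeric",
                 minArea = "numeric", colocFraction = "numeric",
                 dilationRadius = "integer", connectivity = "integer",
                 cfseFraction = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!object@thresholdMethod %in% c("otsu", "manual"))
    msg <- c(msg, "thresholdMethod must be 'otsu' or 'manual'")
  if (object@minArea <= 0) msg <- c(msg, "minArea must be > 0")
  if (object@colocFraction <= 0 || object@colocFraction > 1)
    msg <- c(msg, "colocFraction must be in (0, 1]")
  if (object@cfseFraction <= 0 || object@cfseFraction > 1)
    msg <- c(msg, "cfseFraction must be in (0, 1]")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@dilationRadius < 0L)
    msg <- c(msg, "dilationRadius must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Kymograph: maximum projection of a microchannel lane over time
#'
#' A position (along the channel axis) by time matrix built by taking, for
#' each frame and each x, the maximum intensity over the lane's y-pixels
#' outside the leaf polygons. Columns where the lane is fully covered by
#' leaf polygons are `NA`.
#'
#' @slot data numeric matrix, rows = x positions, columns = frames.
#' @slot pixelSize um per pixel along x.
#' @slot frameInterval seconds between frames.
#' @slot xOrigin device x-coordinate (um) of the outer edge of row 1.
#' @slot laneId integer lane index.
#' @slot barrier numeric(2), barrier x-range in device coordinates (um).
#' @exportClass Kymograph
setClass("Kymograph",
  representation(data = "matrix", pixelSize = "numeric",
                 frameInterval = "numeric", xOrigin = "numeric",
                 laneId = "integer", barrier = "numeric"))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ordinary least-squares time-trend fit
#'
#' @slot slope,intercept regression coefficients.
#' @slot fstat F statistic for the slope.
#' @slot df numeric(2) degrees of freedom (1, n - 2).
#' @slot pvalue p from the F distribution.
#' @slot r2 coefficient of determination.
#' @slot n number of points.
#' @exportClass TrendFit
setClass("TrendFit",
  representation(slope = "numeric", intercept = "numeric", fstat = "numeric",
                 df = "numeric", pvalue = "numeric", r2 = "numeric",
                 n = "integer"))

setValidity("TrendFit", function(object) {
  msg <- character()
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    msg <- c(msg, "R^2 must lie in [0, 1]")
  if (object@df[2L] != object@n - 2L)
    msg <- c(msg, "df2 must equal n - 2")
  if (length(msg)) msg else TRUE
})

#' Two-group comparison by the Mann-Whitney U test
#'
#' @slot meanA,meanB group means.
#' @slot meanDifference meanA - meanB.
#' @slot U the Mann-Whitney U statistic for group A.
#' @slot pvalue two-sided p-value.
#' @slot exact logical, whether p came from exact enumeration.
#' @slot n numeric(2) group sizes.
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(meanA = "numeric", meanB = "numeric",
                 meanDifference = "numeric", U = "numeric",
                 pvalue = "numeric", exact = "logical", n = "numeric"))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (object@U < 0 || object@U > prod(object@n))
    msg <- c(msg, "U must lie in [0, n1*n2]")
  if (!is.na(object@pvalue) && (object@pvalue <= 0 || object@pvalue > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
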