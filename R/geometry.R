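# Device coordinate frame and region-of-interest construction.

#' Construct a device geometry
#'
#' The default geometry places the 1 mm microchannel barrier at
#' \[0, 1000\] um with the forward chamber on the left (x < 0), so x
#' increases from the forward to the reverse chamber and retrograde
#' transport has negative velocity.
#'
#' @param barrier numeric(2) barrier x-interval in um.
#' @param forwardSide `"left"` (default) or `"right"`.
#' @param lanes list of numeric(2) y-intervals (um), one per microchannel.
#' @param leafPolygons list of two-column (x, y) matrices in um lying within
#'   the barrier x-range.
#' @param pixelSize um per pixel; the conventional 20x / 6.5 um-camera value
#'   0.325 by default, always overridable because the calibration is
#'   instrument configuration, not a constant.
#' @return a [DeviceGeometry-class] object.
#' @examples
#' g <- deviceGeometry()
#' distanceToBarrier(c(-400, 50), g)
#' @export
deviceGeometry <- function(barrier = c(0, 1000), forwardSide = "left",
                           lanes = list(), leafPolygons = list(),
                           pixelSize = 0.325) {
  new("DeviceGeometry", barrier = as.numeric(barrier),
      forwardSide = forwardSide, lanes = lanes,
      leafPolygons = leafPolygons, pixelSize = as.numeric(pixelSize))
}

#' Construct a region-of-interest band
#'
#' @param chamber `"forward"` or `"reverse"`.
#' @param range closed distance interval \[d_min, d_max\] in um from the
#'   barrier edge. The main analysis band is `c(400, 1600)`; near-channel
#'   analyses (CFSE) use `c(0, 400)`.
#' @return a [RoiBand-class] object.
#' @export
roiBand <- function(chamber = "forward", range = c(400, 1600)) {
  new("RoiBand", chamber = chamber, range = as.numeric(range))
}

#' Construct a field image
#'
#' @param data numeric matrix of intensities, rows = y, columns = x.
#' @param channel `"psyn"`, `"tubulin"`, `"cfse"` or `"movie_frame"`.
#' @param pixelSize um per pixel.
#' @param offset numeric(2) device coordinates (um) of the image origin
#'   (outer corner of pixel \[1, 1\]); pixel centres sit at
#'   `offset + (index - 0.5) * pixelSize`.
#' @param imageId character identifier.
#' @return a [FieldImage-class] object.
#' @export
fieldImage <- function(data, channel, pixelSize, offset = c(0, 0),
                       imageId = "field") {
  new("FieldImage", data = data, channel = channel,
      pixelSize = as.numeric(pixelSize), offset = as.numeric(offset),
      imageId = imageId)
}

#' Perpendicular distance from a point to the microchannel barrier
#'
#' The distance is taken along the channel (x) axis only: 0 inside the
#' barrier x-range, otherwise the distance to the nearest barrier edge.
#' Total function; vectorised over points.
#'
#' @param point numeric(2) (x, y) in um, or an n x 2 matrix of points.
#' @param geometry a [DeviceGeometry-class].
#' @return distance(s) in um.
#' @examples
#' g <- deviceGeometry()
#' distanceToBarrier(c(-400, 0), g)   # 400
#' distanceToBarrier(c(500, 0), g)    # 0 (inside barrier)
#' @export
distanceToBarrier <- function(point, geometry) {
  x <- if (is.matrix(point)) point[, 1L] else point[1L]
  b <- geometry@barrier
  pmax(0, pmax(b[1L] - x, x - b[2L]))
}

#' Which side of the barrier a device x-coordinate lies on
#'
#' @param x numeric vector of device x-coordinates in um.
#' @param geometry a [DeviceGeometry-class].
#' @return character vector: `"forward"`, `"reverse"` or `"barrier"`.
#' @export
chamberSide <- function(x, geometry) {
  b <- geometry@barrier
  lo <- x < b[1L]
  hi <- x > b[2L]
  side <- rep("barrier", length(x))
  if (geometry@forwardSide == "left") {
    side[lo] <- "forward"; side[hi] <- "reverse"
  } else {
    side[lo] <- "reverse"; side[hi] <- "forward"
  }
  side
}

#' Build a binary ROI mask for a distance band on one chamber side
#'
#' A pixel is included exactly when its centre lies on the requested chamber
#' side and its distance to the barrier satisfies
#' `d_min <= d <= d_max` (closed interval). Pixels inside the barrier
#' x-range lie on neither chamber side and are always excluded.
#'
#' @param geometry a [DeviceGeometry-class].
#' @param band a [RoiBand-class].
#' @param image a [FieldImage-class]; its offset places it in device
#'   coordinates.
#' @return logical matrix with the dimensions of `image`. If the mask is
#'   empty a warning is recorded (the mask is still returned).
#' @examples
#' g <- deviceGeometry()
#' img <- fieldImage(matrix(0, 4, 4), "psyn", 100, offset = c(-500, 0))
#' makeRoiMask(g, roiBand("forward", c(400, 1600)), img)
#' @export
makeRoiMask <- function(geometry, band, image) {
  stopifnot(is(geometry, "DeviceGeometry"), is(band, "RoiBand"),
            is(image, "FieldImage"))
  d <- dim(image@data)
  px <- image@pixelSize
  xc <- image@offset[1L] + (seq_len(d[2L]) - 0.5) * px
  dist <- distanceToBarrier(cbind(xc, 0), geometry)
  side <- chamberSide(xc, geometry)
  colIn <- side == band@chamber & dist >= band@range[1L] &
    dist <= band@range[2L]
  mask <- matrix(rep(colIn, each = d[1L]), nrow = d[1L])
  if (!any(mask))
    warning("ROI mask is empty for image '", image@imageId, "'")
  mask
}

#' Read or write a device geometry as JSON
#'
#' The JSON schema uses keys `barrier_x_range`, `forward_side`,
#' `channel_lanes`, `leaf_polygons` and `pixel_size`; all lengths in um.
#'
#' @param path file path.
#' @param geometry a [DeviceGeometry-class] (for writing).
#' @return `readGeometry` returns a [DeviceGeometry-class];
#'   `writeGeometry` returns `path` invisibly.
#' @export
readGeometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lanes <- list()
  if (!is.null(j$channel_lanes) && length(j$channel_lanes))
    lanes <- lapply(seq_len(nrow(as.matrix(j$channel_lanes))),
                    function(i) as.numeric(as.matrix(j$channel_lanes)[i, ]))
  polys <- list()
  if (!is.null(j$leaf_polygons) && length(j$leaf_polygons)) {
    lp <- j$leaf_polygons
    if (is.array(lp) && length(dim(lp)) == 3L)     # simplified n x v x 2
      lp <- lapply(seq_len(dim(lp)[1L]), function(i) lp[i, , ])
    if (is.matrix(lp)) lp <- list(lp)
    polys <- lapply(lp, function(p) {
      m <- matrix(as.numeric(as.matrix(p)), ncol = 2L)
      colnames(m) <- c("x", "y")
      m
    })
  }
  deviceGeometry(barrier = as.numeric(j$barrier_x_range),
                 forwardSide = j$forward_side %||% "left",
                 lanes = lanes, leafPolygons = polys,
                 pixelSize = as.numeric(j$pixel_size))
}

#' @rdname readGeometry
#' @export
writeGeometry <- function(geometry, path) {
  obj <- list(
    barrier_x_range = geometry@barrier,
    forward_side = geometry@forwardSide,
    channel_lanes = if (length(geometry@lanes))
      do.call(rbind, geometry@lanes) else list(),
    leaf_polygons = lapply(geometry@leafPolygons, function(p)
      unname(as.matrix(p))),
    pixel_size = geometry@pixelSize)
  atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

# Even-odd rule point-in-polygon test, vectorised over points.
# poly: two-column (x, y) matrix; boundary handling is half-open and
# adequate for pixel-centre tests.
pointInPolygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
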