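# Pathology-detection chain: thresholding, colocalisation,
# connected-component fragment extraction, area filtering, length
# measurement and CFSE classification.

#' Construct segmentation parameters
#'
#' @param thresholdMethod `"otsu"` (per-image Otsu) or `"manual"`.
#'   Published thresholds do not exist for this assay (they were tuned
#'   manually per experiment), so both routes are supported and the applied
#'   level is always recorded.
#' @param manualLevel named numeric vector of manual levels per channel,
#'   e.g. `c(psyn = 1900, tubulin = 600, cfse = 800)`.
#' @param minArea minimum fragment area in um^2; objects with area below
#'   this are excluded (default 8, the conventional cutoff for suppressing
#'   non-specific puncta). Objects of exactly `minArea` are kept.
#' @param colocFraction minimum fraction of a fragment's pixels that must
#'   overlap the dilated neurite mask (default 0.5, `>=` comparison).
#' @param dilationRadius dilation radius in px applied to the neurite mask
#'   before overlap testing (default 1; absorbs ~1 px chromatic or
#'   registration offset).
#' @param connectivity 4 or 8 (default 8, keeping thin diagonal fragments
#'   intact).
#' @param cfseFraction minimum overlap fraction with the CFSE mask for a
#'   fragment to be called CFSE-positive (default 0.5, `>=`).
#' @return a [SegmentationParams-class] object.
#' @export
segmentationParams <- function(thresholdMethod = "otsu",
                               manualLevel = c(psyn = NA_real_,
                                               tubulin = NA_real_,
                                               cfse = NA_real_),
                               minArea = 8, colocFraction = 0.5,
                               dilationRadius = 1L, connectivity = 8L,
                               cfseFraction = 0.5) {
  new("SegmentationParams", thresholdMethod = thresholdMethod,
      manualLevel = manualLevel, minArea = as.numeric(minArea),
      colocFraction = as.numeric(colocFraction),
      dilationRadius = as.integer(dilationRadius),
      connectivity = as.integer(connectivity),
      cfseFraction = as.numeric(cfseFraction))
}

#' Threshold a channel image to a binary mask
#'
#' The mask is true where intensity is greater than or equal to the applied
#' threshold. With `method = "otsu"` the level maximises the inter-class
#' variance of the intensity histogram (computed via [EBImage::otsu()]);
#' the applied level is then the smallest observed intensity above it, so
#' the `>=` contract holds exactly. With `method = "manual"` the supplied
#' level is applied directly. The applied level is attached as attribute
#' `"threshold"` so every run is auditable.
#'
#' @param image a [FieldImage-class] or a plain numeric matrix.
#' @param params a [SegmentationParams-class]; or pass `method` / `level`
#'   directly.
#' @param method overrides the params' method if given.
#' @param level manual threshold level (intensity units of `image`).
#' @return logical matrix with attribute `"threshold"` (the applied level).
#'   A constant image under Otsu yields an empty mask with a warning.
#' @examples
#' m <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
#' thresholdMask(m, method = "manual", level = 100)
#' @export
thresholdMask <- function(image, params = segmentationParams(),
                          method = NULL, level = NULL) {
  dat <- if (is(image, "FieldImage")) image@data else image
  stopifnot(is.matrix(dat), length(dat) >= 1L)
  ch <- if (is(image, "FieldImage")) image@channel else "psyn"
  method <- method %||% params@thresholdMethod
  if (method == "manual") {
    lvl <- level %||% unname(params@manualLevel[ch])
    if (is.null(lvl) || is.na(lvl))
      stop("manual threshold level required for channel '", ch, "'")
    mask <- dat >= lvl
    attr(mask, "threshold") <- as.numeric(lvl)
    return(mask)
  }
  rng <- range(dat)
  if (rng[1L] == rng[2L]) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    mask <- matrix(FALSE, nrow(dat), ncol(dat))
    attr(mask, "threshold") <- Inf
    return(mask)
  }
  hi <- max(rng[2L], 1)
  lev <- min(65536L, max(256L, 2L^ceiling(log2(hi + 1))))
  thr <- EBImage::otsu(dat / hi, range = c(0, 1), levels = lev) * hi
  vals <- sort(unique(as.vector(dat)))
  above <- vals[vals > thr]
  applied <- if (length(above)) above[1L] else Inf
  mask <- dat >= applied
  attr(mask, "threshold") <- applied
  mask
}

# Per-component overlap fraction with a reference mask.
# labels: integer label matrix; ref: logical matrix.
overlapFraction <- function(labels, ref, nComp) {
  if (nComp == 0L) return(numeric(0))
  sizes <- tabulate(labels[labels > 0L], nbins = nComp)
  inter <- tabulate(labels[labels > 0L & ref], nbins = nComp)
  inter / sizes
}

#' Extract pathology fragments from thresholded masks
#'
#' Connected components of the pSyn mask are kept when (a) the fraction of
#' their pixels overlapping the dilated neurite (tubulin) mask is at least
#' `colocFraction`, and (b) their area is at least `minArea` um^2. The
#' minimum area is converted to a pixel count by ceiling so no object below
#' `minArea` can ever pass. Kept components become fragment records with
#' area, skeleton-geodesic length, centroid, chamber and
#' distance-to-barrier.
#'
#' @param psynMask logical matrix (from [thresholdMask()] on the pSyn
#'   channel) or a [FieldImage-class] to threshold with `params`.
#' @param tubulinMask logical matrix for the neurite channel (same shape).
#' @param geometry a [DeviceGeometry-class].
#' @param params a [SegmentationParams-class].
#' @param offset numeric(2) device-coordinate (x, y) origin of the masks in
#'   um (taken from the image when `psynMask` is a [FieldImage-class]).
#' @param pixelSize um/px of the masks; defaults to `pixelSize(geometry)`.
#' @param imageId identifier recorded on each fragment.
#' @param computeLength logical; skip the skeleton length (faster) if FALSE.
#' @return a [S4Vectors::DataFrame] with one row per kept fragment:
#'   `id`, `imageId`, `chamber`, `area_um2`, `length_um`, `centroid_x_um`,
#'   `centroid_y_um`, `distance_um`, `on_neurite`, `cfse_status`
#'   (initially `"unevaluated"`) and a list column `pixels` of linear pixel
#'   indices into the mask.
#' @export
extractFragments <- function(psynMask, tubulinMask, geometry,
                             params = segmentationParams(),
                             offset = c(0, 0),
                             pixelSize = NULL, imageId = "field",
                             computeLength = TRUE) {
  if (is(psynMask, "FieldImage")) {
    offset <- psynMask@offset
    pixelSize <- pixelSize %||% psynMask@pixelSize
    imageId <- psynMask@imageId
    psynMask <- thresholdMask(psynMask, params)
  }
  if (is(tubulinMask, "FieldImage"))
    tubulinMask <- thresholdMask(tubulinMask, params)
  px <- pixelSize %||% geometry@pixelSize
  if (!identical(dim(psynMask), dim(tubulinMask)))
    stop("psyn and tubulin masks must share dimensions")
  labels <- .label_components(psynMask, params@connectivity)
  nComp <- max(labels)
  neur <- tubulinMask
  if (params@dilationRadius > 0L && any(neur))
    neur <- EBImage::dilate(
      neur, EBImage::makeBrush(2L * params@dilationRadius + 1L, "box")) > 0
  frac <- overlapFraction(labels, neur, nComp)
  minPx <- as.integer(ceiling(params@minArea / px^2 - 1e-9))
  sizes <- tabulate(labels[labels > 0L], nbins = nComp)
  keep <- which(frac >= params@colocFraction & sizes >= minPx)
  emptyOut <- function() S4Vectors::DataFrame(
    id = integer(0), imageId = character(0), chamber = character(0),
    area_um2 = numeric(0), length_um = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    distance_um = numeric(0), on_neurite = logical(0),
    cfse_status = character(0), pixels = S4Vectors::SimpleList())
  if (!length(keep)) return(emptyOut())
  nr <- nrow(psynMask)
  fg <- which(labels > 0L)
  lab <- labels[fg]
  ord <- order(lab)
  fg <- fg[ord]; lab <- lab[ord]
  bounds <- c(0L, cumsum(sizes))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    comp <- keep[k]
    pix <- fg[(bounds[comp] + 1L):bounds[comp + 1L]]
    yy <- ((pix - 1L) %% nr) + 1L
    xx <- ((pix - 1L) %/% nr) + 1L
    cx <- offset[1L] + (mean(xx) - 0.5) * px
    cy <- offset[2L] + (mean(yy) - 0.5) * px
    len <- NA_real_
    if (computeLength) {
      sub <- matrix(FALSE, max(yy) - min(yy) + 3L, max(xx) - min(xx) + 3L)
      sub[cbind(yy - min(yy) + 2L, xx - min(xx) + 2L)] <- TRUE
      len <- fragmentLengthFromMask(sub, px)
    }
    out[[k]] <- list(pix = pix, area = length(pix) * px^2,
                     cx = cx, cy = cy, len = len)
  }
  cx <- vapply(out, `[[`, 0, "cx")
  S4Vectors::DataFrame(
    id = seq_along(keep),
    imageId = rep(imageId, length(keep)),
    chamber = chamberSide(cx, geometry),
    area_um2 = vapply(out, `[[`, 0, "area"),
    length_um = vapply(out, `[[`, 0, "len"),
    centroid_x_um = cx,
    centroid_y_um = vapply(out, `[[`, 0, "cy"),
    distance_um = distanceToBarrier(cbind(cx, 0), geometry),
    on_neurite = rep(TRUE, length(keep)),
    cfse_status = rep("unevaluated", length(keep)),
    pixels = S4Vectors::SimpleList(lapply(out, `[[`, "pix")))
}

# Skeletonise a padded binary mask and return the geodesic diameter in um.
fragmentLengthFromMask <- function(mask, pixelSize) {
  if (sum(mask) <= 1L) return(0)
  skel <- .thin_mask(mask)
  d <- .geodesic_diameter(skel)
  if (d < 0) 0 else d * pixelSize
}

#' Length of a fragment along its morphological skeleton
#'
#' The fragment's pixel set is thinned (Zhang-Suen) to a 1-px skeleton and
#' the length is the geodesic diameter of that skeleton: the longest
#' shortest path between any two skeleton pixels, with axial steps of 1 px
#' and diagonal steps of sqrt(2) px, scaled to um. A single-pixel fragment
#' has length 0.
#'
#' @param fragment one row of the [extractFragments()] table, or a logical
#'   mask of the fragment's pixels.
#' @param dim integer(2) mask dimensions (rows, cols) when `fragment` is a
#'   table row.
#' @param pixelSize um/px.
#' @return length in um.
#' @examples
#' m <- matrix(FALSE, 5, 35)
#' m[3, 3:33] <- TRUE  # straight 31-px run
#' fragmentLength(m, pixelSize = 0.5)  # (31 - 1) * 0.5 = 15
#' @export
fragmentLength <- function(fragment, dim = NULL, pixelSize = 1) {
  if (is.matrix(fragment) && is.logical(fragment))
    return(fragmentLengthFromMask(fragment, pixelSize))
  pix <- fragment$pixels[[1L]]
  if (!length(pix)) stop("fragment has no pixels")
  stopifnot(!is.null(dim))
  nr <- dim[1L]
  yy <- ((pix - 1L) %% nr) + 1L
  xx <- ((pix - 1L) %/% nr) + 1L
  sub <- matrix(FALSE, max(yy) - min(yy) + 3L, max(xx) - min(xx) + 3L)
  sub[cbind(yy - min(yy) + 2L, xx - min(xx) + 2L)] <- TRUE
  fragmentLengthFromMask(sub, pixelSize)
}

#' Classify fragments as CFSE-positive or CFSE-negative
#'
#' A reverse-chamber fragment within the evaluation band is called
#' `"positive"` when the fraction of its pixels overlapping the CFSE mask
#' is at least `cfseFraction` (default 0.5), else `"negative"`.
#' CFSE-positive pathology was carried there inside forward-originating
#' axons (transported); CFSE-negative pathology sits in reverse-native
#' neurites (transferred). Because the CFSE signal fades with distance from
#' the microchannels, fragments outside the evaluation band are marked
#' `"unevaluated"` and excluded from transfer statistics.
#'
#' @param fragments table from [extractFragments()].
#' @param cfseMask logical matrix from [thresholdMask()] on the CFSE
#'   channel (same shape as the masks that produced `fragments`).
#' @param params a [SegmentationParams-class].
#' @param band a [RoiBand-class] giving the evaluation band (default
#'   reverse chamber, 0-400 um).
#' @return `fragments` with `cfse_status` filled in.
#' @export
classifyCfse <- function(fragments, cfseMask,
                         params = segmentationParams(),
                         band = roiBand("reverse", c(0, 400))) {
  if (!nrow(fragments)) return(fragments)
  status <- rep("unevaluated", nrow(fragments))
  inBand <- fragments$chamber == band@chamber &
    fragments$distance_um >= band@range[1L] &
    fragments$distance_um <= band@range[2L]
  for (i in which(inBand)) {
    pix <- fragments$pixels[[i]]
    frac <- sum(cfseMask[pix]) / length(pix)
    status[i] <- if (frac >= params@cfseFraction) "positive" else "negative"
  }
  fragments$cfse_status <- status
  fragments
}

#' Write a fragment table to CSV
#'
#' Drops the pixel list column; columns follow the documented schema
#' (`id`, `image_id`, `chamber`, `area_um2`, `length_um`, `centroid_x_um`,
#' `centroid_y_um`, `distance_um`, `on_neurite`, `cfse_status`).
#'
#' @param fragments table from [extractFragments()].
#' @param path output CSV path (written atomically).
#' @return `path`, invisibly.
#' @export
writeFragments <- function(fragments, path) {
  df <- as.data.frame(fragments[, setdiff(colnames(fragments), "pixels")])
  names(df)[names(df) == "imageId"] <- "image_id"
  atomicWrite(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE))
  invisible(path)
}
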