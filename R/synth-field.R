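# Synthetic field rendering: neurite networks, pathology fragments with
# ground truth, CFSE channel.

# Rasterise a polyline (two-column matrix, um, image-local) at a given
# width (um): pixels whose centre lies within width/2 of the (densely
# sampled) centreline. The nearest pixel to every sample point is always
# included so thin lines stay connected. Returns unique linear indices
# into an nr x nc matrix.
rasterPolyline <- function(poly, widthUm, dims, px) {
  nr <- dims[1L]; nc <- dims[2L]
  seg <- diff(poly)
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  if (total == 0) return(integer(0))
  step <- px / 4
  s <- seq(0, total, by = step)
  cum <- c(0, cumsum(lens))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(poly)] <- nrow(poly) - 1L
  frac <- (s - cum[idx]) / pmax(lens[idx], 1e-12)
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  r <- widthUm / 2
  rp <- ceiling(r / px) + 1L
  offs <- expand.grid(dy = -rp:rp, dx = -rp:rp)
  cx <- ceiling(pts[, 1L] / px)
  cy <- ceiling(pts[, 2L] / px)
  nOff <- nrow(offs)
  allx <- rep(cx, each = nOff) + offs$dx
  ally <- rep(cy, each = nOff) + offs$dy
  # exact distance from each candidate pixel centre to its sample point
  dx <- (allx - 0.5) * px - rep(pts[, 1L], each = nOff)
  dy <- (ally - 0.5) * px - rep(pts[, 2L], each = nOff)
  near <- sqrt(dx^2 + dy^2) <= pmax(r, px * 0.71)
  ok <- near & allx >= 1L & allx <= nc & ally >= 1L & ally <= nr
  unique((allx[ok] - 1L) * nr + ally[ok])
}

# Rasterise a straight bar of given centre (um), orientation, length and
# width (um). Returns linear pixel indices.
rasterBar <- function(center, angle, lengthUm, widthUm, dims, px) {
  half <- lengthUm / 2
  u <- c(cos(angle), sin(angle))
  poly <- rbind(center - half * u, center + half * u)
  rasterPolyline(poly, widthUm, dims, px)
}

# Add a Gaussian splat to an image (in place semantics via return).
addGaussianSpot <- function(img, centerUm, amp, sigmaUm, px) {
  nr <- nrow(img); nc <- ncol(img)
  rp <- ceiling(3 * sigmaUm / px)
  cx <- ceiling(centerUm[1L] / px); cy <- ceiling(centerUm[2L] / px)
  xs <- max(1L, cx - rp):min(nc, cx + rp)
  ys <- max(1L, cy - rp):min(nr, cy + rp)
  if (!length(xs) || !length(ys)) return(img)
  dx <- (xs - 0.5) * px - centerUm[1L]
  dy <- (ys - 0.5) * px - centerUm[2L]
  g <- amp * exp(-(outer(dy^2, dx^2, `+`)) / (2 * sigmaUm^2))
  img[ys, xs] <- img[ys, xs] + g
  img
}

# Apply the camera model: optical blur, baseline, shot noise, read noise.
renderImage <- function(signal, cfg) {
  img <- signal
  if (cfg@blurSigma > 0)
    img <- EBImage::gblur(img, sigma = cfg@blurSigma)
  img <- img + cfg@baseline
  img[img < 0] <- 0
  if (cfg@poissonNoise) {
    img[] <- rpois(length(img), lambda = as.vector(img))
  }
  if (cfg@readNoiseSd > 0)
    img <- img + rnorm(length(img), 0, cfg@readNoiseSd)
  img[img < 0] <- 0
  round(img)
}

#' Generate a synthetic neurite field (beta-III-tubulin channel)
#'
#' Neurites are persistent random walks rasterised at 1-3 px width;
#' somata are bright discs. The skeleton truth (polylines, per-neurite
#' pixel sets, origin flags) is recorded for downstream generators.
#'
#' @param cfg a [SynthConfig-class].
#' @param geometry a [DeviceGeometry-class].
#' @param offset device-coordinate (x, y) origin of the field in um;
#'   default places the field in the forward chamber with its near edge
#'   400 um from the barrier.
#' @param imageId identifier.
#' @param seed random seed for this field (derived from `cfg@seed` by
#'   default).
#' @return list with `image` (a tubulin [FieldImage-class]) and `truth`:
#'   `neurites` (list of `polyline` um image-local, `widthPx`,
#'   `forwardOrigin`, `pixels`), `skeletonPixels` (all neurite pixel
#'   indices) and `totalLength` (um of polyline).
#' @export
generateNeuriteField <- function(cfg, geometry,
                                 offset = c(geometry@barrier[1L] - 400 -
                                              cfg@fieldSize[1L],
                                            -cfg@fieldSize[2L] / 2),
                                 imageId = "synth_field",
                                 seed = childSeed(cfg@seed, 101L)) {
  px <- cfg@pixelSize
  fs <- cfg@fieldSize
  dims <- c(ceiling(fs[2L] / px), ceiling(fs[1L] / px))
  withSeed(seed, {
    neurites <- list()
    n <- round(cfg@neuriteCount)
    if (n > 0) {
      for (i in seq_len(n)) {
        start <- runif(2) * fs
        heading <- runif(1, 0, 2 * pi)
        pts <- matrix(start, ncol = 2)
        maxSteps <- ceiling(2.5 * sqrt(sum(fs^2)) / cfg@neuriteStep)
        for (s in seq_len(maxSteps)) {
          heading <- heading + rnorm(1, 0, cfg@neuriteWobble)
          nxt <- pts[nrow(pts), ] +
            cfg@neuriteStep * c(cos(heading), sin(heading))
          pts <- rbind(pts, nxt)
          if (nxt[1L] < -5 || nxt[1L] > fs[1L] + 5 ||
              nxt[2L] < -5 || nxt[2L] > fs[2L] + 5) break
        }
        widthPx <- runif(1, cfg@neuriteWidthPx[1L], cfg@neuriteWidthPx[2L])
        neurites[[i]] <- list(
          polyline = pts, widthPx = widthPx,
          forwardOrigin = runif(1) < cfg@forwardFraction,
          pixels = rasterPolyline(pts, widthPx * px, dims, px))
      }
    }
    signal <- matrix(0, dims[1L], dims[2L])
    for (nr in neurites) signal[nr$pixels] <- cfg@neuriteIntensity
    nSoma <- rpois(1, cfg@somaDensity * prod(fs) / 1e6 / 0.25)
    somata <- if (nSoma > 0)
      matrix(runif(2 * nSoma) * rep(fs, each = nSoma), ncol = 2)
    else matrix(0, 0, 2)
    somaPixels <- integer(0)
    for (i in seq_len(nSoma)) {
      pix <- rasterBar(somata[i, ], 0, 1, 10, dims, px)
      somaPixels <- c(somaPixels, pix)
      signal[pix] <- pmax(signal[pix], cfg@neuriteIntensity * 1.3)
    }
    img <- renderImage(signal, cfg)
    list(
      image = fieldImage(img, "tubulin", px, offset, imageId),
      truth = list(
        neurites = neurites,
        somata = somata,
        somaPixels = unique(somaPixels),
        skeletonPixels = unique(unlist(lapply(neurites, `[[`, "pixels"))),
        totalLength = sum(vapply(neurites, function(nr)
          sum(sqrt(rowSums(diff(nr$polyline)^2))), 0)),
        offset = offset, dims = dims))
  })
}

# Pick a random point + tangent on a neurite polyline, weighted by length.
samplePolylinePoint <- function(neurites, which) {
  nr <- neurites[[which]]
  seg <- diff(nr$polyline)
  lens <- sqrt(rowSums(seg^2))
  u <- runif(1, 0, sum(lens))
  i <- findInterval(u, c(0, cumsum(lens)), rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(seg))
  frac <- (u - c(0, cumsum(lens))[i]) / max(lens[i], 1e-12)
  list(point = nr$polyline[i, ] + seg[i, ] * frac,
       angle = atan2(seg[i, 2L], seg[i, 1L]), u = u)
}

# Sub-polyline of arclength L centred at arclength position u (clipped to
# the polyline's ends): the shape of an elongated aggregate that follows
# its axon.
subPolyline <- function(poly, u, lengthUm) {
  seg <- diff(poly)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  a <- max(0, u - lengthUm / 2)
  b <- min(total, u + lengthUm / 2)
  ptAt <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    poly[i, ] + seg[i, ] * ((s - cum[i]) / max(lens[i], 1e-12))
  }
  inner <- which(cum > a & cum < b)
  rbind(ptAt(a), poly[inner, , drop = FALSE], ptAt(b))
}

# Mean realised pixel area (um^2) of a rasterised bar of length L, width W:
# used to convert an expected-area target into an expected fragment count.
expectedBarArea <- function(lengthUm, widthUm, px) {
  # a bar covers roughly (L + W) * max(W, px) of area once rasterised
  (lengthUm + widthUm) * max(widthUm, px)
}

#' Generate the pSer-129 pathology channel with ground truth
#'
#' The expected *detected* pathology (on-neurite fragments of at least
#' 8 um^2) per 0.25 mm^2 follows the linear growth law
#' `max(0, areaSlope * t + areaIntercept) * deviceFactor`; the total number
#' of placed fragments follows the count law, the remainder being
#' deliberate sub-threshold distractors. Off-neurite bars and soft-edged
#' low-intensity background blobs are always added so the colocalisation,
#' area and threshold filters are all exercised. Fragments are elongated
#' bars placed on (and aligned with) the neurite skeleton.
#'
#' @param cfg a [SynthConfig-class].
#' @param field output of [generateNeuriteField()].
#' @param tWeeks weeks since fibril seeding (>= 0).
#' @param geometry a [DeviceGeometry-class] (for distances in truth).
#' @param control logical: an unseeded control field (expected area
#'   `cfg@controlArea`, constant in time).
#' @param seed random seed.
#' @return list with `image` (a pSyn [FieldImage-class]) and `truth`, a
#'   [S4Vectors::DataFrame] of every placed fragment: `pixels`,
#'   `area_um2`, `on_neurite`, `cfse_positive`, `sub_threshold`,
#'   `centroid_x_um`, `centroid_y_um`, `distance_um`; plus attributes
#'   `expected_area_qmm2`, `expected_count_qmm2` and `n_background_blobs`.
#' @export
generatePathologyImage <- function(cfg, field, tWeeks, geometry,
                                   control = FALSE,
                                   seed = childSeed(cfg@seed, 202L,
                                                    round(tWeeks * 1000))) {
  if (tWeeks < 0) stop("tWeeks must be >= 0")
  px <- cfg@pixelSize
  dims <- field$truth$dims
  offset <- field$truth$offset
  fieldQmm <- prod(cfg@fieldSize) / 1e6 / 0.25
  expArea <- if (control) cfg@controlArea
             else max(0, cfg@areaSlope * tWeeks + cfg@areaIntercept)
  expArea <- expArea * cfg@deviceFactor
  expCount <- if (control) cfg@controlArea / 6
              else max(0, cfg@countSlope * tWeeks + cfg@countIntercept)
  expCount <- expCount * cfg@deviceFactor
  neurites <- field$truth$neurites
  haveNeurites <- length(neurites) > 0L
  withSeed(seed, {
    signal <- matrix(0, dims[1L], dims[2L])
    frags <- list()
    # --- detected-class fragments on neurites, area law ---
    loBig <- max(cfg@fragmentLengthRange[1L],
                 8 / max(cfg@fragmentWidth, px) + 2)
    hiBig <- max(cfg@fragmentLengthRange[2L], loBig + 1)
    meanBig <- expectedBarArea((loBig + hiBig) / 2, cfg@fragmentWidth, px)
    targetField <- expArea * fieldQmm
    nBig <- if (haveNeurites && targetField > 0)
      rpois(1, targetField / meanBig) else 0L
    fwdFlags <- vapply(neurites, `[[`, NA, "forwardOrigin")
    lens <- vapply(neurites, function(nr)
      sum(sqrt(rowSums(diff(nr$polyline)^2))), 0)
    pickNeurite <- function(wantForward) {
      pool <- if (is.na(wantForward)) seq_along(neurites)
              else which(fwdFlags == wantForward)
      if (!length(pool)) pool <- seq_along(neurites)
      if (length(pool) == 1L) pool else
        sample(pool, 1L, prob = lens[pool] + 1e-9)
    }
    # occupancy map keeps placed fragments separated by >= 1 px so
    # distinct aggregates stay distinct after segmentation
    occ <- matrix(FALSE, dims[1L], dims[2L])
    nrr <- dims[1L]
    touches <- function(pix) {
      yy <- ((pix - 1L) %% nrr) + 1L
      xx <- ((pix - 1L) %/% nrr) + 1L
      for (dy in -2:2) for (dx in -2:2) {
        y2 <- yy + dy; x2 <- xx + dx
        ok <- y2 >= 1L & y2 <= dims[1L] & x2 >= 1L & x2 <= dims[2L]
        if (any(occ[(x2[ok] - 1L) * nrr + y2[ok]])) return(TRUE)
      }
      FALSE
    }
    placeOn <- function(lengthUm, wantForward = NA) {
      for (try in 1:20) {
        ni <- pickNeurite(wantForward)
        sp <- samplePolylinePoint(neurites, ni)
        shape <- subPolyline(neurites[[ni]]$polyline, sp$u, lengthUm)
        pix <- rasterPolyline(shape, cfg@fragmentWidth, dims, px)
        if (!length(pix) || touches(pix)) next
        occ[pix] <<- TRUE
        return(list(pix = pix, cfse = neurites[[ni]]$forwardOrigin,
                    center = sp$point))
      }
      NULL
    }
    # Draw the detected-class fragment lengths up front, then partition
    # them so the CFSE-negative (reverse-native, i.e. transferred) share
    # of the planned area matches transferFraction as closely as the
    # granularity allows (largest-first best-fit).
    bigLens <- runif(nBig, loBig, hiBig)
    # with no transfer, pathology is strictly transported: it sits only on
    # forward-originating neurites
    wantFwd <- rep(if (any(!fwdFlags)) TRUE else NA, nBig)
    if (cfg@transferFraction > 0 && nBig > 0) {
      aHat <- expectedBarArea(bigLens, cfg@fragmentWidth, px)
      target <- cfg@transferFraction * sum(aHat)
      negSum <- 0
      wantFwd <- rep(TRUE, nBig)
      for (i in order(aHat, decreasing = TRUE)) {
        if (negSum + aHat[i] <= target + min(aHat) / 2) {
          wantFwd[i] <- FALSE
          negSum <- negSum + aHat[i]
        }
      }
    }
    for (i in seq_len(nBig)) {
      pl <- placeOn(bigLens[i], wantFwd[i])
      if (is.null(pl)) next
      frags[[length(frags) + 1L]] <-
        list(pix = pl$pix, on = TRUE, cfse = pl$cfse, center = pl$center)
    }
    # --- sub-threshold on-neurite distractors, count law remainder ---
    nSub <- max(3L, rpois(1, max(0, expCount * fieldQmm - nBig)))
    if (haveNeurites) {
      for (i in seq_len(nSub)) {
        pl <- placeOn(runif(1, cfg@distractorLengthRange[1L],
                            cfg@distractorLengthRange[2L]))
        if (is.null(pl)) next
        frags[[length(frags) + 1L]] <-
          list(pix = pl$pix, on = TRUE, cfse = pl$cfse, center = pl$center)
      }
    }
    # --- off-neurite bars (colocalisation-filter distractors) ---
    avoid <- matrix(FALSE, dims[1L], dims[2L])
    avoid[field$truth$skeletonPixels] <- TRUE
    avoid[field$truth$somaPixels] <- TRUE
    if (any(avoid)) {
      grow <- ceiling(4 / px)
      avoid <- EBImage::dilate(
        avoid, EBImage::makeBrush(2L * grow + 1L, "disc")) > 0
    }
    nOff <- round(cfg@offNeuriteBarCount)
    tries <- 0L
    placed <- 0L
    while (placed < nOff && tries < 200L) {
      tries <- tries + 1L
      center <- runif(2) * cfg@fieldSize
      pix <- rasterBar(center, runif(1, 0, pi),
                       runif(1, loBig, min(hiBig, 15)),
                       cfg@fragmentWidth, dims, px)
      if (!length(pix) || any(avoid[pix]) || touches(pix)) next
      occ[pix] <- TRUE
      placed <- placed + 1L
      frags[[length(frags) + 1L]] <-
        list(pix = pix, on = FALSE, cfse = FALSE, center = center)
    }
    # --- soft-edged non-specific background blobs (below threshold) ---
    nBlob <- rpois(1, cfg@backgroundBlobDensity * fieldQmm)
    for (i in seq_len(nBlob)) {
      signal <- addGaussianSpot(signal, runif(2) * cfg@fieldSize,
                                cfg@backgroundBlobIntensity,
                                cfg@backgroundBlobSigma, px)
    }
    for (fr in frags) signal[fr$pix] <- cfg@fragmentIntensity
    img <- renderImage(signal, cfg)
    nr <- dims[1L]
    truth <- if (length(frags)) {
      cx <- vapply(frags, function(f)
        offset[1L] + (mean(((f$pix - 1L) %/% nr) + 1L) - 0.5) * px, 0)
      cy <- vapply(frags, function(f)
        offset[2L] + (mean(((f$pix - 1L) %% nr) + 1L) - 0.5) * px, 0)
      area <- vapply(frags, function(f) length(f$pix) * px^2, 0)
      S4Vectors::DataFrame(
        id = seq_along(frags),
        pixels = S4Vectors::SimpleList(lapply(frags, `[[`, "pix")),
        area_um2 = area,
        on_neurite = vapply(frags, `[[`, NA, "on"),
        cfse_positive = vapply(frags, `[[`, NA, "cfse"),
        sub_threshold = area < 8,
        centroid_x_um = cx, centroid_y_um = cy,
        distance_um = distanceToBarrier(cbind(cx, 0), geometry))
    } else S4Vectors::DataFrame(
      id = integer(0), pixels = S4Vectors::SimpleList(),
      area_um2 = numeric(0), on_neurite = logical(0),
      cfse_positive = logical(0), sub_threshold = logical(0),
      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
      distance_um = numeric(0))
    S4Vectors::metadata(truth) <- list(
      expected_area_qmm2 = expArea, expected_count_qmm2 = expCount,
      n_background_blobs = nBlob, t_weeks = tWeeks)
    list(image = fieldImage(img, "psyn", px, offset,
                            paste0(field$image@imageId, "_psyn")),
         truth = truth)
  })
}

#' Generate the CFSE channel for a field
#'
#' CFSE dye applied to the forward chamber labels forward-originating
#' axons; its intensity falls with distance from the microchannel barrier
#' (linearly to zero at `cfseScale` um by default, or exponentially).
#' Reverse-native neurites receive no CFSE signal.
#'
#' @param cfg a [SynthConfig-class].
#' @param field output of [generateNeuriteField()].
#' @param geometry a [DeviceGeometry-class].
#' @param seed random seed.
#' @return a CFSE [FieldImage-class].
#' @export
generateCfseChannel <- function(cfg, field, geometry,
                                seed = childSeed(cfg@seed, 303L)) {
  px <- cfg@pixelSize
  dims <- field$truth$dims
  offset <- field$truth$offset
  nr <- dims[1L]
  withSeed(seed, {
    signal <- matrix(0, dims[1L], dims[2L])
    for (ne in field$truth$neurites) {
      if (!ne$forwardOrigin) next
      pix <- rasterPolyline(ne$polyline, (ne$widthPx + 1) * px, dims, px)
      if (!length(pix)) next
      xs <- offset[1L] + ((((pix - 1L) %/% nr) + 1L) - 0.5) * px
      d <- distanceToBarrier(cbind(xs, 0), geometry)
      decay <- switch(cfg@cfseDecay,
        linear = pmax(0, 1 - d / cfg@cfseScale),
        exponential = exp(-d / cfg@cfseScale))
      signal[pix] <- pmax(signal[pix], cfg@cfseMax * decay)
    }
    img <- renderImage(signal, cfg)
    fieldImage(img, "cfse", px, offset,
               paste0(field$image@imageId, "_cfse"))
  })
}
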