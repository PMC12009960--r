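# The pathology-detection chain: thresholding, colocalisation,
# connected components, area filter, length, CFSE classification.

pxGeom <- deviceGeometry(pixelSize = 0.5)

# Build a mask pair and params for synthetic predicate tests.
blankPair <- function(nr = 20, nc = 20) {
  list(psyn = matrix(FALSE, nr, nc), tub = matrix(FALSE, nr, nc))
}

test_that("manual and Otsu thresholding follow their contracts", {
  m <- matrix(10, 4, 4)
  msk <- thresholdMask(m, method = "manual", level = 5)
  expect_true(all(msk))
  expect_equal(attr(msk, "threshold"), 5)
  expect_false(any(thresholdMask(m, method = "manual", level = 10.5)))
  # boundary: >= keeps equality
  expect_true(all(thresholdMask(m, method = "manual", level = 10)))
  expect_warning(msk0 <- thresholdMask(matrix(0, 5, 5), method = "otsu"),
                 "constant")
  expect_false(any(msk0))
})

test_that("Otsu separates a two-population image like exhaustive search", {
  set.seed(8)
  for (rep in 1:5) {
    lo <- sample(5:40, 1); hi <- sample(120:250, 1)
    vals <- sample(c(rep(lo, 50), rep(hi, 50)))
    m <- matrix(vals, 10, 10)
    msk <- thresholdMask(m, method = "otsu")
    thr <- attr(msk, "threshold")
    expect_gt(thr, lo); expect_lte(thr, hi)
    cut <- oracleOtsuPartition(m)
    expect_identical(as.vector(msk), as.vector(m > cut))
    expect_equal(sum(msk), 50)
  }
})

test_that("fragments are filtered by colocalisation then area", {
  pr <- blankPair(30, 40)
  px <- 0.5  # 1 px = 0.25 um^2
  # three on-neurite components of 5, 8 and 12 um^2 (20, 32, 48 px)
  pr$psyn[2:5, 2:6] <- TRUE            # 20 px = 5 um^2
  pr$psyn[10:13, 10:17] <- TRUE        # 32 px = 8 um^2
  pr$psyn[20:25, 20:27] <- TRUE        # 48 px = 12 um^2
  pr$tub[, ] <- TRUE
  p <- segmentationParams(minArea = 8)
  fr <- extractFragments(pr$psyn, pr$tub, pxGeom, p, pixelSize = px)
  expect_equal(sort(fr$area_um2), c(8, 12))  # exactly 8 um^2 is kept
  # a component with no tubulin overlap is dropped
  pr$tub[, ] <- FALSE
  fr0 <- extractFragments(pr$psyn, pr$tub, pxGeom, p, pixelSize = px)
  expect_equal(nrow(fr0), 0)
  # overlap boundary: 40% dropped, 50% kept (with dilation disabled)
  pr2 <- blankPair(12, 22)
  pr2$psyn[2:11, 2:11] <- TRUE               # 100 px component
  pr2$tub[2:11, 2:5] <- TRUE                 # covers 40 px
  p2 <- segmentationParams(minArea = 1, dilationRadius = 0L)
  expect_equal(nrow(extractFragments(pr2$psyn, pr2$tub, pxGeom, p2,
                                     pixelSize = px)), 0)
  pr2$tub[2:11, 2:6] <- TRUE                 # covers 50 px
  expect_equal(nrow(extractFragments(pr2$psyn, pr2$tub, pxGeom, p2,
                                     pixelSize = px)), 1)
  expect_error(extractFragments(matrix(FALSE, 3, 3), matrix(FALSE, 4, 4),
                                pxGeom, p), "dimensions")
})

test_that("extraction matches the flood-fill oracle on random images", {
  set.seed(21)
  for (rep in 1:12) {
    nr <- sample(16:64, 1); nc <- sample(16:64, 1)
    psyn <- matrix(runif(nr * nc) < 0.25, nr, nc)
    tub <- matrix(runif(nr * nc) < 0.4, nr, nc)
    px <- sample(c(0.325, 0.5, 1), 1)
    p <- segmentationParams(minArea = sample(c(2, 8), 1),
                            colocFraction = sample(c(0.3, 0.5), 1),
                            dilationRadius = sample(0:1, 1),
                            connectivity = sample(c(4L, 8L), 1))
    fr <- extractFragments(psyn, tub, pxGeom, p, pixelSize = px,
                           computeLength = FALSE)
    got <- lapply(fr$pixels, sort)
    want <- oracleExtract(psyn, tub, p, px)
    expect_equal(length(got), length(want))
    key <- function(l) sort(vapply(l, function(v) paste(v, collapse = ","),
                                   ""))
    expect_identical(key(got), key(want))
  }
})

test_that("labelling agrees with EBImage on 4-connectivity", {
  set.seed(5)
  m <- matrix(runif(40 * 40) < 0.3, 40, 40)
  ours <- synspread:::.label_components(m, 4L)
  eb <- EBImage::bwlabel(m)
  # same partition up to label names
  expect_equal(max(ours), max(eb))
  expect_true(all(tapply(eb[m], ours[m], function(v)
    length(unique(v))) == 1))
})

test_that("raising minArea or colocFraction never adds fragments", {
  set.seed(33)
  for (rep in 1:6) {
    psyn <- matrix(runif(48 * 48) < 0.3, 48, 48)
    tub <- matrix(runif(48 * 48) < 0.5, 48, 48)
    counts <- vapply(c(1, 2, 4, 8, 16), function(a)
      nrow(extractFragments(psyn, tub, pxGeom,
                            segmentationParams(minArea = a),
                            pixelSize = 0.5, computeLength = FALSE)), 0L)
    expect_true(all(diff(counts) <= 0))
    counts2 <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(fr)
      nrow(extractFragments(psyn, tub, pxGeom,
                            segmentationParams(minArea = 2,
                                               colocFraction = fr),
                            pixelSize = 0.5, computeLength = FALSE)), 0L)
    expect_true(all(diff(counts2) <= 0))
  }
})

test_that("fragment length is the geodesic diameter of the skeleton", {
  m <- matrix(FALSE, 5, 35); m[3, 3:33] <- TRUE
  expect_equal(fragmentLength(m, pixelSize = 0.5), 15)  # (31 - 1) * 0.5
  expect_equal(fragmentLength(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2),
                              pixelSize = 1), 0)
  # L-shaped and random thin skeletons against the Dijkstra oracle
  L <- matrix(FALSE, 20, 20); L[5, 5:15] <- TRUE; L[5:15, 15] <- TRUE
  expect_equal(fragmentLength(L, pixelSize = 1), oracleGeodesic(L))
  set.seed(12)
  for (rep in 1:8) {
    sk <- matrix(FALSE, 15, 15)
    y <- 8; x <- 2; sk[y, x] <- TRUE
    for (s in 1:25) {
      st <- sample(1:8, 1)
      y <- min(15, max(1, y + c(-1, 1, 0, 0, -1, -1, 1, 1)[st]))
      x <- min(15, max(1, x + c(0, 0, -1, 1, -1, 1, -1, 1)[st]))
      sk[y, x] <- TRUE
    }
    expect_equal(synspread:::.geodesic_diameter(sk), oracleGeodesic(sk),
                 tolerance = 1e-12)
  }
})

test_that("CFSE classification applies the overlap rule within the band", {
  g <- deviceGeometry(pixelSize = 0.5)
  pr <- blankPair(10, 40)
  pr$psyn[2:5, 2:9] <- TRUE   # 32 px
  pr$tub[, ] <- TRUE
  p <- segmentationParams()
  # image sits in the reverse chamber at the barrier edge
  fr <- extractFragments(pr$psyn, pr$tub, g, p, offset = c(1000, 0),
                         pixelSize = 0.5)
  full <- matrix(TRUE, 10, 40)
  none <- matrix(FALSE, 10, 40)
  expect_equal(classifyCfse(fr, full, p)$cfse_status, "positive")
  expect_equal(classifyCfse(fr, none, p)$cfse_status, "negative")
  # exactly 50% overlap is positive (>= boundary)
  half <- none; half[, 2:5] <- TRUE  # covers 16 of the 32 px
  expect_equal(classifyCfse(fr, half, p)$cfse_status, "positive")
  under <- none; under[, 2:4] <- TRUE
  expect_equal(classifyCfse(fr, under, p)$cfse_status, "negative")
  # outside the 0-400 um band the status stays unevaluated
  frFar <- extractFragments(pr$psyn, pr$tub, g, p, offset = c(1500, 0),
                            pixelSize = 0.5)
  expect_equal(classifyCfse(frFar, full, p)$cfse_status, "unevaluated")
  # forward-chamber fragments are never evaluated either
  frFwd <- extractFragments(pr$psyn, pr$tub, g, p, offset = c(-100, 0),
                            pixelSize = 0.5)
  expect_equal(classifyCfse(frFwd, full, p)$cfse_status, "unevaluated")
})

test_that("noise-free synthetic fields are recovered exactly", {
  g <- deviceGeometry(pixelSize = 0.65)
  p <- studyParams()
  for (s in c(2, 5, 9)) {
    cfg <- synthConfig(seed = s, poissonNoise = FALSE, readNoiseSd = 0)
    fld <- generateNeuriteField(cfg, g)
    pat <- generatePathologyImage(cfg, fld, 8, g)
    tr <- pat$truth
    fr <- extractFragments(thresholdMask(pat$image, p),
                           thresholdMask(fld$image, p), g, p,
                           offset = pat$image@offset, pixelSize = 0.65,
                           computeLength = FALSE)
    det <- which(tr$on_neurite & !tr$sub_threshold)
    expect_equal(nrow(fr), length(det))
    # every truth object is matched with IoU >= 0.7, nothing else reported
    matched <- logical(nrow(fr))
    for (i in det) {
      pix <- tr$pixels[[i]]
      ious <- vapply(seq_len(nrow(fr)), function(j) {
        inter <- length(intersect(pix, fr$pixels[[j]]))
        inter / length(union(pix, fr$pixels[[j]]))
      }, 0)
      expect_gte(max(ious), 0.7)
      matched[which.max(ious)] <- TRUE
    }
    expect_true(all(matched))
  }
})
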