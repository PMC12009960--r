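# The synthetic-microscopy generator: determinism, truth consistency and
# the statistical structure the downstream analysis assumes.

smallCfg <- function(seed = 1, ...) {
  synthConfig(seed = seed, fieldSize = c(96, 96), neuriteCount = 12, ...)
}
geomPx <- deviceGeometry(pixelSize = 0.65)

test_that("identical config gives bit-identical images and truth", {
  for (build in list(
    function(s) {
      f <- generateNeuriteField(smallCfg(s), geomPx)
      list(imageData(f$image), f$truth$skeletonPixels)
    },
    function(s) {
      f <- generateNeuriteField(smallCfg(s), geomPx)
      p <- generatePathologyImage(smallCfg(s), f, 8, geomPx)
      list(imageData(p$image), as.list(p$truth$pixels))
    },
    function(s) {
      m <- generateChannelTimelapse(smallCfg(s, duration = 30), geomPx,
                                    data.frame(x0 = 500, v = -1))
      list(m$movie, m$truth)
    })) {
    expect_identical(build(7), build(7))
  }
})

test_that("empty configurations degrade gracefully", {
  cfg <- smallCfg(2, neuriteCount = 0)
  f <- generateNeuriteField(cfg, geomPx)
  expect_length(f$truth$neurites, 0)
  expect_equal(f$truth$totalLength, 0)
  m <- generateChannelTimelapse(smallCfg(2, duration = 30), geomPx, NULL)
  expect_length(m$truth, 0)
})

test_that("neurite truth length is consistent with the walk parameters", {
  cfg <- synthConfig(5, fieldSize = c(200, 200), neuriteCount = 50)
  f <- generateNeuriteField(cfg, geomPx)
  perNeurite <- vapply(f$truth$neurites, function(nr)
    sum(sqrt(rowSums(diff(nr$polyline)^2))), 0)
  expect_length(perNeurite, 50)
  # every polyline is a chain of steps of the configured length
  for (nr in f$truth$neurites[1:5]) {
    steps <- sqrt(rowSums(diff(nr$polyline)^2))
    expect_true(all(abs(steps - cfg@neuriteStep) < 1e-9))
  }
  expect_equal(sum(perNeurite), f$truth$totalLength)
})

test_that("pathology truth follows the growth law and its truncation", {
  cfg <- smallCfg(3)
  f <- generateNeuriteField(cfg, geomPx)
  expect_error(generatePathologyImage(cfg, f, -1, geomPx), "tWeeks")
  # at t = 0 the expected area is truncated to zero
  p0 <- generatePathologyImage(cfg, f, 0, geomPx)
  expect_equal(S4Vectors::metadata(p0$truth)$expected_area_qmm2, 0)
  expect_equal(sum(p0$truth$area_um2[p0$truth$on_neurite &
                                       !p0$truth$sub_threshold]), 0)
  # at t = 4.4 weeks the default law gives 53.828 * 4.4 - 137.706
  p44 <- generatePathologyImage(cfg, f, 4.4, geomPx)
  expect_equal(S4Vectors::metadata(p44$truth)$expected_area_qmm2,
               53.828 * 4.4 - 137.706, tolerance = 1e-12)
  expect_equal(S4Vectors::metadata(p44$truth)$expected_area_qmm2, 99.1,
               tolerance = 1e-3)
  # expected area is non-decreasing in t for a positive slope
  tt <- c(0, 2, 4, 6, 10, 14)
  ee <- vapply(tt, function(t)
    S4Vectors::metadata(generatePathologyImage(cfg, f, t, geomPx)$truth
                        )$expected_area_qmm2, 0)
  expect_true(all(diff(ee) >= 0))
})

test_that("truth areas equal pixel count times pixel area", {
  cfg <- smallCfg(9, deviceFactor = 2)
  f <- generateNeuriteField(cfg, geomPx)
  p <- generatePathologyImage(cfg, f, 10, geomPx)
  px <- cfg@pixelSize
  for (i in seq_len(nrow(p$truth))) {
    expect_equal(p$truth$area_um2[i],
                 length(p$truth$pixels[[i]]) * px^2)
    expect_true(all(p$truth$pixels[[i]] >= 1 &
                      p$truth$pixels[[i]] <= prod(f$truth$dims)))
  }
  # the generator always provides sub-threshold and off-neurite
  # distractors so downstream filters are exercised
  expect_gte(sum(p$truth$sub_threshold), 3)
  expect_gte(sum(!p$truth$on_neurite), 1)
})

test_that("CFSE intensity decays with distance and spares native neurites", {
  cfg <- synthConfig(4, fieldSize = c(200, 96), neuriteCount = 20,
                     forwardFraction = 0.5, poissonNoise = FALSE,
                     readNoiseSd = 0, baseline = 0, blurSigma = 0)
  f <- generateNeuriteField(cfg, geomPx, offset = c(1000, -48))
  cf <- generateCfseChannel(cfg, f, geomPx)
  img <- imageData(cf)
  nr <- nrow(img)
  fwdPix <- unlist(lapply(f$truth$neurites,
                          function(ne) if (ne$forwardOrigin) ne$pixels))
  revPix <- setdiff(unlist(lapply(f$truth$neurites,
                          function(ne) if (!ne$forwardOrigin) ne$pixels)),
                    fwdPix)
  # reverse-native neurites carry no CFSE (allowing only for pixels where
  # a forward-originating neurite crosses them)
  expect_gt(mean(img[revPix] == 0), 0.9)
  xs <- 1000 + ((((fwdPix - 1) %/% nr) + 1) - 0.5) * cfg@pixelSize
  d <- xs - 1000
  v <- img[fwdPix]
  # linear decay: zero at the scale distance, maximum at the barrier
  expect_true(all(v[d > cfg@cfseScale] == 0))
  near <- v[d < 20]
  expect_gt(min(near), 0.9 * cfg@cfseMax * (1 - 20 / cfg@cfseScale))
  # mean intensity non-increasing across distance bins
  bins <- cut(d, seq(0, 200, by = 40))
  mbin <- tapply(v, bins, mean)
  mbin <- mbin[!is.na(mbin)]
  expect_true(all(diff(mbin) <= 1e-9))
})

test_that("time-lapse truth obeys the configured kinematics", {
  cfg <- smallCfg(6)
  m <- generateChannelTimelapse(cfg, geomPx,
                                data.frame(x0 = 500, v = -1))
  expect_equal(dim(m$movie)[3], 600 / 5 + 1)
  expect_equal(m$truth[[1]]$exit_time_s, 500)
  expect_equal(m$truth[[1]]$direction, "retrograde")
  stationary <- generateChannelTimelapse(cfg, geomPx,
                                         data.frame(x0 = 400, v = 0))
  expect_equal(stationary$truth[[1]]$direction, "stationary")
  expect_true(is.na(stationary$truth[[1]]$exit_time_s))
  expect_error(
    generateChannelTimelapse(cfg, geomPx, data.frame(x0 = 9000, v = 1)),
    "outside")
})

test_that("studies are reproducible and reject duplicate devices", {
  cfg <- smallCfg(11)
  sched <- data.frame(device_id = c("a", "b"), t_weeks = c(5, 9))
  s1 <- generateStudy(cfg, sched, geomPx, fieldsPerDevice = 2L)
  s2 <- generateStudy(cfg, sched, geomPx, fieldsPerDevice = 2L)
  expect_identical(s1$truth, s2$truth)
  expect_identical(imageData(s1$devices[[1]]$fields[[1]]$psyn),
                   imageData(s2$devices[[1]]$fields[[1]]$psyn))
  expect_error(generateStudy(cfg, data.frame(device_id = c("a", "a"),
                                             t_weeks = c(1, 2)), geomPx),
               "duplicate")
  # zero slope makes expected device areas constant in time
  cfg0 <- smallCfg(11, areaSlope = 0, areaIntercept = 50, deviceCV = 0)
  s0 <- generateStudy(cfg0, sched, geomPx, fieldsPerDevice = 2L)
  expect_equal(s0$truth$expected_area_qmm2, c(50, 50))
})
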