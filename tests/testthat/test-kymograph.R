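# Kymograph construction and puncta-trace quantification.

kgGeom <- deviceGeometry(pixelSize = 1)

test_that("a moving bright pixel draws a sloped line in the kymograph", {
  movie <- array(0, dim = c(5, 30, 10))
  for (f in 1:10) movie[3, 10 + f, f] <- 100
  ky <- buildKymograph(movie, lane = c(0, 5), kgGeom, frameInterval = 1,
                       pixelSize = 1, offset = c(0, 0))
  k <- imageData(ky)
  expect_equal(dim(k), c(30, 10))
  for (f in 1:10) expect_equal(which(k[, f] == 100), 10 + f)
  # conservation of maxima: every kymograph value is a source pixel value
  expect_true(all(k %in% movie))
})

test_that("leaf polygons are excluded from the projection", {
  g <- deviceGeometry(pixelSize = 1,
                      leafPolygons = list(cbind(c(10, 20, 20, 10),
                                                c(0, 0, 5, 5))))
  movie <- array(0, dim = c(5, 30, 3))
  movie[3, 15, ] <- 200   # inside the leaf polygon
  movie[3, 25, ] <- 150   # outside
  ky <- buildKymograph(movie, lane = c(0, 5), g, frameInterval = 1,
                       pixelSize = 1, offset = c(0, 0))
  k <- imageData(ky)
  expect_true(all(is.na(k[15, ])))   # lane fully covered at that x
  expect_equal(k[25, 1], 150)
  # single-frame movie yields a single-column kymograph and no traces
  ky1 <- buildKymograph(movie[, , 1, drop = FALSE], c(0, 5), g,
                        frameInterval = 1, pixelSize = 1)
  expect_equal(ncol(imageData(ky1)), 1)
  expect_equal(nrow(detectTraces(ky1)), 0)
})

test_that("trace speed is the least-squares slope with sign convention", {
  tr <- cbind(t_s = c(0, 30, 60), x_um = c(500, 466.7, 433.4))
  expect_equal(traceSpeed(tr), -66.6 / 60, tolerance = 1e-9)
  expect_equal(traceSpeed(cbind(t_s = c(0, 5, 10), x_um = rep(7, 3))), 0)
  expect_error(traceSpeed(cbind(t_s = c(0, 0, 5), x_um = 1:3)),
               "duplicate")
  expect_error(traceSpeed(cbind(t_s = c(0, 5), x_um = 1:2)), "3 samples")
  # pause exclusion recovers the undisturbed speed
  t <- seq(0, 100, by = 5)
  x <- c(seq(500, 450, by = -10), rep(450, 10), seq(440, 400, by = -10))
  tr2 <- cbind(t_s = t, x_um = x)
  expect_lt(abs(traceSpeed(tr2, excludePauses = TRUE) + 2), 0.35)
  expect_gte(abs(traceSpeed(tr2, excludePauses = TRUE)),
             abs(traceSpeed(tr2)))
})

test_that("direction classes follow the sign and stationary threshold", {
  expect_equal(classifyDirection(-1.11), "retrograde")
  expect_equal(classifyDirection(0.5), "anterograde")
  expect_equal(classifyDirection(-0.05), "stationary")
  expect_equal(classifyDirection(c(-1, 1, 0.01)),
               c("retrograde", "anterograde", "stationary"))
})

test_that("synthetic movies give exact trace counts and 5% speeds", {
  g <- deviceGeometry(pixelSize = 0.65)
  cfg <- synthConfig(seed = 5)
  pun <- data.frame(x0 = c(250, 700), v = c(-1.11, -0.8), t0 = 0)
  m <- generateChannelTimelapse(cfg, g, pun)
  ky <- buildKymograph(m$movie, m$lane, g, m$frameInterval,
                       pixelSize = 0.65, offset = m$offset)
  tr <- detectTraces(ky)
  expect_equal(nrow(tr), 2)
  expect_equal(sort(tr$speed_um_s), sort(pun$v), tolerance = 0.05)
  expect_true(all(tr$direction == "retrograde"))
  # two crossing lines stay two traces with recovered speeds
  punX <- data.frame(x0 = c(200, 800), v = c(1.0, -1.0), t0 = 0)
  mX <- generateChannelTimelapse(synthConfig(seed = 7), g, punX)
  kyX <- buildKymograph(mX$movie, mX$lane, g, mX$frameInterval,
                        pixelSize = 0.65, offset = mX$offset)
  trX <- detectTraces(kyX)
  expect_equal(nrow(trX), 2)
  expect_equal(sort(trX$speed_um_s), sort(punX$v), tolerance = 0.05)
  # a noisy jittered trace recovers the canonical -1.11 um/s within 5%
  mJ <- generateChannelTimelapse(synthConfig(seed = 7, jitterSd = 0.2), g,
                                 data.frame(x0 = 900, v = -1.11))
  kyJ <- buildKymograph(mJ$movie, mJ$lane, g, mJ$frameInterval,
                        pixelSize = 0.65, offset = mJ$offset)
  trJ <- detectTraces(kyJ)
  expect_equal(nrow(trJ), 1)
  expect_lt(abs(trJ$speed_um_s + 1.11) / 1.11, 0.05)
  # blank movie: no traces
  m0 <- generateChannelTimelapse(synthConfig(seed = 8), g, NULL)
  ky0 <- buildKymograph(m0$movie, m0$lane, g, m0$frameInterval,
                        pixelSize = 0.65, offset = m0$offset)
  expect_equal(nrow(detectTraces(ky0)), 0)
})

test_that("barrier exit is detected from observed or extrapolated traces", {
  g <- deviceGeometry(pixelSize = 0.65)
  cfg <- synthConfig(seed = 9)
  # truth exit at 500 s within the 600 s movie
  m <- generateChannelTimelapse(cfg, g, data.frame(x0 = 500, v = -1))
  expect_equal(m$truth[[1]]$exit_time_s, 500)
  ky <- buildKymograph(m$movie, m$lane, g, m$frameInterval,
                       pixelSize = 0.65, offset = m$offset)
  tr <- detectTraces(ky)
  expect_equal(nrow(tr), 1)
  expect_true(tr$exited[1])
  # a trace confined deep in the channel does not exit
  m2 <- generateChannelTimelapse(cfg, g, data.frame(x0 = 900, v = -0.15))
  ky2 <- buildKymograph(m2$movie, m2$lane, g, m2$frameInterval,
                        pixelSize = 0.65, offset = m2$offset)
  tr2 <- detectTraces(ky2)
  expect_equal(nrow(tr2), 1)
  expect_false(tr2$exited[1])
  # explicit observation below the forward edge counts as exited
  fake <- cbind(t_s = c(0, 5, 10), x_um = c(6, 2, -2))
  expect_true(detectExit(fake, ky))
})

test_that("mirroring the movie negates speeds and swaps directions", {
  g <- deviceGeometry(pixelSize = 0.65)
  cfg <- synthConfig(seed = 13)
  pun <- data.frame(x0 = c(200, 500, 850), v = c(-1.4, 0.9, -0.6), t0 = 0)
  m <- generateChannelTimelapse(cfg, g, pun)
  ky <- buildKymograph(m$movie, m$lane, g, m$frameInterval,
                       pixelSize = 0.65, offset = m$offset)
  tr <- detectTraces(ky)
  kyM <- buildKymograph(mirrorMovie(m$movie), m$lane, g, m$frameInterval,
                        pixelSize = 0.65, offset = m$offset)
  trM <- detectTraces(kyM)
  expect_equal(nrow(trM), nrow(tr))
  expect_equal(sort(trM$speed_um_s), sort(-tr$speed_um_s),
               tolerance = 1e-3)
  swap <- c(retrograde = "anterograde", anterograde = "retrograde",
            stationary = "stationary")
  expect_identical(sort(unname(swap[tr$direction])), sort(trM$direction))
})
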