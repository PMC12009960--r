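# Metrics, Grubbs-filtered aggregation and the study statistics.

test_that("field metrics scale to the 0.25 mm^2 reporting unit", {
  g <- deviceGeometry(pixelSize = 1)
  # ROI of 0.5 mm^2: 1000 x 500 px at 1 um/px
  roi <- matrix(TRUE, 500, 1000)
  fr <- S4Vectors::DataFrame(
    area_um2 = c(60, 40), centroid_x_um = c(-100, -200),
    centroid_y_um = c(100, 200))
  out <- summarizeField(fr, roi, NULL, g, offset = c(-1000, 0))
  expect_equal(out$roi_mm2, 0.5)
  expect_equal(out$area_per_qmm2, 100 * 0.25 / 0.5)  # 50
  expect_equal(out$frags_per_qmm2, 2 * 0.5)
  # fragments outside the ROI are not counted
  roi2 <- roi; roi2[, 1:150] <- FALSE  # excludes x in [-1000, -850)
  frOut <- S4Vectors::DataFrame(
    area_um2 = c(60, 40), centroid_x_um = c(-900, -200),
    centroid_y_um = c(100, 200))
  out2 <- summarizeField(frOut, roi2, NULL, g, offset = c(-1000, 0))
  expect_equal(out2$raw_area_um2, 40)
  # % of neurite area
  neur <- matrix(FALSE, 500, 1000); neur[1:5, 1:1000] <- TRUE  # 5000 um^2
  fr3 <- S4Vectors::DataFrame(area_um2 = 50, centroid_x_um = -500,
                              centroid_y_um = 10)
  out3 <- summarizeField(fr3, roi, neur, g, offset = c(-1000, 0))
  expect_equal(out3$pct_neurite, 1.0)
  expect_error(summarizeField(fr3, matrix(FALSE, 2, 2), NULL, g), "empty")
  expect_warning(
    out4 <- summarizeField(fr3, roi, matrix(FALSE, 500, 1000), g,
                           offset = c(-1000, 0)), "neurite")
  expect_true(is.na(out4$pct_neurite))
  expect_equal(out4$area_per_qmm2, 25)
})

test_that("Grubbs flags a planted outlier and nothing else", {
  x <- c(7.9, 8.1, 8.0, 7.95, 8.05, 8.02, 7.98, 8.03, 7.97, 15.0)
  expect_equal(grubbsOutliers(x, alpha = 0.05), 10L)
  expect_equal(grubbsOutliers(rep(4, 10)), integer(0))
  expect_error(grubbsOutliers(c(1, 2)), "at least 3")
})

test_that("Grubbs matches the direct-formula oracle on random sets", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    if (runif(1) < 0.5) x[sample(n, 1)] <- x[sample(n, 1)] + runif(1, 3, 8)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    minKeep <- sample(c(3L, 7L), 1)
    expect_identical(grubbsOutliers(x, alpha, minKeep = minKeep),
                     oracleGrubbs(x, alpha, minKeep = minKeep))
  }
})

test_that("chamber aggregation takes per-metric Grubbs-filtered medians", {
  mkFields <- function(area, count) {
    data.frame(image_id = paste0("f", seq_along(area)),
               area_per_qmm2 = area, frags_per_qmm2 = count,
               pct_neurite = NA_real_)
  }
  f <- mkFields(c(3, 1, 2), c(5, 5, 5))
  agg <- aggregateChamber(f, metrics = c("area_per_qmm2", "frags_per_qmm2"))
  expect_equal(agg$area_per_qmm2, 2)
  expect_equal(agg$frags_per_qmm2, 5)
  expect_error(aggregateChamber(mkFields(1:2, 1:2)), "at least 3")
  # one Grubbs-flagged extreme: median of the remaining nine
  area <- c(7.9, 8.1, 8.0, 7.95, 8.05, 8.02, 7.98, 8.03, 7.97, 50)
  f2 <- mkFields(area, rep(1, 10))
  agg2 <- aggregateChamber(f2, metrics = c("area_per_qmm2",
                                           "frags_per_qmm2"))
  keep <- area[-oracleGrubbs(area)]
  expect_equal(agg2$area_per_qmm2, median(keep))
  expect_equal(agg2$n_used_area_per_qmm2, 9)
  expect_equal(agg2$excluded_fields, "f10")
  # per-metric independence: the field extreme in area still counts for n
  expect_equal(agg2$n_used_frags_per_qmm2, 10)
  # even retained count: mean of the central pair; permutation invariance
  f3 <- mkFields(c(1, 2, 3, 4, 7, 8, 9, 10), rep(1, 8))
  agg3 <- aggregateChamber(f3, metrics = "area_per_qmm2")
  expect_equal(agg3$area_per_qmm2, 5.5)
  f3p <- f3[sample(8), ]
  expect_equal(aggregateChamber(f3p, metrics = "area_per_qmm2")$area_per_qmm2,
               5.5)
})

test_that("mean differences reproduce simple worked examples", {
  expect_equal(meanDifference(145.9, 29.3), 116.6)
  expect_equal(meanDifference(11.745, 5.557), 6.188)
  expect_equal(meanDifference(c(2, 4), c(2, 4)), 0)
  expect_error(meanDifference(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney U and exact p match full enumeration", {
  cmp <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp@U, 0)
  expect_equal(cmp@pvalue, 0.1)
  expect_true(cmp@exact)
  # A == B gives U = n1 n2 / 2
  same <- suppressWarnings(mannWhitneyU(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same@U, 4.5)
  cmp2 <- mannWhitneyU(c(1, 3), c(2, 4))
  oracle2 <- oracleMannWhitney(c(1, 3), c(2, 4))
  expect_equal(cmp2@U, oracle2$U)
  expect_equal(cmp2@pvalue, oracle2$p)
  # property: exact p equals enumeration for all untied n1 + n2 <= 10,
  # and U_A + U_B = n1 n2 always
  set.seed(14)
  for (rep in 1:40) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    pool <- sample(100, n1 + n2)   # untied
    a <- pool[seq_len(n1)]; b <- pool[-seq_len(n1)]
    got <- mannWhitneyU(a, b)
    want <- oracleMannWhitney(a, b)
    expect_equal(got@U, want$U)
    expect_equal(got@pvalue, want$p, tolerance = 1e-12)
    expect_equal(got@U + mannWhitneyU(b, a)@U, n1 * n2)
  }
  expect_warning(p1 <- mannWhitneyU(rep(2, 3), rep(2, 4)), "identical")
  expect_equal(p1@pvalue, 1)
})

test_that("trend fits are exact on closed-form cases", {
  t <- 1:5
  f <- linearTrend(t, 2 * t + 1)
  expect_equal(f@slope, 2)
  expect_equal(f@intercept, 1)
  expect_equal(f@r2, 1)
  f0 <- linearTrend(t, rep(3, 5))
  expect_equal(f0@slope, 0)
  expect_equal(f0@r2, 0)
  # two-point closed form through noise-free pipeline values
  f2 <- linearTrend(c(1, 2, 4), c(3, 5, 9))
  expect_equal(f2@slope, 2); expect_equal(f2@intercept, 1)
  expect_equal(f2@df, c(1, 1))
  # F statistic identity against lm's anova
  set.seed(3)
  y <- 1.5 * t + rnorm(5)
  ft <- linearTrend(t, y)
  av <- anova(lm(y ~ t))
  expect_equal(ft@fstat, av$`F value`[1], tolerance = 1e-10)
  expect_equal(ft@pvalue, av$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(linearTrend(rep(2, 4), 1:4), "degenerate")
})

test_that("noise-free synthetic studies return the generator slope", {
  g <- deviceGeometry(pixelSize = 0.65)
  cfg <- synthConfig(seed = 2, deviceCV = 0)
  sched <- data.frame(device_id = paste0("d", 1:6),
                      t_weeks = seq(4, 14, length.out = 6))
  st <- generateStudy(cfg, sched, g, fieldsPerDevice = 1L)
  # expected (truth-law) values are exactly linear in t
  fit <- linearTrend(st$truth$t_weeks, st$truth$expected_area_qmm2)
  expect_equal(fit@slope, 53.828, tolerance = 1e-9)
  expect_equal(fit@intercept, -137.706, tolerance = 1e-9)
})

test_that("propagation ratio divides unseeded by seeded level", {
  expect_equal(propagationRatio(29.3, 145.9), 29.3 / 145.9)
  expect_equal(round(propagationRatio(29.3, 145.9), 4), 0.2008)
  expect_equal(propagationRatio(5, 5), 1)
  expect_warning(r <- propagationRatio(3, 0), "undefined")
  expect_true(is.na(r))
  u <- data.frame(area_per_qmm2 = 30)
  s <- data.frame(area_per_qmm2 = 120)
  expect_equal(propagationRatio(u, s), 0.25)
})
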