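# Per-field metrics, Grubbs-filtered chamber aggregation, and the study
# statistics: time-trend regressions, Mann-Whitney comparisons and the
# propagation ratio.

#' Per-field pathology metrics normalised to 0.25 mm^2
#'
#' Totals the area and count of fragments whose centroid falls inside the
#' ROI and rescales both to the conventional reporting unit of 0.25 mm^2.
#' Also reports pathology area as a percentage of the neurite area within
#' the ROI.
#'
#' @param fragments table from [extractFragments()] for this field.
#' @param roiMask logical ROI mask (from [makeRoiMask()]).
#' @param neuriteMask logical neurite mask, same shape as `roiMask`
#'   (optional; `%neurite` is `NA` without it).
#' @param geometry a [DeviceGeometry-class].
#' @param pixelSize um/px of the masks; defaults to `pixelSize(geometry)`.
#' @param offset device-coordinate origin of the masks in um.
#' @param imageId identifier for the output row.
#' @return one-row `data.frame`: `image_id`, `roi_mm2`, `area_per_qmm2`
#'   (um^2 per 0.25 mm^2), `frags_per_qmm2`, `pct_neurite`,
#'   `neurite_um2`, `raw_area_um2`, `n_fragments`.
#' @examples
#' g <- deviceGeometry()
#' # a 0.5 mm^2 ROI with 100 um^2 of fragments scales to 50 um^2/0.25 mm^2
#' @export
summarizeField <- function(fragments, roiMask, neuriteMask = NULL,
                           geometry, pixelSize = NULL, offset = c(0, 0),
                           imageId = "field") {
  px <- pixelSize %||% geometry@pixelSize
  roiPx <- sum(roiMask)
  if (roiPx == 0L) stop("empty ROI for image '", imageId, "'")
  roiMm2 <- roiPx * px^2 / 1e6
  inRoi <- logical(nrow(fragments))
  if (nrow(fragments)) {
    nr <- nrow(roiMask)
    ix <- pmin(pmax(ceiling((fragments$centroid_x_um - offset[1L]) / px),
                    1L), ncol(roiMask))
    iy <- pmin(pmax(ceiling((fragments$centroid_y_um - offset[2L]) / px),
                    1L), nr)
    inRoi <- roiMask[cbind(iy, ix)]
  }
  rawArea <- sum(fragments$area_um2[inRoi])
  n <- sum(inRoi)
  scale <- 0.25 / roiMm2
  neuriteArea <- NA_real_
  pct <- NA_real_
  if (!is.null(neuriteMask)) {
    neuriteArea <- sum(neuriteMask & roiMask) * px^2
    pct <- if (neuriteArea > 0) 100 * rawArea / neuriteArea else NA_real_
    if (neuriteArea == 0)
      warning("zero neurite area in ROI for image '", imageId,
              "': %neurite undefined")
  }
  data.frame(image_id = imageId, roi_mm2 = roiMm2,
             area_per_qmm2 = rawArea * scale,
             frags_per_qmm2 = n * scale,
             pct_neurite = pct, neurite_um2 = neuriteArea,
             raw_area_um2 = rawArea, n_fragments = n,
             stringsAsFactors = FALSE)
}

# Two-sided Grubbs critical value for sample size n at significance alpha.
grubbsCritical <- function(n, alpha) {
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier detection
#'
#' At each step the most extreme value's studentised deviation
#' `G = max |x_i - mean| / sd` is compared with the critical value built
#' from the Student-t quantile at `alpha / (2n)`; if it exceeds it, that
#' value is removed and the test repeats on the reduced set. Testing stops
#' when no value is flagged or when fewer than `minKeep` values remain
#' (default 7, which caps removals for the usual 10-field chambers).
#' Zero-variance sets flag nothing.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param minKeep testing stops once fewer than this many values remain.
#' @param iterative if `FALSE`, perform at most one removal.
#' @return integer indices (into `values`) of excluded observations.
#' @examples
#' x <- c(rep(8, 9) + rnorm(9, 0, 0.1), 15)
#' grubbsOutliers(x)  # flags the 15
#' @export
grubbsOutliers <- function(values, alpha = 0.05, minKeep = 7L,
                           iterative = TRUE) {
  if (length(values) < 3L) stop("Grubbs test requires at least 3 values")
  stopifnot(alpha > 0, alpha < 1)
  keep <- seq_along(values)
  excluded <- integer(0)
  repeat {
    n <- length(keep)
    if (n < minKeep || n < 3L) break
    x <- values[keep]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    if (G > grubbsCritical(n, alpha)) {
      excluded <- c(excluded, keep[i])
      keep <- keep[-i]
      if (!iterative) break
    } else break
  }
  sort(excluded)
}

#' Aggregate per-field metrics into a chamber summary
#'
#' For each metric the Grubbs test ([grubbsOutliers()]) is applied across
#' fields, then the median of the retained values is taken (mean of the
#' central pair for even counts). Outlier sets are determined independently
#' per metric: a field extreme in area but not in count still contributes
#' to the count median.
#'
#' @param fields `data.frame` of per-field rows from [summarizeField()].
#' @param alpha Grubbs significance level.
#' @param minKeep passed to [grubbsOutliers()].
#' @param metrics metric columns to aggregate.
#' @param deviceId,chamber identifiers echoed into the output.
#' @return one-row `data.frame`: `device_id`, `chamber`, `n_fields`, one
#'   median column per metric, `n_used_<metric>` counts, and
#'   `excluded_fields` (semicolon-joined image ids over all metrics).
#' @export
aggregateChamber <- function(fields, alpha = 0.05, minKeep = 7L,
                             metrics = c("area_per_qmm2", "frags_per_qmm2",
                                         "pct_neurite"),
                             deviceId = "device", chamber = "forward") {
  if (nrow(fields) < 3L) stop("need at least 3 fields per chamber")
  out <- data.frame(device_id = deviceId, chamber = chamber,
                    n_fields = nrow(fields), stringsAsFactors = FALSE)
  excludedIds <- character(0)
  for (m in metrics) {
    v <- fields[[m]]
    ok <- which(!is.na(v))
    if (length(ok) < 3L) {
      out[[m]] <- NA_real_
      out[[paste0("n_used_", m)]] <- length(ok)
      next
    }
    ex <- grubbsOutliers(v[ok], alpha = alpha, minKeep = minKeep)
    used <- ok[setdiff(seq_along(ok), ex)]
    out[[m]] <- median(v[used])
    out[[paste0("n_used_", m)]] <- length(used)
    excludedIds <- c(excludedIds, fields$image_id[ok[ex]])
  }
  out$excluded_fields <- paste(unique(excludedIds), collapse = ";")
  out
}

#' Difference of group means
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @return `mean(groupA) - mean(groupB)`.
#' @examples
#' meanDifference(c(145.9), c(29.3))  # 116.6
#' @export
meanDifference <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  mean(groupA) - mean(groupB)
}

#' Mann-Whitney U comparison of two groups
#'
#' U is computed from midranks. The two-sided p-value is exact (full
#' enumeration of the null permutation distribution, via
#' [stats::wilcox.test()]) when `n1 + n2 <= 16` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. If every value is identical across both groups the
#' comparison is degenerate and p = 1 is returned with a warning.
#'
#' @param groupA,groupB numeric vectors, each non-empty.
#' @return a [GroupComparison-class] object.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
  n1 <- length(groupA); n2 <- length(groupB)
  U <- uStatistic(groupA, groupB)
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  if (length(unique(c(groupA, groupB))) == 1L) {
    warning("all values identical across both groups: p = 1")
    p <- 1
    exact <- FALSE
  } else {
    exact <- (n1 + n2) <= 16L && !ties
    p <- suppressWarnings(
      wilcox.test(groupA, groupB, exact = exact, correct = TRUE,
                  alternative = "two.sided")$p.value)
    p <- min(1, p)
  }
  new("GroupComparison", meanA = mean(groupA), meanB = mean(groupB),
      meanDifference = mean(groupA) - mean(groupB), U = U,
      pvalue = p, exact = exact, n = c(n1, n2))
}

#' Ordinary least-squares time trend
#'
#' Fits `y ~ t` by OLS across device summaries (one point per device per
#' timepoint). The slope's F statistic is `(R^2 / (1 - R^2)) * (n - 2)`
#' with (1, n - 2) degrees of freedom.
#'
#' @param t numeric predictor (e.g. weeks since seeding); not all equal.
#' @param y numeric response, same length, `n >= 3`.
#' @return a [TrendFit-class] object.
#' @examples
#' f <- linearTrend(1:5, 2 * (1:5) + 1)
#' f@slope  # 2
#' @export
linearTrend <- function(t, y) {
  ok <- complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  n <- length(t)
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(t)) < 2L) stop("predictor is degenerate (all t equal)")
  fit <- lm(y ~ t)
  b <- coef(fit)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(fit$residuals^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  fstat <- if (r2 < 1) (r2 / (1 - r2)) * (n - 2) else Inf
  p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  new("TrendFit", slope = unname(b[2L]), intercept = unname(b[1L]),
      fstat = fstat, df = c(1, n - 2), pvalue = p, r2 = r2,
      n = as.integer(n))
}

#' 95% confidence interval for a fitted trend slope
#'
#' @param fit a [TrendFit-class].
#' @param t,y the data the trend was fitted to.
#' @param level confidence level.
#' @return numeric(2) confidence bounds for the slope.
#' @export
slopeConfint <- function(fit, t, y, level = 0.95) {
  ok <- complete.cases(t, y)
  m <- lm(y[ok] ~ t[ok])
  unname(stats::confint(m, level = level)[2L, ])
}

#' Propagation ratio between chambers
#'
#' The level of pathology in the unseeded chamber divided by the level in
#' the seeded chamber: an estimate of transport/transfer efficiency across
#' the microchannel barrier.
#'
#' @param unseeded,seeded chamber summary rows (from [aggregateChamber()])
#'   or bare numeric levels.
#' @param metric metric column used when summaries are passed.
#' @return the ratio; `NA` with a warning when the seeded level is 0 (such
#'   devices are flagged, not silently dropped).
#' @examples
#' propagationRatio(29.3, 145.9)  # ~0.2008
#' @export
propagationRatio <- function(unseeded, seeded, metric = "area_per_qmm2") {
  u <- if (is.data.frame(unseeded)) unseeded[[metric]] else unseeded
  s <- if (is.data.frame(seeded)) seeded[[metric]] else seeded
  if (any(s == 0, na.rm = TRUE))
    warning("seeded level is 0: propagation ratio undefined, flagged NA")
  ifelse(s == 0, NA_real_, u / s)
}
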