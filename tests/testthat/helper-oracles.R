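# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Flood-fill connected-component labelling in plain R (stack-based).
oracleLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  for (x in seq_len(nc)) for (y in seq_len(nr)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    cur <- cur + 1L
    stack <- list(c(y, x)); lab[y, x] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        yy <- p[1] + nb[k, 1]; xx <- p[2] + nb[k, 2]
        if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          stack[[length(stack) + 1L]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

# Binary dilation by shifting (square structuring element of radius r).
oracleDilate <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    sh <- matrix(FALSE, nr, nc)
    yy <- seq_len(nr)[seq_len(nr) + dy >= 1 & seq_len(nr) + dy <= nr]
    xx <- seq_len(nc)[seq_len(nc) + dx >= 1 & seq_len(nc) + dx <= nc]
    sh[yy + dy, xx + dx] <- mask[yy, xx]
    out <- out | sh
  }
  out
}

# Brute-force fragment extraction: flood fill + per-component predicate.
# Returns a list of sorted pixel-index vectors, one per kept component.
oracleExtract <- function(psynMask, tubulinMask, params, pixelSize) {
  lab <- oracleLabel(psynMask, params@connectivity)
  neur <- if (params@dilationRadius > 0)
    oracleDilate(tubulinMask, params@dilationRadius) else tubulinMask
  minPx <- ceiling(params@minArea / pixelSize^2 - 1e-9)
  kept <- list()
  for (comp in seq_len(max(lab))) {
    pix <- which(lab == comp)
    frac <- sum(neur[pix]) / length(pix)
    if (frac >= params@colocFraction && length(pix) >= minPx)
      kept[[length(kept) + 1L]] <- sort(pix)
  }
  kept
}

# Dijkstra over the pixels of a 1-px skeleton with weights 1 / sqrt(2);
# returns the longest shortest path between any two pixels (geodesic
# diameter) in pixel units.
oracleGeodesic <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dy <- abs(pts[i, 1] - pts[j, 1]); dx <- abs(pts[i, 2] - pts[j, 2])
    if (i != j && dy <= 1 && dx <= 1)
      d[i, j] <- if (dy + dx == 2) sqrt(2) else 1
  }
  for (k in seq_len(n)) {          # Floyd-Warshall
    dk <- d[, k]
    d <- pmin(d, outer(dk, d[k, ], `+`))
  }
  max(d[is.finite(d)])
}

# Direct-formula Grubbs exclusions: studentised extreme deviation against
# the t-quantile critical value, iterated with the same stopping rule as
# the pipeline (test only while at least minKeep values remain).
oracleGrubbs <- function(x, alpha = 0.05, minKeep = 7L) {
  idx <- seq_along(x)
  out <- integer(0)
  repeat {
    n <- length(idx)
    if (n < minKeep || n < 3L) break
    v <- x[idx]
    if (sd(v) == 0 || !is.finite(sd(v))) break
    G <- max(abs(v - mean(v))) / sd(v)
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > gcrit) {
      worst <- idx[which.max(abs(v - mean(v)))]
      out <- c(out, worst)
      idx <- setdiff(idx, worst)
    } else break
  }
  sort(out)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (untied data only).
oracleMannWhitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  uOf <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  u <- uOf(seq_len(n1))
  combs <- combn(n1 + n2, n1)
  us <- apply(combs, 2, uOf)
  pLe <- mean(us <= u); pGe <- mean(us >= u)
  list(U = u, p = min(1, 2 * min(pLe, pGe)))
}

# Exhaustive Otsu: the threshold (cut between consecutive observed values)
# maximising the between-class variance of the intensity histogram.
oracleOtsuPartition <- function(vals) {
  v <- sort(unique(as.vector(vals)))
  best <- -Inf; cut <- v[1]
  for (t in v[-length(v)]) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    w1 <- length(lo) / length(vals); w2 <- 1 - w1
    bc <- w1 * w2 * (mean(hi) - mean(lo))^2
    if (bc > best) { best <- bc; cut <- t }
  }
  cut  # foreground is vals > cut
}
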