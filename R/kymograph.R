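# Kymograph construction from microchannel time-lapse stacks and
# puncta-trace quantification: signed speed, direction class, barrier exit.

#' Build a kymograph from a time-lapse stack
#'
#' For each frame and each x position, the kymograph value is the maximum
#' intensity over the lane's y-pixels that are not inside any leaf polygon.
#' Columns (x positions) where the lane is entirely covered by leaf
#' polygons are `NA` ("missing").
#'
#' @param movie a 3D numeric array `[y, x, frame]`, or a list of frame
#'   matrices.
#' @param lane numeric(2) y-interval of the microchannel lane in um.
#' @param geometry a [DeviceGeometry-class]; supplies the leaf polygons,
#'   pixel size (unless given) and the barrier range.
#' @param frameInterval seconds between frames.
#' @param pixelSize um/px of the movie; defaults to `pixelSize(geometry)`.
#' @param offset numeric(2) device coordinates (um) of the movie origin.
#' @param laneId integer identifier.
#' @return a [Kymograph-class] (rows = x positions, columns = frames).
#' @export
buildKymograph <- function(movie, lane, geometry, frameInterval,
                           pixelSize = NULL, offset = c(0, 0),
                           laneId = 1L) {
  if (is.list(movie) && !is.array(movie))
    movie <- simplify2array(movie)
  stopifnot(length(dim(movie)) == 3L)
  px <- pixelSize %||% geometry@pixelSize
  nr <- dim(movie)[1L]; nc <- dim(movie)[2L]; nf <- dim(movie)[3L]
  yc <- offset[2L] + (seq_len(nr) - 0.5) * px
  rows <- which(yc >= lane[1L] & yc <= lane[2L])
  if (!length(rows)) stop("lane does not intersect the movie")
  xc <- offset[1L] + (seq_len(nc) - 0.5) * px
  allowed <- matrix(TRUE, length(rows), nc)
  for (p in geometry@leafPolygons) {
    grid <- expand.grid(y = yc[rows], x = xc)
    inside <- pointInPolygon(grid$x, grid$y, p)
    allowed <- allowed & !matrix(inside, length(rows), nc)
  }
  nOpen <- colSums(allowed)
  kymo <- matrix(NA_real_, nc, nf)
  for (f in seq_len(nf)) {
    fr <- movie[rows, , f, drop = FALSE]
    fr[!allowed] <- -Inf
    v <- apply(fr, 2L, max)
    v[nOpen == 0L] <- NA_real_
    kymo[, f] <- v
  }
  new("Kymograph", data = kymo, pixelSize = px,
      frameInterval = frameInterval, xOrigin = offset[1L],
      laneId = as.integer(laneId), barrier = geometry@barrier)
}

# Per-frame spot detection on a background-subtracted kymograph column:
# runs of above-threshold pixels (tolerating 1-px interruptions) become
# one detection each, at the intensity-weighted centroid.
detectSpots <- function(col, thr, xCoords) {
  above <- which(!is.na(col) & col > thr)
  if (!length(above)) return(NULL)
  gaps <- which(diff(above) > 2L)
  starts <- c(1L, gaps + 1L)
  ends <- c(gaps, length(above))
  t(vapply(seq_along(starts), function(i) {
    idx <- above[starts[i]]:above[ends[i]]
    w <- pmax(col[idx], 0)
    w[is.na(w)] <- 0
    c(x = sum(xCoords[idx] * w) / sum(w), intensity = max(w))
  }, c(x = 0, intensity = 0)))
}

# Stitch trace segments that belong to one punctum: a later segment is
# appended to an earlier one when their time ranges do not overlap and the
# earlier fit, extrapolated to the later start, matches its first position
# within tol (and speeds are compatible for segments long enough to have
# a stable fit).
stitchTraces <- function(done, tol) {
  if (length(done) < 2L) return(done)
  fitOf <- function(tr) {
    if (length(tr$t) < 2L) return(c(v = 0, x0 = unname(tr$x[1L])))
    tc <- tr$t - mean(tr$t)
    v <- sum(tc * (tr$x - mean(tr$x))) / sum(tc^2)
    c(v = v, x0 = mean(tr$x) - v * mean(tr$t))
  }
  repeat {
    n <- length(done)
    starts <- vapply(done, function(tr) tr$t[1L], 0)
    ord <- order(starts)
    merged <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        i <- ord[a]; j <- ord[b]
        ti <- done[[i]]$t; tj <- done[[j]]$t
        if (tj[1L] <= ti[length(ti)]) next
        fi <- fitOf(done[[i]])
        pred <- fi["x0"] + fi["v"] * tj[1L]
        if (abs(pred - done[[j]]$x[1L]) > tol) next
        fj <- fitOf(done[[j]])
        if (length(tj) >= 5L && length(ti) >= 5L &&
            abs(fj["v"] - fi["v"]) > pmax(0.3, 0.35 * abs(fi["v"]))) next
        done[[i]]$t <- c(ti, tj)
        done[[i]]$x <- c(done[[i]]$x, done[[j]]$x)
        done[[i]]$intensity <- c(done[[i]]$intensity, done[[j]]$intensity)
        done[[i]]$lastFrame <- max(done[[i]]$lastFrame, done[[j]]$lastFrame)
        done <- done[-j]
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) return(done)
  }
}

#' Detect moving puncta traces in a kymograph
#'
#' Stationary structure is suppressed by subtracting the per-position
#' temporal median, then per-frame spot detections (contiguous
#' above-threshold runs, intensity-weighted centroid) are linked across
#' frames by nearest-neighbour association with constant-velocity
#' prediction, which keeps crossing traces separate. Traces interrupted for
#' more than `maxGap` frames are terminated; traces spanning fewer than 3
#' frames are discarded. Each trace's speed is the least-squares slope of
#' position on time.
#'
#' @param kymo a [Kymograph-class].
#' @param threshold intensity threshold applied to the background-subtracted
#'   kymograph; default `4 * mad` of the subtracted values.
#' @param maxGap maximum number of consecutive missed frames before a trace
#'   is closed (default 2).
#' @param maxJump maximum distance (um) between a prediction and a matched
#'   detection (default 15).
#' @param subtractBackground subtract the per-x temporal median (default
#'   TRUE; set FALSE to detect stationary puncta too).
#' @param stationaryThreshold um/s below which a trace is classed
#'   stationary.
#' @return `data.frame` with one row per trace: `trace_id`, `lane`,
#'   `n_frames`, `speed_um_s`, `direction`, `exited`, `t_start_s`,
#'   `t_end_s`, `mean_intensity`, plus a list column `samples` of
#'   per-trace `(t_s, x_um)` matrices.
#' @export
detectTraces <- function(kymo, threshold = NULL, maxGap = 2L, maxJump = 15,
                         subtractBackground = TRUE,
                         stationaryThreshold = 0.1) {
  k <- kymo@data
  nf <- ncol(k)
  out <- data.frame(trace_id = integer(0), lane = integer(0),
                    n_frames = integer(0), speed_um_s = numeric(0),
                    direction = character(0), exited = logical(0),
                    t_start_s = numeric(0), t_end_s = numeric(0),
                    mean_intensity = numeric(0),
                    stringsAsFactors = FALSE)
  out$samples <- list()
  if (nf < 3L) return(out)
  if (subtractBackground) {
    bg <- apply(k, 1L, median, na.rm = TRUE)
    bg[!is.finite(bg)] <- 0
    k <- k - bg
  }
  if (is.null(threshold)) {
    v <- k[is.finite(k)]
    threshold <- max(6 * stats::mad(v, center = 0), 0.25 * max(v))
    if (threshold <= 0) threshold <- Inf
  }
  xCoords <- kymo@xOrigin + (seq_len(nrow(k)) - 0.5) * kymo@pixelSize
  dt <- kymo@frameInterval
  active <- list()   # each: list(t, x, intensity, lastFrame)
  done <- list()
  for (f in seq_len(nf)) {
    det <- detectSpots(k[, f], threshold, xCoords)
    used <- logical(if (is.null(det)) 0L else nrow(det))
    # match active traces to detections (closest prediction first)
    if (length(active)) {
      preds <- vapply(active, function(tr) {
        n <- length(tr$x)
        v <- if (n >= 2L) (tr$x[n] - tr$x[1L]) / (tr$t[n] - tr$t[1L]) else 0
        tr$x[n] + v * ((f - 1) * dt - tr$t[n])
      }, 0)
      ord <- order(vapply(active, function(tr) -tr$lastFrame, 0))
      for (ai in ord) {
        if (is.null(det) || all(used)) break
        dists <- abs(det[, "x"] - preds[ai])
        dists[used] <- Inf
        j <- which.min(dists)
        if (dists[j] <= maxJump) {
          used[j] <- TRUE
          active[[ai]]$t <- c(active[[ai]]$t, (f - 1) * dt)
          active[[ai]]$x <- c(active[[ai]]$x, unname(det[j, "x"]))
          active[[ai]]$intensity <- c(active[[ai]]$intensity,
                                      unname(det[j, "intensity"]))
          active[[ai]]$lastFrame <- f
        }
      }
    }
    # close stale traces
    if (length(active)) {
      stale <- vapply(active, function(tr) f - tr$lastFrame > maxGap,
                      NA)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    # unmatched detections start new traces
    if (!is.null(det)) {
      for (j in which(!used)) {
        active[[length(active) + 1L]] <-
          list(t = (f - 1) * dt, x = unname(det[j, "x"]),
               intensity = unname(det[j, "intensity"]), lastFrame = f)
      }
    }
  }
  done <- c(done, active)
  done <- stitchTraces(done, tol = maxJump)
  done <- Filter(function(tr) length(tr$t) >= 3L, done)
  if (!length(done)) return(out)
  rows <- lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    sp <- traceSpeed(cbind(t_s = tr$t, x_um = tr$x),
                     stationaryThreshold = stationaryThreshold)
    data.frame(trace_id = i, lane = kymo@laneId,
               n_frames = length(tr$t), speed_um_s = sp,
               direction = classifyDirection(sp, stationaryThreshold),
               exited = detectExitImpl(tr$t, tr$x, sp, kymo),
               t_start_s = tr$t[1L], t_end_s = tr$t[length(tr$t)],
               mean_intensity = mean(tr$intensity),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$samples <- lapply(done, function(tr) cbind(t_s = tr$t, x_um = tr$x))
  out
}

#' Signed speed of a punctum trace
#'
#' Least-squares slope of position on time, in um/s; negative speeds run
#' toward the forward chamber (retrograde). With `excludePauses = TRUE`,
#' steps slower than `stationaryThreshold` are discarded and the speed is
#' the net displacement over the remaining (moving) time, so the estimate
#' reflects movement while undisturbed rather than being diluted by
#' pauses.
#'
#' @param trace a two-column matrix or data.frame of `(t_s, x_um)` samples
#'   (>= 3 samples, strictly increasing times), or one row of the
#'   [detectTraces()] table.
#' @param excludePauses drop paused runs before fitting (default FALSE).
#' @param stationaryThreshold um/s defining a pause.
#' @return signed speed in um/s.
#' @examples
#' tr <- cbind(t_s = c(0, 30, 60), x_um = c(500, 466.7, 433.4))
#' traceSpeed(tr)  # ~ -1.11
#' @export
traceSpeed <- function(trace, excludePauses = FALSE,
                       stationaryThreshold = 0.1) {
  if (is.data.frame(trace) && "samples" %in% names(trace))
    trace <- trace$samples[[1L]]
  t <- trace[, 1L]; x <- trace[, 2L]
  if (length(t) < 3L) stop("trace needs at least 3 samples")
  if (anyDuplicated(t)) stop("duplicate timestamps in trace")
  if (excludePauses && length(t) > 3L) {
    dt <- diff(t); dx <- diff(x)
    moving <- abs(dx / dt) >= stationaryThreshold
    if (any(moving)) return(sum(dx[moving]) / sum(dt[moving]))
  }
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

#' Classify a trace's direction of travel
#'
#' @param speed signed speed in um/s (negative = toward the forward
#'   chamber).
#' @param stationaryThreshold absolute speed below which the trace is
#'   `"stationary"` (default 0.1 um/s).
#' @return `"retrograde"`, `"anterograde"` or `"stationary"`.
#' @export
classifyDirection <- function(speed, stationaryThreshold = 0.1) {
  ifelse(abs(speed) < stationaryThreshold, "stationary",
         ifelse(speed < 0, "retrograde", "anterograde"))
}

detectExitImpl <- function(t, x, speed, kymo) {
  edge <- kymo@barrier[1L]
  if (any(x <= edge)) return(TRUE)
  # extrapolate the fitted line to the end of the recording
  if (speed < 0) {
    tEnd <- (ncol(kymo@data) - 1L) * kymo@frameInterval
    xEnd <- x[length(x)] + speed * (tEnd - t[length(t)])
    return(xEnd <= edge)
  }
  FALSE
}

#' Did a trace exit the microchannel into the forward chamber?
#'
#' TRUE when the observed positions cross the forward barrier edge, or when
#' the fitted line extrapolated to the end of the recording does.
#'
#' @param trace one row of the [detectTraces()] table or a `(t_s, x_um)`
#'   matrix.
#' @param kymo the [Kymograph-class] the trace came from.
#' @param speed fitted speed; computed from the trace if missing.
#' @return logical.
#' @export
detectExit <- function(trace, kymo, speed = NULL) {
  if (is.data.frame(trace) && "samples" %in% names(trace)) {
    speed <- speed %||% trace$speed_um_s[1L]
    trace <- trace$samples[[1L]]
  }
  speed <- speed %||% traceSpeed(trace)
  detectExitImpl(trace[, 1L], trace[, 2L], speed, kymo)
}
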