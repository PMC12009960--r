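# Synthetic microchannel time-lapse movies with trace ground truth.

#' Generate a microchannel time-lapse movie with moving puncta
#'
#' Renders a single-lane movie spanning the microchannel barrier plus a
#' margin of both chambers. Each punctum is a Gaussian spot moving at
#' constant velocity, `x(t) = x0 + v * t`, with per-frame localisation
#' jitter; stationary puncta (`v = 0`) are supported. The truth records
#' per-frame positions, nominal speed, direction class and the frame at
#' which a punctum first crosses the forward barrier edge (x = 0), if any.
#'
#' @param cfg a [SynthConfig-class]; timing comes from `frameInterval` and
#'   `duration`.
#' @param geometry a [DeviceGeometry-class].
#' @param puncta `data.frame` with columns `x0` (um, device coordinates),
#'   `v` (um/s, negative = retrograde) and optionally `t0` (s, appearance
#'   time, default 0). May be empty (noise-only movie).
#' @param lane numeric(2) lane y-interval in um; default the first
#'   configured lane, or a lane of `cfg@laneWidth` centred on y = 0.
#' @param seed random seed.
#' @return list with `movie` (3D array `[y, x, frame]`), `offset`
#'   (device um of the movie origin), `frameInterval`, and `truth`: a list
#'   of per-punctum records (`x0`, `v`, `t0`, `times`, `positions`,
#'   `direction`, `exit_time_s` or `NA`), plus `lane`.
#' @examples
#' cfg <- synthConfig(seed = 3, duration = 50)
#' g <- deviceGeometry()
#' m <- generateChannelTimelapse(cfg, g,
#'   puncta = data.frame(x0 = 500, v = -1.1))
#' dim(m$movie)
#' @export
generateChannelTimelapse <- function(cfg, geometry, puncta = NULL,
                                     lane = NULL,
                                     seed = childSeed(cfg@seed, 404L)) {
  px <- cfg@pixelSize
  b <- geometry@barrier
  if (is.null(lane)) {
    lane <- if (length(geometry@lanes)) geometry@lanes[[1L]]
            else c(-cfg@laneWidth / 2, cfg@laneWidth / 2)
  }
  xMin <- b[1L] - cfg@movieMargin
  xMax <- b[2L] + cfg@movieMargin
  pad <- 3 * cfg@punctaSigma
  offset <- c(xMin, lane[1L] - pad)
  nc <- ceiling((xMax - xMin) / px)
  nr <- ceiling((diff(lane) + 2 * pad) / px)
  nFrames <- as.integer(round(cfg@duration / cfg@frameInterval)) + 1L
  times <- (seq_len(nFrames) - 1L) * cfg@frameInterval
  if (is.null(puncta) || !nrow(puncta)) {
    puncta <- data.frame(x0 = numeric(0), v = numeric(0), t0 = numeric(0))
  }
  if (is.null(puncta$t0)) puncta$t0 <- rep(0, nrow(puncta))
  if (nrow(puncta) && any(puncta$x0 < xMin | puncta$x0 > xMax))
    stop("punctum starts outside the movie field")
  if (nrow(puncta) && any(!is.finite(puncta$v)))
    stop("puncta speeds must be finite")
  yCenter <- mean(lane)
  withSeed(seed, {
    movie <- array(0, dim = c(nr, nc, nFrames))
    truth <- vector("list", nrow(puncta))
    for (i in seq_len(nrow(puncta))) {
      x0 <- puncta$x0[i]; v <- puncta$v[i]; t0 <- puncta$t0[i]
      xs <- x0 + v * (times - t0)
      alive <- times >= t0 & xs >= xMin & xs <= xMax
      jx <- rnorm(nFrames, 0, cfg@jitterSd)
      jy <- rnorm(nFrames, 0, cfg@jitterSd)
      exitIdx <- if (v < 0) which(xs <= b[1L] & times >= t0) else integer(0)
      truth[[i]] <- list(
        x0 = x0, v = v, t0 = t0,
        times = times[alive], positions = xs[alive] + jx[alive],
        direction = classifyDirection(v),
        exit_time_s = if (length(exitIdx)) (b[1L] - x0) / v + t0
                      else NA_real_)
      for (f in which(alive)) {
        movie[, , f] <- addGaussianSpot(
          movie[, , f],
          c(xs[f] + jx[f] - offset[1L], yCenter + jy[f] - offset[2L]),
          cfg@punctaIntensity, cfg@punctaSigma, px)
      }
    }
    for (f in seq_len(nFrames)) movie[, , f] <- renderImage(movie[, , f], cfg)
    list(movie = movie, offset = offset,
         frameInterval = cfg@frameInterval, lane = lane,
         pixelSize = px, truth = truth)
  })
}

#' Mirror a movie along the channel axis
#'
#' Reflects every frame left-right (x -> -x about the movie midline).
#' Useful for symmetry checks: mirroring negates every trace velocity and
#' swaps anterograde and retrograde.
#'
#' @param movie 3D array `[y, x, frame]`.
#' @return the reflected array.
#' @export
mirrorMovie <- function(movie) {
  movie[, rev(seq_len(dim(movie)[2L])), , drop = FALSE]
}
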