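# Configuration for the synthetic-microscopy generator.

#' Configuration of the synthetic-microscopy generator
#'
#' Holds every parameter of the ground-truthed generator: field geometry,
#' neurite-network model, the pathology growth laws, fragment geometry,
#' non-specific background staining, CFSE decay, puncta kinematics, the
#' camera noise model and the master seed. A fixed seed makes every
#' generated image and truth record bit-identical.
#'
#' @slot seed master random seed (integer).
#' @slot fieldSize numeric(2) field extent (x, y) in um.
#' @slot pixelSize rendering calibration in um/px.
#' @slot neuriteCount neurites per field.
#' @slot neuriteStep,neuriteWobble persistent-random-walk step length (um)
#'   and per-step heading s.d. (radians).
#' @slot neuriteWidthPx numeric(2) min/max rasterised neurite width in px.
#' @slot neuriteIntensity,somaDensity tubulin-channel amplitude and somata
#'   per 0.25 mm^2 (rendered as discs).
#' @slot forwardFraction fraction of neurites that are forward-originating
#'   (CFSE-labelled in the reverse chamber).
#' @slot areaSlope,areaIntercept growth law of detected (>= minArea,
#'   on-neurite) pathology area, um^2 per 0.25 mm^2 per week.
#' @slot countSlope,countIntercept growth law of the total number of placed
#'   pathology fragments (including sub-threshold ones) per 0.25 mm^2 per
#'   week.
#' @slot controlArea expected pathology-like background area for unseeded
#'   control devices, um^2 per 0.25 mm^2 (constant in time).
#' @slot fragmentLengthRange,fragmentWidth,fragmentIntensity geometry (um)
#'   and amplitude of rendered pathology fragments.
#' @slot distractorLengthRange length range (um) of deliberate
#'   sub-threshold fragments.
#' @slot backgroundBlobDensity,backgroundBlobIntensity,backgroundBlobSigma
#'   soft-edged non-specific staining blobs: count per 0.25 mm^2,
#'   amplitude, Gaussian radius (um).
#' @slot offNeuriteBarCount number of >= minArea fragments placed off
#'   neurites per field (exercise the colocalisation filter).
#' @slot cfseDecay `"linear"` or `"exponential"` CFSE fall-off with
#'   distance from the microchannels.
#' @slot cfseScale decay scale in um (linear: intensity reaches 0 here).
#' @slot cfseMax CFSE amplitude at the barrier.
#' @slot transferFraction fraction of pathology placed on reverse-native
#'   (CFSE-negative) neurites.
#' @slot deviceFactor multiplicative device-level factor on expected
#'   metrics.
#' @slot deviceCV coefficient of variation of the log-normal device factor
#'   drawn by [generateStudy()].
#' @slot baseline,blurSigma,poissonNoise,readNoiseSd camera model: offset
#'   counts, optical Gaussian blur (px), Poisson shot noise on/off,
#'   Gaussian read noise s.d.
#' @slot frameInterval,duration time-lapse timing in seconds.
#' @slot punctaIntensity,punctaSigma,jitterSd moving-puncta rendering:
#'   amplitude, spot Gaussian radius (um), per-frame localisation jitter
#'   s.d. (um).
#' @slot laneWidth,movieMargin microchannel lane width (um) and how far the
#'   movie extends beyond the barrier into the chambers (um).
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    seed = "integer", fieldSize = "numeric", pixelSize = "numeric",
    neuriteCount = "numeric", neuriteStep = "numeric",
    neuriteWobble = "numeric", neuriteWidthPx = "numeric",
    neuriteIntensity = "numeric", somaDensity = "numeric",
    forwardFraction = "numeric",
    areaSlope = "numeric", areaIntercept = "numeric",
    countSlope = "numeric", countIntercept = "numeric",
    controlArea = "numeric",
    fragmentLengthRange = "numeric", fragmentWidth = "numeric",
    fragmentIntensity = "numeric", distractorLengthRange = "numeric",
    backgroundBlobDensity = "numeric", backgroundBlobIntensity = "numeric",
    backgroundBlobSigma = "numeric", offNeuriteBarCount = "numeric",
    cfseDecay = "character", cfseScale = "numeric", cfseMax = "numeric",
    transferFraction = "numeric",
    deviceFactor = "numeric", deviceCV = "numeric",
    baseline = "numeric", blurSigma = "numeric", poissonNoise = "logical",
    readNoiseSd = "numeric",
    frameInterval = "numeric", duration = "numeric",
    punctaIntensity = "numeric", punctaSigma = "numeric",
    jitterSd = "numeric", laneWidth = "numeric", movieMargin = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  num <- c(object@fieldSize, object@pixelSize, object@neuriteCount,
           object@backgroundBlobDensity, object@somaDensity,
           object@deviceFactor, object@deviceCV, object@readNoiseSd,
           object@frameInterval, object@duration)
  if (any(!is.finite(num)) || any(num < 0))
    msg <- c(msg, "all rates and sizes must be finite and >= 0")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    msg <- c(msg, "pixelSize and frameInterval must be > 0")
  if (!object@cfseDecay %in% c("linear", "exponential"))
    msg <- c(msg, "cfseDecay must be 'linear' or 'exponential'")
  if (object@transferFraction < 0 || object@transferFraction > 1)
    msg <- c(msg, "transferFraction must lie in [0, 1]")
  if (object@forwardFraction < 0 || object@forwardFraction > 1)
    msg <- c(msg, "forwardFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-generator configuration
#'
#' Defaults encode the study conditions the analysis is designed for:
#' detected pathology area growing linearly at 53.828 um^2 per 0.25 mm^2
#' per week (intercept -137.706), total placed fragment count growing at
#' 12.941 per 0.25 mm^2 per week (intercept -16.656), 30% device-level
#' coefficient of variation, CFSE intensity falling linearly to zero 400 um
#' from the microchannels, and burst time-lapse imaging of 10 min at 5 s
#' intervals with puncta moving at around 1 um/s.
#'
#' @param seed master seed.
#' @param ... any slot of [SynthConfig-class] to override.
#' @return a [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 1, fieldSize = c(128, 128))
#' @export
synthConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed), fieldSize = c(256, 256), pixelSize = 0.65,
    neuriteCount = 35, neuriteStep = 2, neuriteWobble = 0.25,
    neuriteWidthPx = c(1, 3), neuriteIntensity = 1200, somaDensity = 4,
    forwardFraction = 1,
    areaSlope = 53.828, areaIntercept = -137.706,
    countSlope = 12.941, countIntercept = -16.656,
    controlArea = 40,
    fragmentLengthRange = c(2, 20), fragmentWidth = 1.2,
    fragmentIntensity = 5000, distractorLengthRange = c(2, 4.5),
    backgroundBlobDensity = 20, backgroundBlobIntensity = 400,
    backgroundBlobSigma = 3, offNeuriteBarCount = 2,
    cfseDecay = "linear", cfseScale = 400, cfseMax = 2500,
    transferFraction = 0,
    deviceFactor = 1, deviceCV = 0.3,
    baseline = 100, blurSigma = 0.6, poissonNoise = TRUE, readNoiseSd = 10,
    frameInterval = 5, duration = 600,
    punctaIntensity = 4000, punctaSigma = 1, jitterSd = 0.2,
    laneWidth = 10, movieMargin = 50)
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown SynthConfig fields: ",
                        paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list(Class = "SynthConfig"), defaults))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  seed %d; field %g x %g um @ %g um/px; %g neurites\n",
              object@seed, object@fieldSize[1L], object@fieldSize[2L],
              object@pixelSize, object@neuriteCount))
  cat(sprintf("  area law: %.3f t %+.3f um^2/0.25mm^2; count law: %.3f t %+.3f\n",
              object@areaSlope, object@areaIntercept, object@countSlope,
              object@countIntercept))
  cat(sprintf("  device factor %.2f (CV %.2f); transfer fraction %.2f\n",
              object@deviceFactor, object@deviceCV,
              object@transferFraction))
  cat(sprintf("  CFSE: %s decay, scale %g um; movie: %g s @ %g s/frame\n",
              object@cfseDecay, object@cfseScale, object@duration,
              object@frameInterval))
})

#' Read or write a generator configuration as YAML
#'
#' @param path file path.
#' @param cfg a [SynthConfig-class] (for writing).
#' @return `readSynthConfig` returns a [SynthConfig-class];
#'   `writeSynthConfig` returns `path` invisibly.
#' @export
readSynthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(synthConfig, y)
}

#' @rdname readSynthConfig
#' @export
writeSynthConfig <- function(cfg, path) {
  slots <- slotNames(cfg)
  obj <- lapply(slots, function(s) slot(cfg, s))
  names(obj) <- slots
  atomicWrite(path, function(tmp) yaml::write_yaml(obj, tmp))
  invisible(path)
}
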