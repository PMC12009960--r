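# Full synthetic studies: devices x timepoints x fields, with truth
# tables for regression-recovery tests.

#' Generate a synthetic multi-device study
#'
#' Emulates a pathology time-course: each device receives a log-normal
#' multiplicative factor (mean 1, CV `cfg@deviceCV`) on its expected
#' metrics, and each of its fields is generated under a per-field child
#' seed derived deterministically from the master seed, so the study is
#' reproducible field-by-field and safe to generate in any order.
#'
#' @param cfg a [SynthConfig-class].
#' @param schedule `data.frame` with columns `device_id` (unique),
#'   `t_weeks`, and optionally `group` (`"pff"` or `"control"`, default
#'   `"pff"`).
#' @param geometry a [DeviceGeometry-class].
#' @param fieldsPerDevice fields imaged per device chamber.
#' @param band a [RoiBand-class]: fields are placed uniformly at random
#'   with their full extent inside this distance band.
#' @param cfse also generate the CFSE channel per field.
#' @param fieldFun optional `function(psyn, tubulin, cfse, truth, field)`
#'   applied to each field as it is generated; only its result is kept
#'   (memory-friendly for large studies). Without it, images and truth are
#'   stored.
#' @return list with `devices` (per device: `device_id`, `t_weeks`,
#'   `group`, `factor`, `fields` — each either the `fieldFun` result or a
#'   list of images plus truth) and `truth`, a `data.frame` with one row
#'   per device: expected and realised detected pathology per 0.25 mm^2.
#' @export
generateStudy <- function(cfg, schedule, geometry = deviceGeometry(),
                          fieldsPerDevice = 5L,
                          band = roiBand("forward", c(400, 1600)),
                          cfse = FALSE, fieldFun = NULL) {
  if (anyDuplicated(schedule$device_id))
    stop("duplicate device IDs in schedule")
  if (is.null(schedule$group)) schedule$group <- "pff"
  nDev <- nrow(schedule)
  factors <- withSeed(childSeed(cfg@seed, 7L), {
    cv <- cfg@deviceCV
    sdl <- sqrt(log(1 + cv^2))
    rlnorm(nDev, meanlog = -sdl^2 / 2, sdlog = sdl)
  })
  fs <- cfg@fieldSize
  b <- geometry@barrier
  devices <- vector("list", nDev)
  truthRows <- vector("list", nDev)
  for (i in seq_len(nDev)) {
    devCfg <- cfg
    devCfg@deviceFactor <- cfg@deviceFactor * factors[i]
    control <- schedule$group[i] == "control"
    fields <- vector("list", fieldsPerDevice)
    realArea <- realCount <- numeric(fieldsPerDevice)
    expArea <- NA_real_
    for (f in seq_len(fieldsPerDevice)) {
      fseed <- childSeed(cfg@seed, i, f)
      # place the field fully inside the band, on the requested side
      off <- withSeed(childSeed(fseed, 3L), {
        dNear <- runif(1, band@range[1L],
                       max(band@range[1L], band@range[2L] - fs[1L]))
        y0 <- runif(1, -fs[2L], 0)
        onLeft <- (band@chamber == "forward") ==
          (geometry@forwardSide == "left")
        if (onLeft) c(b[1L] - dNear - fs[1L], y0)
        else c(b[2L] + dNear, y0)
      })
      fld <- generateNeuriteField(devCfg, geometry, offset = off,
        imageId = sprintf("%s_f%02d", schedule$device_id[i], f),
        seed = childSeed(fseed, 1L))
      pat <- generatePathologyImage(devCfg, fld, schedule$t_weeks[i],
        geometry, control = control, seed = childSeed(fseed, 2L))
      cfseImg <- if (cfse)
        generateCfseChannel(devCfg, fld, geometry,
                            seed = childSeed(fseed, 4L)) else NULL
      md <- S4Vectors::metadata(pat$truth)
      expArea <- md$expected_area_qmm2
      det <- pat$truth$on_neurite & !pat$truth$sub_threshold
      qmm <- prod(fs) / 1e6 / 0.25
      realArea[f] <- sum(pat$truth$area_um2[det]) / qmm
      realCount[f] <- sum(det) / qmm
      fields[[f]] <- if (is.null(fieldFun))
        list(psyn = pat$image, tubulin = fld$image, cfse = cfseImg,
             truth = pat$truth, field = fld)
      else fieldFun(pat$image, fld$image, cfseImg, pat$truth, fld)
    }
    devices[[i]] <- list(device_id = schedule$device_id[i],
                         t_weeks = schedule$t_weeks[i],
                         group = schedule$group[i],
                         factor = factors[i], fields = fields)
    truthRows[[i]] <- data.frame(
      device_id = schedule$device_id[i], t_weeks = schedule$t_weeks[i],
      group = schedule$group[i], device_factor = factors[i],
      expected_area_qmm2 = expArea,
      truth_area_qmm2 = median(realArea),
      truth_count_qmm2 = median(realCount),
      stringsAsFactors = FALSE)
  }
  list(devices = devices, truth = do.call(rbind, truthRows))
}

#' Quantify a synthetic study with the image pipeline
#'
#' Runs the full truth-free detection chain (threshold, colocalise,
#' extract, filter, summarise, Grubbs-filtered chamber median) over every
#' device of a study generated by [generateStudy()] — or generates fields
#' on the fly via `fieldFun` when given a schedule — and returns one row
#' per device, ready for [linearTrend()].
#'
#' @param cfg a [SynthConfig-class].
#' @param schedule study schedule (see [generateStudy()]).
#' @param geometry a [DeviceGeometry-class].
#' @param params a [SegmentationParams-class]; the default uses manual
#'   thresholds matched to the generator's amplitudes
#'   (`psyn` 1900, `tubulin` 700, `cfse` 450).
#' @param fieldsPerDevice,band passed to [generateStudy()].
#' @param alpha Grubbs significance level for the chamber medians.
#' @return `data.frame` with one row per device: `device_id`, `t_weeks`,
#'   `group`, `area_per_qmm2`, `frags_per_qmm2`, `pct_neurite`.
#' @export
quantifyStudy <- function(cfg, schedule, geometry = deviceGeometry(),
                          params = studyParams(),
                          fieldsPerDevice = 5L,
                          band = roiBand("forward", c(400, 1600)),
                          alpha = 0.05) {
  fieldFun <- function(psyn, tubulin, cfseImg, truth, fld) {
    pm <- thresholdMask(psyn, params)
    tm <- thresholdMask(tubulin, params)
    fr <- extractFragments(pm, tm, geometry, params,
                           offset = psyn@offset,
                           pixelSize = psyn@pixelSize,
                           imageId = psyn@imageId, computeLength = FALSE)
    roi <- makeRoiMask(geometry, band, psyn)
    summarizeField(fr, roi, tm, geometry, pixelSize = psyn@pixelSize,
                   offset = psyn@offset, imageId = psyn@imageId)
  }
  study <- generateStudy(cfg, schedule, geometry, fieldsPerDevice,
                         band = band, fieldFun = fieldFun)
  rows <- lapply(study$devices, function(dev) {
    fields <- do.call(rbind, dev$fields)
    agg <- aggregateChamber(fields, alpha = alpha,
                            deviceId = dev$device_id,
                            chamber = band@chamber)
    data.frame(device_id = dev$device_id, t_weeks = dev$t_weeks,
               group = dev$group,
               area_per_qmm2 = agg$area_per_qmm2,
               frags_per_qmm2 = agg$frags_per_qmm2,
               pct_neurite = agg$pct_neurite,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- study$truth
  out
}

#' Segmentation parameters matched to the synthetic generator
#'
#' Manual thresholds sitting halfway between the generator's background and
#' signal plateaus for each channel (thresholds for this assay are tuned
#' per experiment, so the synthetic study carries its own).
#'
#' @param ... overrides passed to [segmentationParams()].
#' @return a [SegmentationParams-class].
#' @export
studyParams <- function(...) {
  segmentationParams(thresholdMethod = "manual",
                     manualLevel = c(psyn = 1900, tubulin = 700,
                                     cfse = 450), ...)
}
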