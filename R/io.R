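# File I/O and the end-to-end assay runners: pathology time-course,
# CFSE transport-vs-transfer, kymograph transport.

#' Read a TIFF image or stack as field images
#'
#' Single- or multi-page, 8/16-bit TIFF. Intensities are returned in
#' native counts (the tiff package's \[0, 1\] scaling is undone using the
#' stored bit depth). The calibration must come from a sidecar or the
#' caller: a missing `pixelSize` is a hard error naming the missing key.
#'
#' @param path TIFF file.
#' @param channel channel label for a single-page file, or a character
#'   vector mapping pages to channels (e.g. `c("psyn", "tubulin",
#'   "cfse")`); pages of a movie should use `"movie_frame"`.
#' @param pixelSize um/px; may be omitted only if a JSON sidecar
#'   `<path>.json` with a `pixel_size` key exists.
#' @param offset device-coordinate origin in um (sidecar key `offset`).
#' @param imageId identifier prefix.
#' @return a [FieldImage-class] for a single page; a list of them for a
#'   multi-page channel stack; a 3D array `[y, x, frame]` with attributes
#'   `pixelSize` and `offset` when `channel = "movie_frame"`.
#' @export
readStack <- function(path, channel = "psyn", pixelSize = NULL,
                      offset = NULL, imageId = basename(path)) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  pixelSize <- pixelSize %||% meta$pixel_size
  if (is.null(pixelSize))
    stop("pixel_size required: not supplied and no sidecar for ", path)
  offset <- offset %||% meta$offset %||% c(0, 0)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # greyscale written as RGB
    storage.mode(p) <- "double"
    p
  })
  if (identical(channel, "movie_frame") ||
      (length(channel) == 1L && length(pages) > 3L)) {
    movie <- simplify2array(pages)
    attr(movie, "pixelSize") <- pixelSize
    attr(movie, "offset") <- as.numeric(offset)
    return(movie)
  }
  channel <- rep_len(channel, length(pages))
  if (length(unique(channel)) != length(pages) && length(pages) > 1L &&
      length(unique(channel)) != 1L)
    stop("channel mapping does not match page count in ", path)
  imgs <- lapply(seq_along(pages), function(i)
    fieldImage(pages[[i]], channel[i], pixelSize, as.numeric(offset),
               paste0(imageId, "_", channel[i])))
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Write field images or a movie as a (multi-page) TIFF
#'
#' 16-bit output; a JSON sidecar `<path>.json` records `pixel_size` and
#' `offset` so the stack can be read back placed in device coordinates.
#'
#' @param x a [FieldImage-class], a list of them, or a 3D movie array.
#' @param path output path.
#' @param pixelSize,offset calibration for plain arrays.
#' @return `path`, invisibly.
#' @export
writeStack <- function(x, path, pixelSize = NULL, offset = c(0, 0)) {
  if (is(x, "FieldImage")) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    pages <- lapply(seq_len(dim(x)[3L]), function(f) x[, , f])
    pixelSize <- pixelSize %||% attr(x, "pixelSize")
    offset <- attr(x, "offset") %||% offset
  } else {
    pages <- lapply(x, imageData)
    pixelSize <- pixelSize %||% x[[1L]]@pixelSize
    offset <- x[[1L]]@offset
  }
  pages <- lapply(pages, function(p) {
    p <- pmin(pmax(p, 0), 65535) / 65535
    p
  })
  atomicWrite(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = 16L))
  atomicWrite(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(list(pixel_size = pixelSize,
                              offset = as.numeric(offset)),
                         tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Write a generated study to disk as TIFFs plus metadata
#'
#' Lays out `<dir>/<device>/<field>.tif` multi-page stacks (pSyn, tubulin
#' and CFSE when present), the geometry JSON, the generator configuration
#' YAML and the device truth table CSV, producing a self-describing
#' directory that [runQuantify()] can consume.
#'
#' @param study output of [generateStudy()] (with images kept).
#' @param dir output directory.
#' @param cfg the [SynthConfig-class] used.
#' @param geometry the [DeviceGeometry-class] used.
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir, cfg, geometry) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGeometry(geometry, file.path(dir, "geometry.json"))
  writeSynthConfig(cfg, file.path(dir, "synth_config.yaml"))
  atomicWrite(file.path(dir, "truth.csv"), function(tmp)
    write.csv(study$truth, tmp, row.names = FALSE))
  for (dev in study$devices) {
    ddir <- file.path(dir, dev$device_id)
    dir.create(ddir, showWarnings = FALSE)
    for (f in seq_along(dev$fields)) {
      fl <- dev$fields[[f]]
      imgs <- list(fl$psyn, fl$tubulin)
      if (!is.null(fl$cfse)) imgs <- c(imgs, list(fl$cfse))
      writeStack(imgs, file.path(ddir, sprintf("field%02d.tif", f)))
    }
  }
  invisible(dir)
}

#' Read a run configuration YAML
#'
#' Keys: `geometry` (path to geometry JSON), `images` (directory laid out
#' as by [writeStudy()]), `out` (output directory), `assay`, `band`
#' (`chamber`, `range`), `params` (threshold method/levels, `min_area`,
#' `coloc_fraction`, `connectivity`), `alpha`, `channels` (page order,
#' default `psyn`, `tubulin`, `cfse`), `lanes` and `frame_interval` for
#' kymograph runs, `seed`.
#'
#' @param path YAML file.
#' @return a named list with parsed `geometry`, `params` and `band`
#'   objects alongside the raw fields.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base, p)
  y$geometry_path <- resolve(y$geometry)
  y$geometry <- readGeometry(y$geometry_path)
  p <- y$params %||% list()
  y$params <- segmentationParams(
    thresholdMethod = p$threshold_method %||% "otsu",
    manualLevel = unlist(p$manual_level %||%
      list(psyn = NA_real_, tubulin = NA_real_, cfse = NA_real_)),
    minArea = p$min_area %||% 8,
    colocFraction = p$coloc_fraction %||% 0.5,
    dilationRadius = p$dilation_radius %||% 1L,
    connectivity = p$connectivity %||% 8L,
    cfseFraction = p$cfse_fraction %||% 0.5)
  y$bandSet <- !is.null(y$band)
  bd <- y$band %||% list()
  y$band <- roiBand(bd$chamber %||% "forward",
                    as.numeric(bd$range %||% c(400, 1600)))
  y$alpha <- y$alpha %||% 0.05
  y$channels <- unlist(y$channels %||% c("psyn", "tubulin", "cfse"))
  y$images <- resolve(y$images)
  y
}

# Device directories: immediate subdirectories that contain TIFF fields.
deviceDirs <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs[vapply(dirs, function(d)
    length(list.files(d, pattern = "\\.tiff?$")) > 0L, NA)]
}

# Load all fields of one device directory as lists of channel images.
readDeviceFields <- function(ddir, channels) {
  tifs <- sort(list.files(ddir, pattern = "\\.tiff?$", full.names = TRUE))
  lapply(tifs, function(tf) {
    imgs <- readStack(tf, channel = channels,
                      imageId = paste0(basename(ddir), "_",
                                       sub("\\.tiff?$", "", basename(tf))))
    if (is(imgs, "FieldImage")) imgs <- list(imgs)
    names(imgs) <- vapply(imgs, channelType, "")[seq_along(imgs)]
    imgs
  })
}

# Shared per-device quantification used by runQuantify / runCfse.
quantifyDevice <- function(fieldsImgs, geometry, params, band, alpha,
                           cfse = FALSE, deviceId = "device") {
  fieldRows <- list()
  frags <- list()
  for (imgs in fieldsImgs) {
    psyn <- imgs[["psyn"]]; tub <- imgs[["tubulin"]]
    pm <- thresholdMask(psyn, params)
    tm <- thresholdMask(tub, params)
    fr <- extractFragments(pm, tm, geometry, params, offset = psyn@offset,
                           pixelSize = psyn@pixelSize,
                           imageId = psyn@imageId)
    if (cfse) {
      if (is.null(imgs[["cfse"]]))
        stop("CFSE channel missing for image ", psyn@imageId)
      cm <- thresholdMask(imgs[["cfse"]], params)
      fr <- classifyCfse(fr, cm, params,
                         band = roiBand(band@chamber, band@range))
    }
    roi <- makeRoiMask(geometry, band, psyn)
    fieldRows[[length(fieldRows) + 1L]] <-
      summarizeField(fr, roi, tm, geometry, pixelSize = psyn@pixelSize,
                     offset = psyn@offset, imageId = psyn@imageId)
    fdf <- as.data.frame(fr[, setdiff(colnames(fr), "pixels")])
    fdf$threshold_psyn <- rep(attr(pm, "threshold"), nrow(fdf))
    frags[[length(frags) + 1L]] <- fdf
  }
  fields <- do.call(rbind, fieldRows)
  list(summary = aggregateChamber(fields, alpha = alpha,
                                  deviceId = deviceId,
                                  chamber = band@chamber),
       fields = fields,
       fragments = do.call(rbind, frags))
}

#' Run the pathology quantification assay
#'
#' Composes threshold, colocalisation, fragment extraction, per-field
#' summary and Grubbs-filtered chamber medians over every device directory
#' under the configured image root. A failing device is logged and
#' skipped; the others proceed. All tables are written atomically.
#'
#' @param config path to a run-configuration YAML (see [readRunConfig()])
#'   or an already-parsed list.
#' @return invisibly, a list with `summaries` (device x chamber table),
#'   `fields`, `fragments` and `errors` (named list of device failures).
#' @export
runQuantify <- function(config) {
  cfgr <- if (is.character(config)) readRunConfig(config) else config
  devDirs <- deviceDirs(cfgr$images)
  if (!length(devDirs)) stop("no device directories under ", cfgr$images)
  summaries <- list(); fields <- list(); fragments <- list()
  errors <- list()
  for (ddir in devDirs) {
    id <- basename(ddir)
    res <- tryCatch({
      imgs <- readDeviceFields(ddir, cfgr$channels)
      if (length(imgs) < 3L) stop("need >= 3 fields per chamber")
      quantifyDevice(imgs, cfgr$geometry, cfgr$params, cfgr$band,
                     cfgr$alpha, deviceId = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("device ", id, " failed: ", conditionMessage(res))
      errors[[id]] <- conditionMessage(res)
      next
    }
    summaries[[id]] <- res$summary
    fields[[id]] <- res$fields
    fragments[[id]] <- cbind(device_id = id, res$fragments)
  }
  out <- list(summaries = do.call(rbind, summaries),
              fields = do.call(rbind, fields),
              fragments = do.call(rbind, fragments),
              errors = errors)
  if (!is.null(cfgr$out)) {
    dir.create(cfgr$out, recursive = TRUE, showWarnings = FALSE)
    atomicWrite(file.path(cfgr$out, "chamber_summaries.csv"), function(t)
      write.csv(out$summaries, t, row.names = FALSE))
    atomicWrite(file.path(cfgr$out, "field_metrics.csv"), function(t)
      write.csv(out$fields, t, row.names = FALSE))
    atomicWrite(file.path(cfgr$out, "fragments.csv"), function(t)
      write.csv(out$fragments, t, row.names = FALSE))
  }
  invisible(out)
}

#' Run the CFSE transport-versus-transfer assay
#'
#' Restricts analysis to the near-channel band (default 0-400 um in the
#' reverse chamber, where the CFSE signal is reliable), classifies every
#' fragment as CFSE-positive (transported inside forward-originating
#' axons) or CFSE-negative (transferred to reverse-native neurites), and
#' reports area and count per 0.25 mm^2 for each class per device.
#'
#' @param config run-configuration path or list; `band` defaults to the
#'   reverse chamber, 0-400 um.
#' @return invisibly, a `data.frame` with one row per device:
#'   `cfse_positive_area_qmm2`, `cfse_negative_area_qmm2`,
#'   `cfse_positive_frags_qmm2`, `cfse_negative_frags_qmm2`.
#' @export
runCfse <- function(config) {
  cfgr <- if (is.character(config)) readRunConfig(config) else config
  if (!isTRUE(cfgr$bandSet))
    cfgr$band <- roiBand("reverse", c(0, 400))
  devDirs <- deviceDirs(cfgr$images)
  rows <- list()
  for (ddir in devDirs) {
    id <- basename(ddir)
    imgs <- readDeviceFields(ddir, cfgr$channels)
    if (!all(vapply(imgs, function(x) "cfse" %in% names(x), NA)))
      stop("CFSE channel missing in device ", id)
    perField <- lapply(imgs, function(im) {
      pm <- thresholdMask(im$psyn, cfgr$params)
      tm <- thresholdMask(im$tubulin, cfgr$params)
      cm <- thresholdMask(im$cfse, cfgr$params)
      fr <- extractFragments(pm, tm, cfgr$geometry, cfgr$params,
                             offset = im$psyn@offset,
                             pixelSize = im$psyn@pixelSize,
                             imageId = im$psyn@imageId,
                             computeLength = FALSE)
      fr <- classifyCfse(fr, cm, cfgr$params, band = cfgr$band)
      roi <- makeRoiMask(cfgr$geometry, cfgr$band, im$psyn)
      roiMm2 <- sum(roi) * im$psyn@pixelSize^2 / 1e6
      sc <- 0.25 / roiMm2
      ev <- fr$cfse_status != "unevaluated"
      pos <- ev & fr$cfse_status == "positive"
      neg <- ev & fr$cfse_status == "negative"
      c(posArea = sum(fr$area_um2[pos]) * sc,
        negArea = sum(fr$area_um2[neg]) * sc,
        posN = sum(pos) * sc, negN = sum(neg) * sc, evaluated = sum(ev))
    })
    m <- do.call(rbind, perField)
    if (sum(m[, "evaluated"]) == 0)
      warning("device ", id, ": no fragments within the CFSE band")
    rows[[id]] <- data.frame(
      device_id = id,
      cfse_positive_area_qmm2 = median(m[, "posArea"]),
      cfse_negative_area_qmm2 = median(m[, "negArea"]),
      cfse_positive_frags_qmm2 = median(m[, "posN"]),
      cfse_negative_frags_qmm2 = median(m[, "negN"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(cfgr$out)) {
    dir.create(cfgr$out, recursive = TRUE, showWarnings = FALSE)
    atomicWrite(file.path(cfgr$out, "cfse_summary.csv"), function(t)
      write.csv(out, t, row.names = FALSE))
  }
  invisible(out)
}

#' Run the kymograph transport assay
#'
#' Builds one kymograph per configured lane (maximum projection over the
#' lane width, excluding leaf polygons), detects puncta traces, and
#' reports per-lane trace tables plus direction and exit counts.
#'
#' @param config run-configuration path or list; requires `movie` (TIFF
#'   stack path or 3D array), `frame_interval` (s) and lanes on the
#'   geometry (or a `lanes` list of y-intervals).
#' @return invisibly, a list with `traces` (all lanes), `counts`
#'   (per-direction trace counts and exits) and `kymographs`.
#' @export
runKymo <- function(config) {
  cfgr <- if (is.character(config)) readRunConfig(config) else config
  movie <- cfgr$movie
  offset <- cfgr$offset %||% c(0, 0)
  if (is.character(movie)) {
    movie <- readStack(if (file.exists(movie)) movie
                       else file.path(dirname(cfgr$geometry_path), movie),
                       channel = "movie_frame")
    offset <- attr(movie, "offset")
  }
  lanes <- cfgr$lanes %||% channelLanes(cfgr$geometry)
  if (!length(lanes)) stop("no lanes defined")
  if (!is.list(lanes)) lanes <- list(as.numeric(lanes))
  fi <- cfgr$frame_interval %||% cfgr$frameInterval
  if (is.null(fi)) stop("frame_interval required")
  px <- cfgr$pixel_size %||% attr(movie, "pixelSize") %||%
    pixelSize(cfgr$geometry)
  kymos <- list(); traces <- list()
  for (li in seq_along(lanes)) {
    ky <- buildKymograph(movie, as.numeric(lanes[[li]]), cfgr$geometry,
                         frameInterval = fi, pixelSize = px,
                         offset = offset, laneId = li)
    tr <- detectTraces(ky)
    kymos[[li]] <- ky
    traces[[li]] <- tr
  }
  allTr <- do.call(rbind, traces)
  counts <- data.frame(
    retrograde = sum(allTr$direction == "retrograde"),
    anterograde = sum(allTr$direction == "anterograde"),
    stationary = sum(allTr$direction == "stationary"),
    exited = sum(allTr$exited))
  if (!is.null(cfgr$out)) {
    dir.create(cfgr$out, recursive = TRUE, showWarnings = FALSE)
    tout <- allTr[, setdiff(names(allTr), "samples")]
    atomicWrite(file.path(cfgr$out, "traces.csv"), function(t)
      write.csv(tout, t, row.names = FALSE))
    atomicWrite(file.path(cfgr$out, "trace_counts.csv"), function(t)
      write.csv(counts, t, row.names = FALSE))
  }
  invisible(list(traces = allTr, counts = counts, kymographs = kymos))
}
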