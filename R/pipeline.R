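# Recognized configuration schema: block -> allowed keys.
pipelineSchema <- list(
  seed = NULL,
  voxel_size_mm = NULL,
  pixel_size_mm = NULL,
  paths = c("volume", "section", "out_dir"),
  detection = c("n_sample", "block_size", "offset", "canny_low", "canny_high",
                "morph_radius", "max_eccentricity", "min_contour_points",
                "refine", "n_cones"),
  calibration = c("n_cones", "residual_threshold_mm"),
  matching = c("layout"),
  plane = c("out_rows", "out_cols", "pitch_mm", "fill_value"),
  register = c("max_shift_px", "max_rotation_deg", "levels"),
  metric = c("window_px", "checkerboard_tile_px")
)

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration (or validates an already-parsed list) against
#' the pipeline schema; unknown blocks or keys are rejected so that typos
#' fail before any stage runs.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("configuration must be a YAML file or a list")
  unknown <- setdiff(names(config), names(pipelineSchema))
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    allowed <- pipelineSchema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(config$paths$volume) || is.null(config$paths$section) ||
      is.null(config$paths$out_dir))
    stop("paths: volume, section and out_dir are required")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

cfgGet <- function(config, block, key, default) {
  v <- config[[block]][[key]]
  if (is.null(v)) default else v
}

withStage <- function(stage, hint, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s (%s)", stage, conditionMessage(e), hint),
         call. = FALSE)
  })
}

stageLog <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full fusion pipeline
#'
#' Executes detect, calibrate, locate-markers, extract-plane, register and
#' score on the configured volume and section image, writing all
#' intermediates (detections CSV, calibration JSON, markers JSON, extracted
#' plane and heatmap TIFF, checkerboard PNG) plus a `summary.json` into the
#' output directory. Given a seed the run is deterministic.
#'
#' @param config YAML path or list, see [readPipelineConfig()].
#' @param verbose log stage progress (default TRUE).
#' @return the summary list, invisibly: plane embedding, rigid transform,
#'   LNCC mean/max.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  config <- readPipelineConfig(config)
  outDir <- config$paths$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  volume <- withStage("read-volume", "check paths.volume and the voxel size",
    readVolume(config$paths$volume, voxelSize = config$voxel_size_mm))
  section <- withStage("read-section", "check paths.section and the pixel size",
    readSectionImage(config$paths$section, pixelSize = config$pixel_size_mm))
  vs <- voxelSize(volume)
  nCones <- cfgGet(config, "detection", "n_cones", 3L)

  params <- detectionParams(
    blockSize = cfgGet(config, "detection", "block_size", 51L),
    offset = cfgGet(config, "detection", "offset", 0.02),
    cannyLow = cfgGet(config, "detection", "canny_low", 0.1),
    cannyHigh = cfgGet(config, "detection", "canny_high", 0.3),
    morphRadius = cfgGet(config, "detection", "morph_radius", 2L),
    maxEccentricity = cfgGet(config, "detection", "max_eccentricity", 0.9),
    minContourPoints = cfgGet(config, "detection", "min_contour_points", 10L),
    pixelSize = vs
  )
  stageLog(verbose, "detect", "sampling %d slices (seed %d), block %d px",
           cfgGet(config, "detection", "n_sample", 100L), seed,
           params$blockSize)
  dets <- withStage("detect", "inspect the volume contrast and detection block size",
    detectConeSections(volume,
      nSample = cfgGet(config, "detection", "n_sample", 100L),
      seed = seed, params = params, nCones = nCones,
      refine = cfgGet(config, "detection", "refine", TRUE)))
  writeDetections(dets, file.path(outDir, "detections.csv"))

  stageLog(verbose, "calibrate", "%d detections -> %d cones", nrow(dets), nCones)
  calib <- withStage("calibrate", "check that all cones are visible in the sampled slices",
    calibrateCones(dets, pixelSize = vs,
      nCones = cfgGet(config, "calibration", "n_cones", nCones),
      residualThreshold = config$calibration$residual_threshold_mm))
  writeCalibration(calib$models, file.path(outDir, "calibration.json"))

  stageLog(verbose, "locate-markers", "detecting section ellipses")
  secDet <- withStage("locate-markers", "check section contrast / detection parameters",
    detectSectionEllipses(section, detectionParams(pixelSize = pixelSize(section)),
                          expectedCones = nCones))
  layout <- config$matching$layout
  if (is.null(layout)) {
    layout <- do.call(rbind, lapply(calib$tracks, meanCenter))
    rownames(layout) <- vapply(calib$tracks, coneId, integer(1))
  } else {
    layout <- do.call(rbind, lapply(layout, unlist))
  }
  markers <- withStage("locate-markers", "provide matching.layout if the default is ambiguous",
    matchToCones(secDet, layout, pixelSize = pixelSize(section)))
  jsonlite::write_json(
    list(ellipses = markers@ellipses,
         assignment = as.list(markers@assignment),
         pixel_size_mm = markers@pixelSize),
    file.path(outDir, "markers.json"), auto_unbox = TRUE, digits = NA)

  stageLog(verbose, "extract-plane", "locating cone points and embedding")
  pts3d <- withStage("extract-plane", "calibration may not cover the section widths",
    locateConePoints(markers, calib$models, vs))
  sec2d <- cbind(markers@ellipses$cx[markers@assignment],
                 markers@ellipses$cy[markers@assignment]) * pixelSize(section)
  embedding <- withStage("extract-plane", "matched points may be collinear",
    buildEmbedding(sec2d, pts3d))
  outShape <- c(cfgGet(config, "plane", "out_rows", dim(volume@data)[2]),
                cfgGet(config, "plane", "out_cols", dim(volume@data)[3]))
  plane <- withStage("extract-plane", "check plane.out_rows/out_cols",
    extractObliqueSlice(volume, embedding, outShape = outShape,
      pitch = cfgGet(config, "plane", "pitch_mm", vs),
      fillValue = cfgGet(config, "plane", "fill_value", 0)))
  writeSectionImage(plane, file.path(outDir, "plane.tif"))
  jsonlite::write_json(
    list(origin_mm = embedding@origin, basis_u = embedding@basisU,
         basis_v = embedding@basisV, normal = embedding@normal,
         correspondences = embedding@correspondences),
    file.path(outDir, "embedding.json"), auto_unbox = TRUE, digits = NA)

  # resample the section to the plane pitch before rigid registration
  pitch <- cfgGet(config, "plane", "pitch_mm", vs)
  movScale <- pixelSize(section) / pitch
  stageLog(verbose, "register", "rigid MSE registration (scale %.4g)", movScale)
  reg <- withStage("register", "check the initial overlap / plane extraction",
    rigidRegister(section@data, plane@data,
      init = rigidTransform2D(scale = movScale),
      maxShift = cfgGet(config, "register", "max_shift_px", 12),
      maxRotation = cfgGet(config, "register", "max_rotation_deg", 6),
      levels = cfgGet(config, "register", "levels", 3L)))

  window <- as.integer(cfgGet(config, "metric", "window_px", 45L))
  stageLog(verbose, "score", "LNCC window %d px", window)
  resampled <- reg$resampled
  resampled[is.na(resampled)] <- 0
  score <- withStage("score", "window may exceed the image size",
    lncc(normalize01(plane@data), resampled, window))
  writeSectionImage(sectionImage(score@heatmap, pitch),
                    file.path(outDir, "lncc_heatmap.tif"))
  tile <- as.integer(cfgGet(config, "metric", "checkerboard_tile_px", 32L))
  cb <- overlayCheckerboard(normalize01(plane@data), resampled, tile)
  png::writePNG(normalize01(cb), file.path(outDir, "checkerboard.png"))

  summary <- list(
    seed = seed,
    plane = list(origin_mm = embedding@origin, normal = embedding@normal,
                 basis_u = embedding@basisU, basis_v = embedding@basisV),
    rigid_transform = list(rotation_deg = reg$transform@rotation,
                           translation_px = reg$transform@translation,
                           scale = reg$transform@scale, mse = reg$mse),
    lncc = list(window_px = window, mean = score@meanLNCC,
                max = score@maxLNCC)
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
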