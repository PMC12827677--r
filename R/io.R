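sidecarPath <- function(path) paste0(path, ".json")

#' Write a volume as multi-page 32-bit float TIFF with a JSON sidecar
#'
#' Volumes are stored one z slice per TIFF page with 32-bit samples. Because
#' TIFF storage here is defined on `[0, 1]`, data outside that range are
#' min-max normalized and the original bounds recorded in the sidecar
#' (`<path>.json`, which also carries the voxel size); [readVolume()]
#' restores the original scale. Data within `[0, 1]` are written unchanged
#' and round-trip exactly up to the 32-bit sample quantization (one part in
#' 2^32, about 2.4e-10).
#'
#' @param volume [VoxelVolume-class].
#' @param path output file, e.g. `volume.tif`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  arr <- volume@data
  r <- range(arr)
  normalized <- r[1] < 0 || r[2] > 1
  if (normalized) {
    arr <- if (r[2] > r[1]) (arr - r[1]) / (r[2] - r[1]) else arr * 0
  }
  pages <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(voxel_size_mm = volume@voxelSize,
         intensity_min = r[1], intensity_max = r[2],
         normalized = normalized),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF or a directory of slice TIFFs
#'
#' Accepts either a multi-page TIFF or a directory of single-page TIFFs
#' (z-sorted by file name). The voxel size comes from the JSON sidecar
#' written by [writeVolume()] or, for foreign files, from the `voxelSize`
#' argument. Intensities normalized at write time are restored to their
#' recorded bounds.
#'
#' @param path TIFF file or directory.
#' @param voxelSize mm; overrides/replaces the sidecar value.
#' @return a [VoxelVolume-class].
#' @export
readVolume <- function(path, voxelSize = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE)
      if (length(p) != 1L)
        stop("slice file with multiple pages: ", f)
      p[[1]]
    })
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent slice dimensions in file ",
           files[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]])
    side <- sidecarPath(path)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    side <- sidecarPath(path)
  }
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  vs <- if (!is.null(voxelSize)) voxelSize else meta$voxel_size_mm
  if (is.null(vs))
    stop("voxel size unknown: no sidecar found, pass voxelSize=")
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (k in seq_along(pages)) {
    if (!all(dim(pages[[k]]) == dim(pages[[1]])))
      stop(sprintf("inconsistent slice dimensions at page %d", k))
    arr[k, , ] <- pages[[k]]
  }
  if (isTRUE(meta$normalized)) {
    lo <- meta$intensity_min; hi <- meta$intensity_max
    arr <- arr * (hi - lo) + lo
  }
  voxelVolume(arr, vs)
}

#' Write a section image (16-bit PNG/TIFF or float TIFF) with sidecar
#'
#' @param image [SectionImage-class].
#' @param path `.tif`/`.tiff` (32-bit samples, as [writeVolume()]; the
#'   quantitative path) or `.png` (8-bit preview, min-max normalized with
#'   bounds recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
writeSectionImage <- function(image, path) {
  stopifnot(is(image, "SectionImage"))
  m <- image@data
  r <- range(m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    mn <- if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
    png::writePNG(mn, path, dpi = NULL)
    normalized <- TRUE
  } else {
    normalized <- r[1] < 0 || r[2] > 1
    mw <- if (normalized) {
      if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
    } else m
    tiff::writeTIFF(mw, path, bits.per.sample = 32L, reduce = FALSE)
  }
  jsonlite::write_json(
    list(pixel_size_mm = image@pixelSize, intensity_min = r[1],
         intensity_max = r[2], normalized = normalized),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a section image written by [writeSectionImage()] or a foreign PNG/TIFF
#'
#' @param path image file.
#' @param pixelSize mm; overrides/replaces the sidecar value.
#' @return a [SectionImage-class].
#' @export
readSectionImage <- function(path, pixelSize = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of RGB(A)
  side <- sidecarPath(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  ps <- if (!is.null(pixelSize)) pixelSize else meta$pixel_size_mm
  if (is.null(ps))
    stop("pixel size unknown: no sidecar found, pass pixelSize=")
  if (isTRUE(meta$normalized)) {
    lo <- meta$intensity_min; hi <- meta$intensity_max
    m <- m * (hi - lo) + lo
  }
  sectionImage(m, ps)
}

#' Write / read detection tables as CSV
#'
#' Plain CSV with the detection columns (slice_index, cx, cy, major, minor,
#' angle, source), readable without the package.
#'
#' @param detections detection data.frame.
#' @param path CSV file.
#' @return `path` (write) / data.frame (read).
#' @export
writeDetections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read taper calibrations as JSON
#'
#' One record per cone: slope, intercept, residual threshold, inlier count,
#' center drift coefficients and calibrated width range.
#'
#' @param models list of [TaperModel-class].
#' @param path JSON file.
#' @return `path` (write) / list of [TaperModel-class] (read).
#' @export
writeCalibration <- function(models, path) {
  recs <- lapply(models, function(m) list(
    cone_id = m@coneId, slope_mm_per_slice = m@slope, intercept_mm = m@intercept,
    residual_threshold_mm = m@residualThreshold, inlier_count = m@inlierCount,
    center_drift = list(cx = as.list(stats::setNames(m@centerDrift["cx", ],
                                                     c("intercept", "slope"))),
                        cy = as.list(stats::setNames(m@centerDrift["cy", ],
                                                     c("intercept", "slope")))),
    width_range_mm = m@widthRange))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    drift <- rbind(cx = c(r$center_drift$cx$intercept, r$center_drift$cx$slope),
                   cy = c(r$center_drift$cy$intercept, r$center_drift$cy$slope))
    colnames(drift) <- c("intercept", "slope")
    new("TaperModel", coneId = as.integer(r$cone_id),
        slope = r$slope_mm_per_slice, intercept = r$intercept_mm,
        residualThreshold = r$residual_threshold_mm,
        inlierCount = as.integer(r$inlier_count), centerDrift = drift,
        widthRange = as.numeric(unlist(r$width_range_mm)))
  })
}
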