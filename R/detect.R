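#' Parameters for the rule-based conic-section detector
#'
#' Bundles the tunables of the slice-wise detection chain (adaptive threshold,
#' Canny edge detection, morphology, ellipse filtering). None of these values
#' are universal; the defaults work on the bundled phantom renderer and are
#' all exposed for configuration. When `pixelSize` is supplied the ellipse
#' area bounds are derived from the cone geometry (`coneDiameters`): minimum
#' half the apex disc area, maximum twice the base disc area.
#'
#' @param blockSize odd adaptive-threshold window edge, px (default 51).
#' @param offset adaptive-threshold offset as a fraction of the image dynamic
#'   range (default 0.02).
#' @param cannyLow,cannyHigh hysteresis thresholds as fractions of the
#'   maximum gradient magnitude (defaults 0.1, 0.3).
#' @param morphRadius disc radius for morphological opening/closing, px
#'   (default 2).
#' @param areaBounds numeric(2), accepted ellipse area range in px^2
#'   (default derived from geometry, or c(20, 1e6)).
#' @param maxEccentricity maximum accepted eccentricity
#'   \eqn{\sqrt{1 - (b/a)^2}} (default 0.9).
#' @param minContourPoints minimum boundary points for a fit (default 10).
#' @param pixelSize optional mm/px used to derive `areaBounds`.
#' @param coneDiameters numeric(2) (base, apex) mm used with `pixelSize`
#'   (default c(3, 0.5)).
#' @return a named list of validated parameters.
#' @export
detectionParams <- function(blockSize = 51, offset = 0.02, cannyLow = 0.1,
                            cannyHigh = 0.3, morphRadius = 2,
                            areaBounds = NULL, maxEccentricity = 0.9,
                            minContourPoints = 10, pixelSize = NULL,
                            coneDiameters = c(3, 0.5)) {
  blockSize <- as.integer(blockSize)
  if (blockSize < 3L || blockSize %% 2L == 0L)
    stop("blockSize must be odd and >= 3")
  if (cannyLow >= cannyHigh) stop("cannyLow must be < cannyHigh")
  if (is.null(areaBounds)) {
    areaBounds <- if (!is.null(pixelSize)) {
      rb <- coneDiameters[1] / 2 / pixelSize
      ra <- coneDiameters[2] / 2 / pixelSize
      c(0.5 * pi * ra^2, 2 * pi * rb^2)
    } else c(20, 1e6)
  }
  if (any(areaBounds <= 0) || areaBounds[1] >= areaBounds[2])
    stop("areaBounds must be positive and increasing")
  list(blockSize = blockSize, offset = offset, cannyLow = cannyLow,
       cannyHigh = cannyHigh, morphRadius = as.integer(morphRadius),
       areaBounds = areaBounds, maxEccentricity = maxEccentricity,
       minContourPoints = as.integer(minContourPoints))
}

#' Randomly sample slice indices from a stack
#'
#' Draws `nSample` unique slice indices (0-based, sorted) without
#' replacement, the subsampling strategy used to keep full-stack processing
#' tractable: parameters measured on the sampled slices are interpolated
#' across the unsampled layers by the taper model.
#'
#' @param nTotal number of slices in the stack.
#' @param nSample number of slices to draw (`0 < nSample <= nTotal`).
#' @param seed integer seed; the draw is deterministic per seed.
#' @return sorted integer vector of 0-based slice indices.
#' @examples
#' idx <- sampleSliceIndices(1982, 500, seed = 7)
#' length(unique(idx))  # 500
#' @export
sampleSliceIndices <- function(nTotal, nSample, seed) {
  stopifnot(nTotal >= 1)
  if (nSample <= 0 || nSample > nTotal)
    stop(sprintf("nSample must be in [1, %d]", nTotal))
  withSeed(seed, sort(sample.int(nTotal, nSample)) - 1L)
}

emptyDetections <- function() {
  data.frame(slice_index = integer(), cx = numeric(), cy = numeric(),
             major = numeric(), minor = numeric(), angle = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Detect conic cross-sections in one slice (rule-based chain)
#'
#' Applies, in order: adaptive thresholding, Canny edge detection,
#' morphological opening then closing, contour extraction, and a direct
#' least-squares ellipse fit per contour; fits outside the area bounds or
#' above the eccentricity cut are rejected. Candidate boundaries come from
#' the connected components of the cleaned threshold mask; where Canny edge
#' pixels trace a component's rim they replace the raw contour, giving the
#' fit gradient-localized boundary points. False positives may survive: they
#' are removed downstream by clustering and width filtering.
#'
#' The image is min-max normalized first and all thresholds are relative, so
#' the output is invariant under affine intensity rescaling.
#'
#' @param image numeric matrix `[y, x]` or [SectionImage-class].
#' @param params from [detectionParams()].
#' @param sliceIndex 0-based slice index recorded in the output.
#' @return data.frame with columns slice_index, cx, cy (0-based px), major,
#'   minor (full axes, px), angle (deg), source (`"rule"`).
#' @export
detectEllipsesSlice <- function(image, params = detectionParams(),
                                sliceIndex = 0L) {
  if (is(image, "SectionImage")) image <- image@data
  if (min(dim(image)) < params$blockSize)
    stop("image smaller than the adaptive-threshold block size")
  img <- normalize01(image)
  half <- (params$blockSize - 1L) %/% 2L
  bw <- as.matrix(EBImage::thresh(img, w = half, h = half,
                                  offset = params$offset))
  edges <- cannyEdges(img, params$cannyLow, params$cannyHigh)
  brush <- EBImage::makeBrush(2L * params$morphRadius + 1L, shape = "disc")
  bw <- as.matrix(EBImage::closing(EBImage::opening(bw, brush), brush))
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(emptyDetections())
  contours <- EBImage::ocontour(lab)
  out <- emptyDetections()
  for (i in seq_len(nlab)) {
    pts <- contours[[i]]
    if (is.null(pts) || nrow(pts) < params$minContourPoints) next
    # ocontour gives 0-based (row, col); convert to (x, y)
    py <- pts[, 1]; px <- pts[, 2]
    # snap to Canny edges near this contour when enough edge points trace it
    comp <- lab == i
    rim <- EBImage::dilate(comp, EBImage::makeBrush(5, "disc")) & edges
    ep <- which(as.matrix(rim), arr.ind = TRUE)
    if (nrow(ep) >= max(params$minContourPoints, nrow(pts) %/% 2)) {
      py <- ep[, 1] - 1; px <- ep[, 2] - 1
    }
    cf <- fitConicLS(px, py)
    if (is.null(cf)) next
    ell <- conicToEllipse(cf)
    if (is.null(ell)) next
    area <- pi * ell$major * ell$minor / 4
    ecc <- sqrt(max(0, 1 - (ell$minor / ell$major)^2))
    if (area < params$areaBounds[1] || area > params$areaBounds[2]) next
    if (ecc > params$maxEccentricity) next
    if (ell$cx < 0 || ell$cx > ncol(image) - 1 ||
        ell$cy < 0 || ell$cy > nrow(image) - 1) next
    out <- rbind(out, data.frame(
      slice_index = as.integer(sliceIndex), cx = ell$cx, cy = ell$cy,
      major = ell$major, minor = ell$minor, angle = ell$angle,
      source = "rule", stringsAsFactors = FALSE))
  }
  # overlapping duplicates: keep the larger-area fit
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$major * out$minor)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        j <- ord[b]
        if (i == j || !keep[j]) next
        d <- sqrt((out$cx[i] - out$cx[j])^2 + (out$cy[i] - out$cy[j])^2)
        if (d < out$minor[i] / 2) keep[j] <- (out$major[j] * out$minor[j] >
                                                out$major[i] * out$minor[i])
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Built-in promptable-mask backend (seeded threshold region grow)
#'
#' The default segmentation backend behind [segmentWithBackend()]: a seeded
#' region grow. For each point prompt, pixels within an intensity band of
#' `tolerance` (fraction of the min-max normalized range) around the prompt's
#' intensity are thresholded, lightly opened to break noise bridges, and the
#' connected component containing the prompt is returned. Prompts on the
#' dominant background produce a component covering most of the image, which
#' is discarded. No neural model is involved; any promptable-mask model
#' (e.g. a SAM-style segmenter) can be plugged in as a function with the same
#' contract.
#'
#' @param image numeric matrix `[y, x]`.
#' @param prompts n x 2 matrix of (x, y) 0-based pixel coordinates.
#' @param tolerance intensity band half-width as a fraction of the image
#'   dynamic range (default 0.2).
#' @param maxAreaFraction masks covering more than this fraction of the image
#'   are treated as background and dropped (default 0.25).
#' @return list of logical masks (possibly fewer than prompts).
#' @export
thresholdBackend <- function(image, prompts, tolerance = 0.2,
                             maxAreaFraction = 0.25) {
  img <- normalize01(image)
  brush <- EBImage::makeBrush(3, "disc")
  masks <- list()
  for (i in seq_len(nrow(prompts))) {
    r <- round(prompts[i, 2]) + 1L
    cc <- round(prompts[i, 1]) + 1L
    if (r < 1 || r > nrow(img) || cc < 1 || cc > ncol(img)) next
    bw <- as.matrix(EBImage::opening(abs(img - img[r, cc]) <= tolerance, brush))
    if (!bw[r, cc]) next
    lab <- EBImage::bwlabel(bw)
    m <- lab == lab[r, cc]
    if (sum(m) > maxAreaFraction * length(m)) next
    masks[[length(masks) + 1L]] <- m
  }
  masks
}

#' Segment markers with a promptable-mask backend
#'
#' Runs a promptable segmentation backend (a function taking the image and
#' point prompts and returning binary masks) and keeps one mask per prompt;
#' masks that do not contain their prompt are discarded. The default backend
#' is [thresholdBackend()]; a failing external backend falls back to it with
#' a warning.
#'
#' @param image numeric matrix `[y, x]`.
#' @param prompts n x 2 matrix of (x, y) 0-based prompt coordinates.
#' @param backend function(image, prompts) -> list of logical masks.
#' @return list of logical masks, each containing its prompt; empty when no
#'   prompt yields a valid mask.
#' @export
segmentWithBackend <- function(image, prompts, backend = thresholdBackend) {
  prompts <- matrix(prompts, ncol = 2)
  masks <- tryCatch(backend(image, prompts), error = function(e) {
    warning("segmentation backend failed (", conditionMessage(e),
            "); falling back to the built-in threshold backend")
    thresholdBackend(image, prompts)
  })
  containsPrompt <- function(m) {
    any(vapply(seq_len(nrow(prompts)), function(i) {
      r <- round(prompts[i, 2]) + 1L; cc <- round(prompts[i, 1]) + 1L
      r >= 1 && r <= nrow(m) && cc >= 1 && cc <= ncol(m) && isTRUE(m[r, cc])
    }, logical(1)))
  }
  Filter(containsPrompt, masks)
}

#' Measure a binary mask as an ellipse
#'
#' Fits the second-moment ellipse of a binary mask (the solid ellipse with
#' the mask's centroid and covariance); the cone width is read off as the
#' major axis.
#'
#' @param mask logical/0-1 matrix `[y, x]` with at least 5 foreground pixels.
#' @param sliceIndex 0-based slice index recorded in the output.
#' @return one-row detection data.frame (source `"backend"`).
#' @export
maskToEllipse <- function(mask, sliceIndex = 0L) {
  if (sum(mask > 0) < 5L)
    stop("mask too small for an ellipse fit (need >= 5 foreground pixels)")
  mm <- maskMoments(mask)
  data.frame(slice_index = as.integer(sliceIndex), cx = mm$cx, cy = mm$cy,
             major = mm$major, minor = mm$minor, angle = mm$angle,
             source = "backend", stringsAsFactors = FALSE)
}

#' Detect cone cross-sections across a volume
#'
#' Convenience driver for the full detection stage: samples `nSample` slices
#' ([sampleSliceIndices()]), runs the rule-based detector on each
#' ([detectEllipsesSlice()]), and - when `refine = TRUE` - clusters the
#' rule-based detections, uses each cluster's mean center as a point prompt
#' for the segmentation backend on every sampled slice, and re-measures each
#' cone from the resulting masks ([maskToEllipse()]). The refined (backend)
#' detections supersede the rule-based ones where available.
#'
#' @param volume [VoxelVolume-class].
#' @param nSample slices to sample.
#' @param seed integer seed for the slice draw.
#' @param params [detectionParams()].
#' @param nCones expected cone count (used only for refinement clustering).
#' @param refine logical; run the backend refinement pass (default TRUE).
#' @param backend promptable-mask backend, see [segmentWithBackend()].
#' @return detection data.frame (columns as [detectEllipsesSlice()]).
#' @export
detectConeSections <- function(volume, nSample, seed,
                               params = detectionParams(), nCones = 3L,
                               refine = TRUE, backend = thresholdBackend) {
  stopifnot(is(volume, "VoxelVolume"))
  arr <- volume@data
  idx <- sampleSliceIndices(dim(arr)[1], nSample, seed)
  dets <- do.call(rbind, lapply(idx, function(k) {
    detectEllipsesSlice(arr[k + 1L, , ], params, sliceIndex = k)
  }))
  if (is.null(dets) || nrow(dets) == 0)
    return(emptyDetections())
  if (!refine) return(dets)
  tracks <- tryCatch(clusterDetections(dets, nCones = nCones),
                     error = function(e) NULL)
  if (is.null(tracks)) return(dets)
  # median centers: robust to merged-contour false positives in the clusters
  prompts <- do.call(rbind, lapply(tracks, function(tr) {
    det <- detections(tr)
    c(stats::median(det$cx), stats::median(det$cy))
  }))
  refined <- do.call(rbind, lapply(idx, function(k) {
    img <- arr[k + 1L, , ]
    masks <- segmentWithBackend(img, prompts, backend)
    if (!length(masks)) return(NULL)
    do.call(rbind, lapply(masks, function(m) {
      if (sum(m) < 5L) return(NULL)
      maskToEllipse(m, sliceIndex = k)
    }))
  }))
  if (is.null(refined) || nrow(refined) == 0) dets else refined
}
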