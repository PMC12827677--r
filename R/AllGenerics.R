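#' Accessors for coneFuse classes
#'
#' Small accessor generics: `voxelSize()` and `imageData()` read physical
#' scale and raw pixel data from [VoxelVolume-class] and
#' [SectionImage-class]; `pixelSize()` reads the section pixel pitch;
#' `heatmap()`, `meanLNCC()` and `maxLNCC()` read [LNCCResult-class] parts.
#'
#' @param object an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelVolume", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomGroundTruth", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setMethod("imageData", "VoxelVolume", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("imageData", "SectionImage", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "SectionImage", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SectionMarkers", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("heatmap2", function(object) standardGeneric("heatmap2"))

#' @rdname accessors
#' @export
setMethod("heatmap2", "LNCCResult", function(object) object@heatmap)

#' @rdname accessors
#' @export
setGeneric("meanLNCC", function(object) standardGeneric("meanLNCC"))

#' @rdname accessors
#' @export
setMethod("meanLNCC", "LNCCResult", function(object) object@meanLNCC)

#' @rdname accessors
#' @export
setGeneric("maxLNCC", function(object) standardGeneric("maxLNCC"))

#' @rdname accessors
#' @export
setMethod("maxLNCC", "LNCCResult", function(object) object@maxLNCC)

#' @rdname accessors
#' @export
setGeneric("coneId", function(object) standardGeneric("coneId"))

#' @rdname accessors
#' @export
setMethod("coneId", "TaperModel", function(object) object@coneId)

#' @rdname accessors
#' @export
setMethod("coneId", "ConeTrack", function(object) object@coneId)

#' @rdname accessors
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname accessors
#' @export
setMethod("detections", "ConeTrack", function(object) object@detections)

#' @rdname accessors
#' @export
setGeneric("inliers", function(object) standardGeneric("inliers"))

#' @rdname accessors
#' @export
setMethod("inliers", "ConeTrack", function(object) object@inlier)

#' @rdname accessors
#' @export
setGeneric("meanCenter", function(object) standardGeneric("meanCenter"))

#' @rdname accessors
#' @export
setMethod("meanCenter", "ConeTrack", function(object) object@meanCenter)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VoxelVolume: %d x %d x %d voxels [z, y, x], %.4g mm/voxel (%.3g x %.3g x %.3g mm)\n",
    d[1], d[2], d[3], object@voxelSize,
    d[3] * object@voxelSize, d[2] * object@voxelSize, d[1] * object@voxelSize
  ))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SectionImage: %d x %d px [y, x], %.4g mm/px\n",
              d[1], d[2], object@pixelSize))
})

setMethod("show", "ConeSpec", function(object) {
  cat(sprintf(
    "ConeSpec: base ⌀%.3g mm -> apex ⌀%.3g mm over %.3g mm, base at (%.3g, %.3g, %.3g) mm\n",
    object@baseDiameter, object@apexDiameter, object@height,
    object@baseCenter[1], object@baseCenter[2], object@baseZ
  ))
})

setMethod("show", "TaperModel", function(object) {
  cat(sprintf(
    "TaperModel (cone %d): width = %.6g %+.6g * slice  [mm], %d inliers, residual cut %.3g mm\n",
    object@coneId, object@intercept, object@slope, object@inlierCount,
    object@residualThreshold
  ))
})

setMethod("show", "ConeTrack", function(object) {
  cat(sprintf("ConeTrack (cone %d): %d detections (%d inliers), mean center (%.2f, %.2f) px\n",
              object@coneId, nrow(object@detections), sum(object@inlier),
              object@meanCenter[1], object@meanCenter[2]))
})

setMethod("show", "PlaneEmbedding", function(object) {
  cat("PlaneEmbedding (2D mm -> 3D mm):\n")
  cat(sprintf("  origin: (%.4g, %.4g, %.4g)\n",
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  normal: (%.4g, %.4g, %.4g)\n",
              object@normal[1], object@normal[2], object@normal[3]))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: rotation %.4g deg, translation (%.4g, %.4g) px, scale %.4g\n",
              object@rotation, object@translation[1], object@translation[2],
              object@scale))
})

setMethod("show", "LNCCResult", function(object) {
  cat(sprintf("LNCCResult: window %d px, heatmap %d x %d, mean %.4f, max %.4f\n",
              object@window, nrow(object@heatmap), ncol(object@heatmap),
              object@meanLNCC, object@maxLNCC))
})

setMethod("show", "SectionMarkers", function(object) {
  cat(sprintf("SectionMarkers: %d ellipses, %d assigned to cones [%s], %.4g mm/px\n",
              nrow(object@ellipses), length(object@assignment),
              paste(names(object@assignment), collapse = ", "),
              object@pixelSize))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf("PhantomGroundTruth: %d cones, volume (%d, %d, %d), %.4g mm/voxel\n",
              length(object@coneSpecs), object@shape[1], object@shape[2],
              object@shape[3], object@voxelSize))
})
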