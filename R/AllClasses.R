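#' @import methods
NULL

#' Coordinate conventions used throughout coneFuse
#'
#' All geometry in the package follows one convention, stated here and used
#' everywhere:
#'
#' * Volumes are arrays indexed `[z, y, x]`; `z` is the stack (cone) axis.
#' * 2D images are matrices indexed `[y, x]` (rows run down the image).
#' * Pixel/voxel *centers* sit at integer coordinates, **0-based**: the first
#'   voxel center is at coordinate 0, so physical position (mm) =
#'   index \eqn{\times} voxel size. All reported coordinates (ellipse centers,
#'   slice indices, plane origins) are 0-based.
#' * Ellipse axes (`major`, `minor`) are *full* axis lengths (diameters), in
#'   pixels unless a function documents mm. `angle` is the orientation of the
#'   major axis in degrees, counter-clockwise from the +x (column) axis.
#'
#' @name coneFuse-coordinates
#' @keywords internal
NULL

#' ConeSpec: geometry and attenuation of one truncated-cone marker
#'
#' Describes a single upright truncated cone: its base-plane center, base
#' height, vertical extent, base and apex diameters, marker attenuation above
#' the embedding medium, and an optional linear depth variation of attenuation
#' emulating sedimentation of the contrast agent during printing.
#'
#' @slot baseCenter numeric(2), (x, y) of the cone axis at the base, mm.
#' @slot baseZ numeric(1), z of the base plane, mm.
#' @slot height numeric(1), cone height, mm.
#' @slot baseDiameter numeric(1), diameter at the base, mm.
#' @slot apexDiameter numeric(1), diameter at the (truncated) apex, mm.
#' @slot attenuation numeric(1), marker intensity at the base (image units).
#' @slot sedimentationSlope numeric(1), intensity change per mm of height
#'   within the marker (0 = uniform marker).
#'
#' @seealso [coneSpec()], [generatePhantomVolume()]
#' @exportClass ConeSpec
setClass("ConeSpec",
  representation(
    baseCenter = "numeric",
    baseZ = "numeric",
    height = "numeric",
    baseDiameter = "numeric",
    apexDiameter = "numeric",
    attenuation = "numeric",
    sedimentationSlope = "numeric"
  )
)

setValidity("ConeSpec", function(object) {
  msg <- character()
  if (length(object@baseCenter) != 2L || !all(is.finite(object@baseCenter)))
    msg <- c(msg, "baseCenter must be two finite numbers (x, y) in mm")
  if (!isTRUE(object@height > 0))
    msg <- c(msg, "height must be > 0")
  if (!isTRUE(object@baseDiameter > object@apexDiameter) ||
      !isTRUE(object@apexDiameter > 0))
    msg <- c(msg, "need baseDiameter > apexDiameter > 0")
  if (!is.finite(object@attenuation))
    msg <- c(msg, "attenuation must be finite")
  if (length(msg)) msg else TRUE
})

#' VoxelVolume: a 3D scalar grid with physical voxel size
#'
#' The central 3D container: a `[z, y, x]` array of finite intensities with an
#' isotropic voxel size in mm. See [coneFuse-coordinates] for the axis and
#' origin conventions.
#'
#' @slot data 3D numeric array, `[z, y, x]`.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#'
#' @seealso [voxelVolume()], [readVolume()], [writeVolume()]
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric")
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array [z, y, x]")
  if (!isTRUE(object@voxelSize > 0) || length(object@voxelSize) != 1L)
    msg <- c(msg, "voxelSize must be a single positive number (mm)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' SectionImage: a 2D image with physical pixel size
#'
#' @slot data numeric matrix `[y, x]`.
#' @slot pixelSize numeric(1), pixel edge length in mm.
#'
#' @seealso [sampleSectionImage()], [extractObliqueSlice()]
#' @exportClass SectionImage
setClass("SectionImage",
  representation(data = "matrix", pixelSize = "numeric")
)

setValidity("SectionImage", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (!isTRUE(object@pixelSize > 0))
    msg <- c(msg, "pixelSize must be a single positive number (mm)")
  if (!all(is.finite(object@data))) msg <- c(msg, "all pixels must be finite")
  if (length(msg)) msg else TRUE
})

#' PlaneEmbedding: affine map from 2D section coordinates into the volume
#'
#' An affine embedding \eqn{A(u, v) = origin + u\,basisU + v\,basisV} taking
#' 2D section coordinates (mm) to 3D volume coordinates (mm, (x, y, z) order).
#' Built from three point correspondences by [buildEmbedding()] or directly
#' from a point and normal by [planeFromNormal()].
#'
#' @slot origin numeric(3), image of (0, 0), mm (x, y, z).
#' @slot basisU numeric(3), image of the section u (x) unit vector, mm.
#' @slot basisV numeric(3), image of the section v (y) unit vector, mm.
#' @slot normal numeric(3), unit normal, perpendicular to both basis vectors.
#' @slot correspondences list with elements `section` (3x2 matrix, mm) and
#'   `volume` (3x3 matrix, mm) holding the defining point pairs, or an empty
#'   list when constructed synthetically.
#'
#' @seealso [buildEmbedding()], [planeFromNormal()], [extractObliqueSlice()]
#' @exportClass PlaneEmbedding
setClass("PlaneEmbedding",
  representation(
    origin = "numeric",
    basisU = "numeric",
    basisV = "numeric",
    normal = "numeric",
    correspondences = "list"
  )
)

setValidity("PlaneEmbedding", function(object) {
  msg <- character()
  if (length(object@origin) != 3L || length(object@basisU) != 3L ||
      length(object@basisV) != 3L || length(object@normal) != 3L)
    msg <- c(msg, "origin, basisU, basisV, normal must each have length 3")
  cr <- crossProduct3(object@basisU, object@basisV)
  if (sqrt(sum(cr^2)) < 1e-12)
    msg <- c(msg, "basis vectors must be linearly independent")
  if (abs(sum(object@normal * object@basisU)) > 1e-9 ||
      abs(sum(object@normal * object@basisV)) > 1e-9)
    msg <- c(msg, "normal must be perpendicular to both basis vectors")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    msg <- c(msg, "normal must be a unit vector")
  if (length(object@correspondences)) {
    s2 <- object@correspondences$section
    p3 <- object@correspondences$volume
    pred <- applyEmbedding(object, s2)
    if (max(abs(pred - p3)) > 1e-6)
      msg <- c(msg, "embedding must map each stored 2D point to its 3D partner within 1e-6 mm")
  }
  if (length(msg)) msg else TRUE
})

#' TaperModel: per-cone linear width-height calibration
#'
#' The calibrated linear relation between a cone's cross-section width (mm)
#' and the stack slice index, fitted by the two-pass regression in
#' [fitTaper()], together with the per-axis linear drift of the cross-section
#' center with slice index (which interpolates center positions across
#' unsampled layers and absorbs small cone tilts).
#'
#' @slot coneId integer(1), cone identifier.
#' @slot slope numeric(1), mm of width per slice index (negative: cones taper
#'   towards the apex as z grows).
#' @slot intercept numeric(1), width in mm extrapolated to slice index 0.
#' @slot residualThreshold numeric(1), mm; pass-1 residual cut-off used.
#' @slot inlierCount integer(1), points surviving pass 1.
#' @slot centerDrift 2x2 numeric matrix; rows `cx`, `cy`, columns
#'   `intercept` (px) and `slope` (px per slice index).
#' @slot widthRange numeric(2), mm; width range covered by the inliers
#'   (lookups outside it warn about extrapolation).
#'
#' @seealso [fitTaper()], [widthAt()], [widthToHeight()]
#' @exportClass TaperModel
setClass("TaperModel",
  representation(
    coneId = "integer",
    slope = "numeric",
    intercept = "numeric",
    residualThreshold = "numeric",
    inlierCount = "integer",
    centerDrift = "matrix",
    widthRange = "numeric"
  )
)

setValidity("TaperModel", function(object) {
  msg <- character()
  if (!is.finite(object@slope) || object@slope == 0)
    msg <- c(msg, "slope must be finite and non-zero (a cone tapers)")
  if (!is.finite(object@intercept)) msg <- c(msg, "intercept must be finite")
  if (!identical(dim(object@centerDrift), c(2L, 2L)))
    msg <- c(msg, "centerDrift must be a 2x2 matrix")
  if (length(msg)) msg else TRUE
})

#' ConeTrack: detections clustered onto one cone
#'
#' @slot coneId integer(1).
#' @slot detections data.frame of ellipse detections (see [detectEllipsesSlice()]
#'   for columns).
#' @slot inlier logical vector, one flag per detection row.
#' @slot meanCenter numeric(2), (cx, cy) px, mean over inliers.
#'
#' @seealso [clusterDetections()], [filterOutliers()]
#' @exportClass ConeTrack
setClass("ConeTrack",
  representation(
    coneId = "integer",
    detections = "data.frame",
    inlier = "logical",
    meanCenter = "numeric"
  )
)

setValidity("ConeTrack", function(object) {
  msg <- character()
  if (nrow(object@detections) != length(object@inlier))
    msg <- c(msg, "one inlier flag per detection required")
  if (length(object@meanCenter) != 2L)
    msg <- c(msg, "meanCenter must be (cx, cy)")
  if (length(msg)) msg else TRUE
})

#' SectionMarkers: section ellipses matched to cones
#'
#' @slot ellipses data.frame of ellipse detections from the section image
#'   (source `"histology"`).
#' @slot pixelSize numeric(1), mm per section pixel.
#' @slot assignment integer vector named by cone id; each entry is the row of
#'   `ellipses` assigned to that cone.
#'
#' @seealso [matchToCones()], [locateConePoints()]
#' @exportClass SectionMarkers
setClass("SectionMarkers",
  representation(
    ellipses = "data.frame",
    pixelSize = "numeric",
    assignment = "integer"
  )
)

setValidity("SectionMarkers", function(object) {
  msg <- character()
  if (!isTRUE(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
  if (anyDuplicated(object@assignment))
    msg <- c(msg, "assignment must be a bijection (no ellipse assigned twice)")
  if (length(object@assignment) &&
      (max(object@assignment) > nrow(object@ellipses) || min(object@assignment) < 1L))
    msg <- c(msg, "assignment indices must address rows of ellipses")
  if (length(msg)) msg else TRUE
})

#' RigidTransform2D: rotation + translation (+ optional fixed scale)
#'
#' Maps moving-image coordinates into fixed-image coordinates as
#' \eqn{p' = s R(\theta) (p - c) + c + t} where `c` is the fixed-image center,
#' passed at application time.
#'
#' @slot rotation numeric(1), degrees counter-clockwise.
#' @slot translation numeric(2), (tx, ty) px.
#' @slot scale numeric(1), isotropic factor, default 1 (not optimized by
#'   [rigidRegister()]).
#'
#' @seealso [rigidTransform2D()], [rigidRegister()], [applyRigidTransform()]
#' @exportClass RigidTransform2D
setClass("RigidTransform2D",
  representation(rotation = "numeric", translation = "numeric", scale = "numeric")
)

setValidity("RigidTransform2D", function(object) {
  msg <- character()
  if (!isTRUE(object@scale > 0)) msg <- c(msg, "scale must be > 0")
  if (length(object@translation) != 2L)
    msg <- c(msg, "translation must be (tx, ty)")
  if (!is.finite(object@rotation)) msg <- c(msg, "rotation must be finite")
  if (length(msg)) msg else TRUE
})

#' LNCCResult: local normalized cross-correlation heatmap and summary
#'
#' Per-window absolute NCC scores over all fully interior windows. The
#' heatmap has dimensions `dim(input) - window + 1`; its arithmetic mean is
#' the LNCC score.
#'
#' @slot heatmap numeric matrix of per-window |NCC| in `[0, 1]`.
#' @slot window integer(1), odd window edge length in px.
#' @slot meanLNCC numeric(1), mean of the heatmap.
#' @slot maxLNCC numeric(1), max of the heatmap.
#'
#' @seealso [lncc()], [lnccLayerSweep()]
#' @exportClass LNCCResult
setClass("LNCCResult",
  representation(
    heatmap = "matrix",
    window = "integer",
    meanLNCC = "numeric",
    maxLNCC = "numeric"
  )
)

setValidity("LNCCResult", function(object) {
  msg <- character()
  if (object@window %% 2L != 1L) msg <- c(msg, "window must be odd")
  h <- object@heatmap
  if (any(h < -1e-12) || any(h > 1 + 1e-12))
    msg <- c(msg, "heatmap values must lie in [0, 1]")
  if (abs(object@meanLNCC - mean(h)) > 1e-9)
    msg <- c(msg, "meanLNCC must equal the heatmap mean")
  if (length(msg)) msg else TRUE
})

#' PhantomGroundTruth: analytic truth record for a generated phantom
#'
#' Everything a parameter-recovery test needs: the cone specifications, the
#' analytic per-slice width (mm) and center (px) of every cone, the embedding
#' medium value, the tissue texture field (so sections can re-evaluate the
#' identical tissue geometry), and optionally the cutting plane a section was
#' sampled along.
#'
#' @slot coneSpecs list of [ConeSpec-class] objects.
#' @slot trueWidths numeric matrix, slices x cones, analytic width in mm
#'   (NA where a slice is outside a cone's extent).
#' @slot trueCenters list with matrices `cx`, `cy` (slices x cones, px).
#' @slot mediumValue numeric(1), embedding background intensity.
#' @slot voxelSize numeric(1), mm.
#' @slot shape integer(3), volume dimensions (z, y, x).
#' @slot tissue list describing the tissue texture field (or empty).
#' @slot plane the [PlaneEmbedding-class] a section was sampled along, or NULL.
#'
#' @seealso [generatePhantomVolume()], [sampleSectionImage()]
#' @exportClass PhantomGroundTruth
setClass("PhantomGroundTruth",
  representation(
    coneSpecs = "list",
    trueWidths = "matrix",
    trueCenters = "list",
    mediumValue = "numeric",
    voxelSize = "numeric",
    shape = "integer",
    tissue = "list",
    plane = "ANY"
  )
)
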