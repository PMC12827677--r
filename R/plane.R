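#' Locate the 3D volume point of each matched cone section
#'
#' For every cone in the section-marker assignment: converts the measured
#' major axis to mm, inverts the cone's taper calibration to get the
#' continuous slice index at which the cone has that width, evaluates the
#' center-drift model at that index for the in-plane position, and returns
#' the resulting (x, y, z) volume coordinates in mm.
#'
#' @param markers [SectionMarkers-class] (assignment named by cone id).
#' @param tapers list of [TaperModel-class]; matched to cones by `coneId`.
#' @param voxelSize mm per voxel of the calibrated volume.
#' @return matrix with one row per assigned cone (rownames = cone ids),
#'   columns (x, y, z) in mm.
#' @export
locateConePoints <- function(markers, tapers, voxelSize) {
  ids <- names(markers@assignment)
  taperIds <- vapply(tapers, coneId, integer(1))
  pts <- matrix(NA_real_, length(ids), 3,
                dimnames = list(ids, c("x", "y", "z")))
  for (i in seq_along(ids)) {
    hit <- which(taperIds == as.integer(ids[i]))
    if (!length(hit))
      stop(sprintf("no taper model for assigned cone %s", ids[i]))
    model <- tapers[[hit[1]]]
    ell <- markers@ellipses[markers@assignment[i], , drop = FALSE]
    wmm <- majorAxisMm(ell, markers@pixelSize)
    z <- widthToHeight(model, wmm)
    ctr <- centerAt(model, z)
    pts[i, ] <- c(ctr[1] * voxelSize, ctr[2] * voxelSize, z * voxelSize)
  }
  pts
}

#' Build the affine plane embedding from three point correspondences
#'
#' Solves the unique affine map \eqn{A} from 2D section coordinates (mm) to
#' 3D volume coordinates (mm) with \eqn{A(p_i) = P_i} for the three
#' correspondences; `origin = A(0, 0)`, the basis vectors are the images of
#' the section unit vectors and the normal is their normalized cross product.
#' Using a full affine frame (not just point + normal) means the in-plane
#' orientation and scale of the section are carried into the volume, giving
#' the rigid registration a complete initial guess.
#'
#' @param sectionPoints 3 x 2 matrix, section coordinates in mm.
#' @param volumePoints 3 x 3 matrix, volume coordinates (x, y, z) in mm.
#' @return a [PlaneEmbedding-class].
#' @export
buildEmbedding <- function(sectionPoints, volumePoints) {
  sectionPoints <- as.matrix(sectionPoints)
  volumePoints <- as.matrix(volumePoints)
  stopifnot(nrow(sectionPoints) == 3L, ncol(sectionPoints) == 2L,
            nrow(volumePoints) == 3L, ncol(volumePoints) == 3L)
  M <- cbind(sectionPoints, 1)
  if (abs(det(M)) < 1e-10 * max(abs(sectionPoints), 1)^2)
    stop("section points are collinear; cannot define a plane")
  v12 <- volumePoints[2, ] - volumePoints[1, ]
  v13 <- volumePoints[3, ] - volumePoints[1, ]
  if (sqrt(sum(crossProduct3(v12, v13)^2)) <
      1e-10 * max(sqrt(sum(v12^2)) * sqrt(sum(v13^2)), 1e-12))
    stop("volume points are collinear; cannot define a plane")
  X <- solve(M, volumePoints)  # rows: coef of u, coef of v, constant
  planeEmbedding(
    origin = X[3, ], basisU = X[1, ], basisV = X[2, ],
    correspondences = list(section = unname(sectionPoints),
                           volume = unname(volumePoints))
  )
}

#' Extract an oblique slice from a volume by trilinear interpolation
#'
#' Samples the volume along the embedded plane: output pixel (row i, col j)
#' (0-based) takes the trilinearly interpolated intensity at
#' \eqn{A(j \cdot s, i \cdot s)} where `s` is the output pixel pitch
#' (default: the voxel size, i.e. the section is resampled at CT scale).
#' Sample points outside the volume take `fillValue`, so a plane tilted out
#' of the volume shows a filled region rather than an error.
#'
#' @param volume [VoxelVolume-class].
#' @param embedding [PlaneEmbedding-class].
#' @param outShape integer(2), output (rows, cols); default covers the
#'   volume footprint at pitch `pitch`.
#' @param pitch output pixel pitch in mm (default `voxelSize(volume)`).
#' @param fillValue intensity for out-of-volume samples (default 0).
#' @return a [SectionImage-class] with `pixelSize = pitch`.
#' @export
extractObliqueSlice <- function(volume, embedding, outShape = NULL,
                                pitch = NULL, fillValue = 0) {
  stopifnot(is(volume, "VoxelVolume"), is(embedding, "PlaneEmbedding"))
  vs <- volume@voxelSize
  if (is.null(pitch)) pitch <- vs
  d <- dim(volume@data)
  if (is.null(outShape)) outShape <- c(d[2], d[3])
  outShape <- as.integer(outShape)
  us <- (seq_len(outShape[2]) - 1) * pitch
  vv <- (seq_len(outShape[1]) - 1) * pitch
  gu <- rep(us, each = outShape[1])
  gv <- rep(vv, times = outShape[2])
  p3 <- applyEmbedding(embedding, cbind(gu, gv))
  zyx <- cbind(p3[, 3], p3[, 2], p3[, 1]) / vs
  vals <- trilinearSample(volume@data, zyx, fill = fillValue)
  sectionImage(matrix(vals, outShape[1], outShape[2]), pitch)
}

#' Angle between two plane normals
#'
#' @param a,b numeric(3) normals (any length).
#' @return angle in degrees, in `[0, 90]` (sign of the normal is ignored).
#' @export
normalAngle <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, ca)) * 180 / pi
}
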