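#' Create a truncated-cone marker specification
#'
#' Constructor for [ConeSpec-class]. Defaults follow the reference-marker
#' design used for resin embedding: 11 mm tall truncated cones with a 3 mm
#' base and a 0.5 mm apex, standing upright on the block base (the cone axis
#' is the z / stack axis).
#'
#' @param baseCenter numeric(2), (x, y) mm of the cone axis at the base.
#' @param baseZ mm, z of the base plane (default 0).
#' @param height mm (default 11).
#' @param baseDiameter mm (default 3).
#' @param apexDiameter mm (default 0.5).
#' @param attenuation marker intensity at the base, image units; must exceed
#'   the embedding medium value used at generation time.
#' @param sedimentationSlope intensity change per mm of height inside the
#'   marker (default 0 = uniform). Negative values emulate contrast-agent
#'   sedimentation towards the base.
#' @return a [ConeSpec-class] object.
#' @examples
#' coneSpec(baseCenter = c(3, 3), attenuation = 0.75)
#' @export
coneSpec <- function(baseCenter, baseZ = 0, height = 11, baseDiameter = 3,
                     apexDiameter = 0.5, attenuation = 0.75,
                     sedimentationSlope = 0) {
  new("ConeSpec",
    baseCenter = as.numeric(baseCenter), baseZ = as.numeric(baseZ),
    height = as.numeric(height), baseDiameter = as.numeric(baseDiameter),
    apexDiameter = as.numeric(apexDiameter),
    attenuation = as.numeric(attenuation),
    sedimentationSlope = as.numeric(sedimentationSlope)
  )
}

#' Create a VoxelVolume
#'
#' @param data 3D numeric array `[z, y, x]`.
#' @param voxelSize isotropic voxel size in mm.
#' @return a [VoxelVolume-class].
#' @export
voxelVolume <- function(data, voxelSize) {
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' Create a SectionImage
#'
#' @param data numeric matrix `[y, x]`.
#' @param pixelSize pixel size in mm.
#' @return a [SectionImage-class].
#' @export
sectionImage <- function(data, pixelSize) {
  new("SectionImage", data = as.matrix(data), pixelSize = as.numeric(pixelSize))
}

# Analytic radius (mm) of a cone at height z_mm; NA outside [baseZ, baseZ+height].
coneRadiusAt <- function(spec, zmm) {
  h <- zmm - spec@baseZ
  r <- (spec@baseDiameter - (spec@baseDiameter - spec@apexDiameter) *
          h / spec@height) / 2
  r[h < 0 | h > spec@height] <- NA_real_
  r
}

# Evaluate the tissue texture field (band-limited random field, values in
# [0, 1]) at arbitrary mm points (n x 3, columns x, y, z). The field is a
# trilinear upsampling of a small uniform-random lattice spanning the volume.
tissueFieldAt <- function(tissue, ptsmm) {
  ext <- tissue$extent  # mm, (x, y, z)
  cd <- dim(tissue$field)  # (z, y, x)
  zyx <- cbind(
    ptsmm[, 3] / ext[3] * (cd[1] - 1),
    ptsmm[, 2] / ext[2] * (cd[2] - 1),
    ptsmm[, 1] / ext[1] * (cd[3] - 1)
  )
  trilinearSample(tissue$field, zyx, fill = 0)
}

tissueMaskAt <- function(tissue, ptsmm) {
  f <- tissueFieldAt(tissue, ptsmm)
  ctr <- tissue$center; rad <- tissue$radius
  d2 <- ((ptsmm[, 1] - ctr[1]) / rad[1])^2 +
    ((ptsmm[, 2] - ctr[2]) / rad[2])^2 +
    ((ptsmm[, 3] - ctr[3]) / rad[3])^2
  list(mask = f > tissue$threshold & d2 <= 1, field = f)
}

#' Generate a synthetic microCT phantom with cone markers
#'
#' Builds a `[z, y, x]` volume emulating a resin-embedded block scanned by
#' microCT: a uniform embedding background, upright truncated-cone markers
#' with elevated (optionally depth-varying) attenuation, a blob of
#' band-limited tissue-like texture between the cones, and additive Gaussian
#' noise. The returned ground truth carries the analytic per-slice width and
#' center of every cone, so downstream stages have a parameter-recovery
#' oracle.
#'
#' @param coneSpecs list of [ConeSpec-class] objects (see [coneSpec()]).
#' @param shape integer(3), volume dimensions (z, y, x) in voxels.
#' @param voxelSize mm per voxel (isotropic). Default 0.05 mm with a 256^3
#'   grid gives a 12.8 mm block, a desk-scale stand-in for micrometer-scale
#'   scans.
#' @param mediumValue embedding background intensity (default 0.25).
#' @param tissueParams list controlling the tissue blob, or `NULL` to omit
#'   tissue. Recognized entries: `coarseDim` (lattice size of the random
#'   field, default 5), `threshold` (field level defining the blob, default
#'   0.55), `low`, `high` (tissue intensity range as fractions of the
#'   marker-medium contrast, defaults 0.2 and 0.45 so tissue always stays
#'   below the marker half-contrast threshold), `center`, `radius`
#'   (ellipsoidal region holding the blob, mm; defaults center the blob in
#'   the volume at 30% of its extent).
#' @param noiseSigma standard deviation of additive Gaussian noise, image
#'   units (default 0).
#' @param seed integer seed; the same seed and parameters reproduce the
#'   volume bit-identically.
#' @return list with elements `volume` ([VoxelVolume-class]) and `truth`
#'   ([PhantomGroundTruth-class]).
#' @examples
#' cones <- list(coneSpec(c(2.2, 2.2)), coneSpec(c(7.4, 2.6)),
#'               coneSpec(c(4.6, 7.6)))
#' ph <- generatePhantomVolume(cones, shape = c(64, 96, 96), voxelSize = 0.1,
#'                             noiseSigma = 0, seed = 1)
#' ph$volume
#' @export
generatePhantomVolume <- function(coneSpecs, shape, voxelSize = 0.05,
                                  mediumValue = 0.25, tissueParams = list(),
                                  noiseSigma = 0, seed = 1) {
  stopifnot(length(shape) == 3L, all(shape > 0), voxelSize > 0,
            noiseSigma >= 0, length(coneSpecs) >= 1L)
  shape <- as.integer(shape)
  for (cs in coneSpecs) validObject(cs)
  extent <- (rev(shape) - 1) * voxelSize  # mm, (x, y, z)

  # containment: every cone must lie fully inside the voxel-center extent
  for (i in seq_along(coneSpecs)) {
    cs <- coneSpecs[[i]]
    r0 <- cs@baseDiameter / 2
    if (cs@baseCenter[1] - r0 < 0 || cs@baseCenter[1] + r0 > extent[1] ||
        cs@baseCenter[2] - r0 < 0 || cs@baseCenter[2] + r0 > extent[2] ||
        cs@baseZ < 0 || cs@baseZ + cs@height > extent[3])
      stop(sprintf("cone %d extends outside the volume (extent %.3g x %.3g x %.3g mm)",
                   i, extent[1], extent[2], extent[3]))
  }
  # overlap: radii shrink with z, so it suffices to check slicewise
  zmm <- (seq_len(shape[1]) - 1) * voxelSize
  nC <- length(coneSpecs)
  radii <- vapply(coneSpecs, coneRadiusAt, numeric(length(zmm)), zmm = zmm)
  if (nC >= 2L) {
    for (i in seq_len(nC - 1L)) for (j in seq((i + 1L), nC)) {
      dc <- sqrt(sum((coneSpecs[[i]]@baseCenter - coneSpecs[[j]]@baseCenter)^2))
      rs <- radii[, i] + radii[, j]
      if (any(!is.na(rs) & rs >= dc))
        stop(sprintf("cones %d and %d overlap", i, j))
    }
  }

  tissue <- list()
  useTissue <- !is.null(tissueParams)
  vol <- array(mediumValue, dim = shape)

  withSeed(seed, {
    if (useTissue) {
      tp <- tissueParams
      cd <- if (is.null(tp$coarseDim)) 5L else as.integer(tp$coarseDim)
      attRef <- mean(vapply(coneSpecs, function(cs) cs@attenuation, 0))
      tissue <- list(
        field = array(stats::runif(cd^3), dim = c(cd, cd, cd)),
        extent = extent,
        threshold = if (is.null(tp$threshold)) 0.55 else tp$threshold,
        low = if (is.null(tp$low)) 0.2 else tp$low,
        high = if (is.null(tp$high)) 0.45 else tp$high,
        center = if (is.null(tp$center)) extent / 2 else tp$center,
        radius = if (is.null(tp$radius)) extent * 0.3 else tp$radius,
        mediumValue = mediumValue,
        attRef = attRef
      )
    }

    xs <- (seq_len(shape[3]) - 1) * voxelSize
    ys <- (seq_len(shape[2]) - 1) * voxelSize
    gx <- matrix(rep(xs, each = shape[2]), shape[2], shape[3])
    gy <- matrix(rep(ys, times = shape[3]), shape[2], shape[3])
    trueWidths <- matrix(NA_real_, shape[1], nC)
    cxs <- matrix(NA_real_, shape[1], nC)
    cys <- matrix(NA_real_, shape[1], nC)

    for (k in seq_len(shape[1])) {
      z <- zmm[k]
      sl <- matrix(mediumValue, shape[2], shape[3])
      if (useTissue) {
        pts <- cbind(as.vector(gx), as.vector(gy), z)
        tm <- tissueMaskAt(tissue, pts)
        if (any(tm$mask)) {
          tval <- mediumValue + (tissue$low + (tissue$high - tissue$low) *
            tm$field[tm$mask]) * (tissue$attRef - mediumValue)
          sl[matrix(tm$mask, shape[2], shape[3])] <- tval
        }
      }
      for (i in seq_len(nC)) {
        cs <- coneSpecs[[i]]
        r <- radii[k, i]
        if (is.na(r) || r <= 0) next
        inside <- (gx - cs@baseCenter[1])^2 + (gy - cs@baseCenter[2])^2 <= r^2
        if (any(inside))
          sl[inside] <- cs@attenuation + cs@sedimentationSlope * (z - cs@baseZ)
        trueWidths[k, i] <- 2 * r
        cxs[k, i] <- cs@baseCenter[1] / voxelSize
        cys[k, i] <- cs@baseCenter[2] / voxelSize
      }
      if (noiseSigma > 0)
        sl <- sl + stats::rnorm(length(sl), 0, noiseSigma)
      vol[k, , ] <- sl
    }
  })

  truth <- new("PhantomGroundTruth",
    coneSpecs = coneSpecs, trueWidths = trueWidths,
    trueCenters = list(cx = cxs, cy = cys),
    mediumValue = mediumValue, voxelSize = voxelSize, shape = shape,
    tissue = tissue, plane = NULL
  )
  list(volume = voxelVolume(vol, voxelSize), truth = truth)
}

# Exact conic section of a truncated cone by an (orthonormal-basis) plane.
# Returns list(cx, cy [mm in plane coords], major, minor [mm], angle [deg],
# zCenter [mm]) or NULL when the plane misses the truncated cone.
coneSectionConic <- function(spec, plane) {
  s <- (spec@baseDiameter - spec@apexDiameter) / (2 * spec@height)  # radius per mm
  za <- spec@baseZ + (spec@baseDiameter / 2) / s  # extended apex z
  wgt <- c(1, 1, -s^2)
  apex <- c(spec@baseCenter[1], spec@baseCenter[2], za)
  a <- plane@origin - apex
  e1 <- plane@basisU; e2 <- plane@basisV
  A <- sum(wgt * e1^2)
  B <- 2 * sum(wgt * e1 * e2)
  C <- sum(wgt * e2^2)
  D <- 2 * sum(wgt * a * e1)
  E <- 2 * sum(wgt * a * e2)
  F <- sum(wgt * a^2)
  ell <- conicToEllipse(c(A, B, C, D, E, F))
  if (is.null(ell)) return(NULL)
  p3 <- applyEmbedding(plane, c(ell$cx, ell$cy))
  if (p3[3] < spec@baseZ || p3[3] > spec@baseZ + spec@height) return(NULL)
  c(ell, list(zCenter = p3[3], conic = c(A, B, C, D, E, F)))
}

#' Sample a synthetic "histology" section along a plane of a phantom
#'
#' Renders the 2D image a stained section cut along `plane` would show:
#' marker cross-sections are drawn at their *analytic* elliptical footprint
#' (the exact conic section of each truncated cone by the plane), the tissue
#' blob is re-rendered from the identical texture field but with
#' histology-like contrast (markers dark on a bright background by default,
#' unlike the CT contrast), and stain noise is added. The analytic ellipse
#' parameters are returned alongside as ground truth.
#'
#' @param truth [PhantomGroundTruth-class] from [generatePhantomVolume()].
#' @param plane [PlaneEmbedding-class] with orthonormal basis vectors; must
#'   cut all cones within their truncated extent.
#' @param pixelSize mm per section pixel.
#' @param stainParams list: `background` (default 0.85), `tissueLow`/
#'   `tissueHigh` (default 0.35 / 0.6), `marker` (default 0.15), `noiseSigma`
#'   (default 0.005).
#' @param seed integer seed for the stain noise.
#' @param outShape integer(2) output (rows, cols); default covers the volume
#'   footprint at `pixelSize`.
#' @return list with `image` ([SectionImage-class]) and `ellipses`, a
#'   data.frame of the analytic marker footprints (cone, cx, cy px 0-based,
#'   major, minor px, angle deg).
#' @export
sampleSectionImage <- function(truth, plane, pixelSize,
                               stainParams = list(), seed = 1,
                               outShape = NULL) {
  stopifnot(is(truth, "PhantomGroundTruth"), is(plane, "PlaneEmbedding"),
            pixelSize > 0)
  if (abs(sum(plane@basisU * plane@basisV)) > 1e-9 ||
      abs(sqrt(sum(plane@basisU^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(plane@basisV^2)) - 1) > 1e-9)
    stop("sampleSectionImage requires an orthonormal plane basis")
  sp <- list(background = 0.85, tissueLow = 0.35, tissueHigh = 0.6,
             marker = 0.15, noiseSigma = 0.005)
  sp[names(stainParams)] <- stainParams

  ext <- (rev(truth@shape) - 1) * truth@voxelSize
  if (is.null(outShape))
    outShape <- c(floor(ext[2] / pixelSize) + 1, floor(ext[1] / pixelSize) + 1)
  outShape <- as.integer(outShape)

  nC <- length(truth@coneSpecs)
  conics <- vector("list", nC)
  cut <- logical(nC)
  for (i in seq_len(nC)) {
    conics[i] <- list(coneSectionConic(truth@coneSpecs[[i]], plane))
    cut[i] <- !is.null(conics[[i]])
  }
  if (!all(cut))
    stop(sprintf("plane misses cone(s) %s; cones cut: %s",
                 paste(which(!cut), collapse = ", "),
                 if (any(cut)) paste(which(cut), collapse = ", ") else "none"))

  # pixel grid in plane mm coordinates (u along columns, v along rows)
  us <- (seq_len(outShape[2]) - 1) * pixelSize
  vs <- (seq_len(outShape[1]) - 1) * pixelSize
  gu <- matrix(rep(us, each = outShape[1]), outShape[1], outShape[2])
  gv <- matrix(rep(vs, times = outShape[2]), outShape[1], outShape[2])

  img <- withSeed(seed, {
    m <- matrix(sp$background, outShape[1], outShape[2])
    if (length(truth@tissue)) {
      p3 <- applyEmbedding(plane, cbind(as.vector(gu), as.vector(gv)))
      tm <- tissueMaskAt(truth@tissue, p3)
      if (any(tm$mask)) {
        tval <- sp$tissueLow + (sp$tissueHigh - sp$tissueLow) * tm$field[tm$mask]
        m[matrix(tm$mask, outShape[1], outShape[2])] <- tval
      }
    }
    for (i in seq_len(nC)) {
      cf <- conics[[i]]$conic
      f <- cf[1] * gu^2 + cf[2] * gu * gv + cf[3] * gv^2 +
        cf[4] * gu + cf[5] * gv + cf[6]
      m[f <= 0] <- sp$marker
    }
    if (sp$noiseSigma > 0)
      m <- m + stats::rnorm(length(m), 0, sp$noiseSigma)
    m
  })

  ellipses <- do.call(rbind, lapply(seq_len(nC), function(i) {
    e <- conics[[i]]
    data.frame(cone = i, cx = e$cx / pixelSize, cy = e$cy / pixelSize,
               major = e$major / pixelSize, minor = e$minor / pixelSize,
               angle = e$angle, z_mm = e$zCenter)
  }))
  list(image = sectionImage(img, pixelSize), ellipses = ellipses)
}

#' Construct a plane embedding from a point and normal
#'
#' Builds a [PlaneEmbedding-class] with an orthonormal in-plane basis: the
#' u basis vector is the projection of the global +x axis onto the plane
#' (or +y when the normal is parallel to x) and v completes the right-handed
#' frame.
#'
#' @param origin numeric(3), a point on the plane, mm (x, y, z).
#' @param normal numeric(3), plane normal (any length, normalized internally).
#' @return a [PlaneEmbedding-class].
#' @examples
#' planeFromNormal(c(0, 0, 5.5), c(0, 0, 1))          # horizontal at z = 5.5 mm
#' planeFromNormal(c(0, 0, 5), c(0, sin(0.05), cos(0.05)))  # tilted about x
#' @export
planeFromNormal <- function(origin, normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- crossProduct3(n, u)
  new("PlaneEmbedding", origin = as.numeric(origin), basisU = u, basisV = v,
      normal = n, correspondences = list())
}

#' Construct a plane embedding from explicit origin and basis vectors
#'
#' @param origin numeric(3) mm; @param basisU,basisV numeric(3) mm per section
#'   mm unit.
#' @param correspondences optional list(section = 3x2, volume = 3x3) of the
#'   defining point pairs.
#' @return a [PlaneEmbedding-class].
#' @export
planeEmbedding <- function(origin, basisU, basisV, correspondences = list()) {
  n <- crossProduct3(basisU, basisV)
  n <- unname(n / sqrt(sum(n^2)))
  new("PlaneEmbedding", origin = unname(as.numeric(origin)),
      basisU = unname(as.numeric(basisU)), basisV = unname(as.numeric(basisV)),
      normal = n, correspondences = correspondences)
}
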