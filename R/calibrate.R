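#' Cluster detections into per-cone tracks
#'
#' Partitions ellipse detections into `nCones` spatial clusters by center
#' proximity: k-centroid clustering on (cx, cy), seeded from the `nCones`
#' most widely separated detections (farthest-point initialization, making
#' the result deterministic). Detections farther from every cluster mean
#' than `distanceThreshold` are left unassigned.
#'
#' @param detections detection data.frame (see [detectEllipsesSlice()]).
#' @param nCones number of cones expected (default 3).
#' @param distanceThreshold px; default 1.5 x the largest detected major
#'   axis, i.e. three times the cone base radius when the base is visible.
#' @return list of [ConeTrack-class], ordered by cone id (clusters sorted by
#'   cx then cy for stability).
#' @export
clusterDetections <- function(detections, nCones = 3L,
                              distanceThreshold = NULL) {
  nCones <- as.integer(nCones)
  if (length(unique(detections$slice_index)) < 2L)
    stop("need detections from at least 2 distinct slices")
  if (is.null(distanceThreshold))
    distanceThreshold <- 1.5 * max(detections$major)
  xy <- cbind(detections$cx, detections$cy)

  # farthest-point seeding
  n <- nrow(xy)
  if (nCones == 1L) {
    seeds <- matrix(colMeans(xy), 1)
  } else {
    dmat <- as.matrix(stats::dist(xy))
    pick <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    sel <- as.integer(pick)
    while (length(sel) < nCones) {
      mind <- apply(dmat[, sel, drop = FALSE], 1, min)
      sel <- c(sel, which.max(mind))
    }
    seeds <- xy[sel, , drop = FALSE]
  }
  km <- suppressWarnings(stats::kmeans(xy, centers = seeds, iter.max = 100,
                                       algorithm = "Lloyd"))
  centers <- km$centers
  # distance filter against per-cluster *median* centers (robust to gross
  # false positives dragging the mean): unassign far detections
  med <- t(vapply(seq_len(nCones), function(k) {
    rows <- km$cluster == k
    if (!any(rows)) return(centers[k, ])
    c(stats::median(xy[rows, 1]), stats::median(xy[rows, 2]))
  }, numeric(2)))
  d2c <- sqrt((xy[, 1] - med[km$cluster, 1])^2 +
                (xy[, 2] - med[km$cluster, 2])^2)
  assigned <- d2c <= distanceThreshold
  eff <- vapply(seq_len(nCones), function(k) sum(assigned & km$cluster == k),
                integer(1))
  if (any(eff == 0) || nCones > 1 &&
      min(stats::dist(centers)) < .Machine$double.eps^0.5)
    stop(sprintf("found only %d distinct cluster(s), expected %d",
                 sum(eff > 0), nCones))
  ord <- order(centers[, 1], centers[, 2])
  lapply(seq_along(ord), function(i) {
    k <- ord[i]
    rows <- which(assigned & km$cluster == k)
    det <- detections[rows, , drop = FALSE]
    rownames(det) <- NULL
    new("ConeTrack", coneId = i, detections = det,
        inlier = rep(TRUE, nrow(det)),
        meanCenter = c(mean(det$cx), mean(det$cy)))
  })
}

#' Flag outlier detections within a cone track
#'
#' Marks as outlier any detection whose center lies beyond
#' `distanceThreshold` from the track's mean center or whose major axis falls
#' outside `widthBounds`; the mean center is then recomputed over the inliers.
#'
#' @param track [ConeTrack-class].
#' @param distanceThreshold px.
#' @param widthBounds numeric(2), accepted major-axis range, px.
#' @return the track with updated inlier flags and mean center.
#' @export
filterOutliers <- function(track, distanceThreshold = Inf,
                           widthBounds = c(0, Inf)) {
  det <- track@detections
  if (nrow(det) == 0) stop("empty track")
  d <- sqrt((det$cx - track@meanCenter[1])^2 +
              (det$cy - track@meanCenter[2])^2)
  ok <- d <= distanceThreshold & det$major >= widthBounds[1] &
    det$major <= widthBounds[2]
  if (!any(ok))
    stop(sprintf("all %d detections of cone %d flagged as outliers",
                 nrow(det), track@coneId))
  new("ConeTrack", coneId = track@coneId, detections = det, inlier = ok,
      meanCenter = c(mean(det$cx[ok]), mean(det$cy[ok])))
}

#' Fit the two-pass linear taper (width vs slice index) of a cone
#'
#' Pass 1 fits ordinary least squares of the cross-section width (converted
#' to mm) on the slice index over the track's inliers; points whose absolute
#' residual exceeds the residual threshold (default 3 x the MAD of the
#' pass-1 residuals) are dropped; pass 2 refits on the survivors. The
#' per-axis linear drift of the detection centers with slice index is fitted
#' on the same survivors, so both width and center can be interpolated across
#' unsampled layers.
#'
#' @param track [ConeTrack-class] (use [filterOutliers()] first for gross
#'   center/width outliers).
#' @param pixelSize mm per pixel (converts detected widths to mm).
#' @param residualThreshold mm; fixed override of the 3 x MAD default.
#' @return a [TaperModel-class].
#' @seealso [widthAt()], [widthToHeight()]
#' @export
fitTaper <- function(track, pixelSize, residualThreshold = NULL) {
  det <- track@detections[track@inlier, , drop = FALSE]
  if (nrow(det) < 2L || length(unique(det$slice_index)) < 2L)
    stop("need >= 2 inlier detections on >= 2 distinct slices")
  w <- det$major * pixelSize
  z <- det$slice_index
  f1 <- stats::lm(w ~ z)
  r <- stats::residuals(f1)
  thr <- if (is.null(residualThreshold)) {
    m <- stats::mad(r)
    if (m <= .Machine$double.eps^0.5) Inf else 3 * m
  } else residualThreshold
  keep <- abs(r) <= thr
  if (sum(keep) < 2L || length(unique(z[keep])) < 2L)
    stop("fewer than 2 points survive the pass-1 residual cut")
  f2 <- stats::lm(w[keep] ~ z[keep])
  slope <- unname(stats::coef(f2)[2])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate taper fit (zero slope)")
  dx <- stats::lm(det$cx[keep] ~ z[keep])
  dy <- stats::lm(det$cy[keep] ~ z[keep])
  drift <- rbind(cx = unname(stats::coef(dx)), cy = unname(stats::coef(dy)))
  colnames(drift) <- c("intercept", "slope")
  new("TaperModel", coneId = track@coneId, slope = slope,
      intercept = unname(stats::coef(f2)[1]),
      residualThreshold = if (is.finite(thr)) thr else 0,
      inlierCount = as.integer(sum(keep)), centerDrift = drift,
      widthRange = range(w[keep]))
}

#' Width predicted by a taper model at a slice index
#'
#' @param model [TaperModel-class].
#' @param z slice index (continuous, 0-based).
#' @return width in mm.
#' @export
widthAt <- function(model, z) {
  model@intercept + model@slope * z
}

#' Slice index at which a cone has a given width
#'
#' Inverts the calibrated taper line, mapping a measured cross-section width
#' (mm) to a continuous (sub-slice) stack index. Widths outside the range
#' covered by the calibration inliers are extrapolated with a warning.
#'
#' @param model [TaperModel-class].
#' @param width mm.
#' @return continuous 0-based slice index.
#' @examples
#' # round trip: widthToHeight(model, widthAt(model, z)) == z
#' @export
widthToHeight <- function(model, width) {
  if (model@slope == 0) stop("taper slope is zero; width does not encode height")
  if (length(model@widthRange) == 2 &&
      (width < model@widthRange[1] - 1e-12 ||
         width > model@widthRange[2] + 1e-12))
    warning(sprintf(
      "width %.4g mm outside the calibrated range [%.4g, %.4g] mm; extrapolating",
      width, model@widthRange[1], model@widthRange[2]))
  (width - model@intercept) / model@slope
}

#' Center position predicted by a taper model's drift fit
#'
#' @param model [TaperModel-class].
#' @param z slice index (continuous).
#' @return numeric(2), (cx, cy) px.
#' @export
centerAt <- function(model, z) {
  c(model@centerDrift["cx", "intercept"] + model@centerDrift["cx", "slope"] * z,
    model@centerDrift["cy", "intercept"] + model@centerDrift["cy", "slope"] * z)
}

#' Calibrate all cones of a detection set
#'
#' Clusters detections, filters outliers per track and fits one taper model
#' per cone. Width bounds default to the physically possible range derived
#' from the cone geometry.
#'
#' @param detections detection data.frame.
#' @param pixelSize mm/px of the volume slices.
#' @param nCones cone count (default 3).
#' @param coneDiameters numeric(2) (base, apex) mm for the default width
#'   bounds (default c(3, 0.5), widened by 25%).
#' @param residualThreshold optional fixed pass-1 residual cut, mm.
#' @return list with `tracks` (list of [ConeTrack-class]) and `models`
#'   (list of [TaperModel-class], by cone id).
#' @export
calibrateCones <- function(detections, pixelSize, nCones = 3L,
                           coneDiameters = c(3, 0.5),
                           residualThreshold = NULL) {
  tracks <- clusterDetections(detections, nCones = nCones)
  wb <- c(coneDiameters[2] * 0.75, coneDiameters[1] * 1.25) / pixelSize
  dth <- 3 * (coneDiameters[1] / 2) / pixelSize  # 3 x base radius, px
  tracks <- lapply(tracks, filterOutliers, distanceThreshold = dth,
                   widthBounds = wb)
  models <- lapply(tracks, fitTaper, pixelSize = pixelSize,
                   residualThreshold = residualThreshold)
  list(tracks = tracks, models = models)
}
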