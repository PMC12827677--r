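#' Detect marker ellipses in a 2D section image
#'
#' Runs the same rule-based chain as the microCT path
#' ([detectEllipsesSlice()]) on the section image after a marker-emphasis
#' preprocessing step: the image is min-max normalized and, when
#' `polarity = "auto"`, the polarity (markers bright vs dark) yielding more
#' valid ellipse candidates is chosen, since stained sections typically show
#' the resin markers dark on a bright background while CT shows them bright.
#' When `refine = TRUE` each candidate is re-measured from a promptable-mask
#' segmentation at its center ([segmentWithBackend()] + [maskToEllipse()]).
#'
#' @param image numeric matrix `[y, x]` or [SectionImage-class].
#' @param params [detectionParams()].
#' @param expectedCones minimum number of candidates required (default 3).
#' @param polarity `"auto"`, `"bright"` (markers already bright) or `"dark"`.
#' @param refine logical, backend refinement (default TRUE).
#' @return detection data.frame with source `"histology"`.
#' @export
detectSectionEllipses <- function(image, params = detectionParams(),
                                  expectedCones = 3L, polarity = "auto",
                                  refine = TRUE) {
  if (is(image, "SectionImage")) image <- image@data
  img <- normalize01(image)
  candidates <- switch(polarity,
    bright = list(img),
    dark = list(1 - img),
    auto = list(img, 1 - img),
    stop("polarity must be 'auto', 'bright' or 'dark'")
  )
  runs <- lapply(candidates, function(g)
    tryCatch(detectEllipsesSlice(g, params), error = function(e) emptyDetections()))
  best <- which.max(vapply(runs, nrow, integer(1)))
  g <- candidates[[best]]
  det <- runs[[best]]
  if (refine) {
    # prompts: rule-based centers plus centroids of the brightest compact
    # components (markers are, by radiopacity design, the intensity extreme
    # in both modalities, so a top-intensity scan recovers candidates the
    # threshold chain lost to touching structures)
    prompts <- if (nrow(det)) cbind(det$cx, det$cy) else matrix(0, 0, 2)
    bw <- g >= max(g) - 0.25 * diff(range(g))
    bw <- as.matrix(EBImage::opening(bw, EBImage::makeBrush(3, "disc")))
    lab <- EBImage::bwlabel(bw)
    if (max(lab) > 0) {
      cent <- do.call(rbind, lapply(seq_len(max(lab)), function(i) {
        w <- which(lab == i, arr.ind = TRUE)
        if (nrow(w) < 5L) return(NULL)
        c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
      }))
      if (!is.null(cent)) prompts <- rbind(prompts, cent)
    }
    if (nrow(prompts)) {
      masks <- segmentWithBackend(g, prompts)
      ref <- do.call(rbind, lapply(masks, function(m) {
        if (sum(m) < 5L) return(NULL)
        maskToEllipse(m)
      }))
      if (!is.null(ref) && nrow(ref) > 0) {
        ref <- unique(ref)
        # drop near-duplicate measurements from coincident prompts
        if (nrow(ref) > 1) {
          keep <- rep(TRUE, nrow(ref))
          for (i in 2:nrow(ref)) for (j in seq_len(i - 1L)) {
            if (keep[j] && sqrt((ref$cx[i] - ref$cx[j])^2 +
                                  (ref$cy[i] - ref$cy[j])^2) < 2)
              keep[i] <- FALSE
          }
          ref <- ref[keep, , drop = FALSE]
        }
        # re-apply the size/eccentricity filters on the refined measurements
        area <- pi * ref$major * ref$minor / 4
        ecc <- sqrt(pmax(0, 1 - (ref$minor / ref$major)^2))
        ref <- ref[area >= params$areaBounds[1] & area <= params$areaBounds[2] &
                     ecc <= params$maxEccentricity, , drop = FALSE]
        if (nrow(ref) > 0) det <- ref
      }
    }
  }
  if (nrow(det) < expectedCones)
    stop(sprintf("found %d marker candidate(s) in the section, expected >= %d",
                 nrow(det), expectedCones))
  det$source <- "histology"
  rownames(det) <- NULL
  det
}

# normalize a point set: translate to centroid, scale to unit RMS radius
normalizePoints <- function(p) {
  p <- sweep(p, 2, colMeans(p))
  s <- sqrt(mean(rowSums(p^2)))
  if (s > 0) p / s else p
}

#' Match section ellipses to cones by relative layout
#'
#' Assigns each cone (given its approximate relative 2D position, e.g. the
#' mean cluster centers from the microCT calibration) the section ellipse
#' that minimizes the total squared distance after both point sets are
#' normalized (translated to their centroid and scaled to unit RMS radius),
#' making the assignment invariant to global translation and isotropic
#' scaling of the section. All cone-to-ellipse injections are enumerated
#' (exhaustive, intended for 3 cones); surplus ellipses stay unassigned. Two
#' injections with (near-)equal cost are ambiguous and raise an error rather
#' than guessing.
#'
#' @param sectionEllipses detection data.frame from [detectSectionEllipses()].
#' @param expectedLayout numeric matrix, one row per cone (rownames = cone
#'   ids, or cones are numbered in order), columns (x, y): relative cone
#'   positions.
#' @param pixelSize mm per section pixel (stored in the result).
#' @param tol relative cost gap below which two assignments count as
#'   ambiguous (default 1e-6).
#' @return a [SectionMarkers-class].
#' @export
matchToCones <- function(sectionEllipses, expectedLayout, pixelSize,
                         tol = 1e-6) {
  nE <- nrow(sectionEllipses)
  nC <- nrow(expectedLayout)
  if (nE < nC)
    stop(sprintf("%d ellipse(s) for %d cones; need at least one per cone", nE, nC))
  L <- normalizePoints(as.matrix(expectedLayout[, 1:2]))
  E <- normalizePoints(cbind(sectionEllipses$cx, sectionEllipses$cy))
  # enumerate injections cone -> ellipse
  perms <- function(v, k) {
    if (k == 0) return(list(integer()))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1)) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  asg <- perms(seq_len(nE), nC)
  cost <- vapply(asg, function(a)
    sum((L - E[a, , drop = FALSE])^2), numeric(1))
  ord <- order(cost)
  best <- asg[[ord[1]]]
  if (length(ord) > 1) {
    second <- asg[[ord[2]]]
    if (!identical(best, second) &&
        cost[ord[2]] - cost[ord[1]] <= tol * max(cost[ord[1]], 1e-12))
      stop("ambiguous cone assignment: two ellipse matchings have equal cost")
  }
  ids <- rownames(expectedLayout)
  if (is.null(ids)) ids <- as.character(seq_len(nC))
  assignment <- stats::setNames(as.integer(best), ids)
  new("SectionMarkers", ellipses = sectionEllipses, pixelSize = pixelSize,
      assignment = assignment)
}

#' Convert an ellipse major axis to millimetres
#'
#' The major axis (not the minor) is the width used for the height lookup:
#' an oblique cut through an upright cone lengthens only the major axis,
#' while the minor axis stays close to the local cone diameter.
#'
#' @param ellipse one-row detection data.frame (or any list with `$major`).
#' @param pixelSize mm per pixel, > 0.
#' @return major axis in mm.
#' @examples
#' majorAxisMm(list(major = 1000), 0.00116)  # 1.16 mm
#' @export
majorAxisMm <- function(ellipse, pixelSize) {
  stopifnot(pixelSize > 0)
  ellipse$major * pixelSize
}
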