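#' Local normalized cross-correlation with absolute-value modification
#'
#' Computes, for every fully interior `window x window` position, the
#' normalized cross-correlation between the two images over that window and
#' takes its absolute value, preventing cancellation between positively and
#' negatively correlated regions (so the score is invariant to local
#' contrast inversion, as needed when comparing CT to stained sections):
#' \deqn{LNCC(I,J) = \frac{1}{|N_W|} \sum_{k \in N_W}
#'   \left| \frac{\sum_{i \in W_k} (I_i - \bar I_k)(J_i - \bar J_k)}
#'   {\sqrt{\sum_{i \in W_k} (I_i - \bar I_k)^2
#'          \sum_{i \in W_k} (J_i - \bar J_k)^2}} \right|}
#' Windows in which either image has zero variance contribute 0. The heatmap
#' contains one value per interior window center, so its dimensions are
#' `dim(I) - window + 1`; its arithmetic mean is the LNCC score. The
#' computation uses integral images and is algebraically identical to the
#' per-window double loop.
#'
#' @param I,J numeric matrices of equal dimensions, each >= `window`.
#' @param window odd window edge length, px (default 45).
#' @return an [LNCCResult-class].
#' @examples
#' I <- matrix(rnorm(64^2), 64, 64)
#' meanLNCC(lncc(I, I, window = 15))          # 1
#' meanLNCC(lncc(I, -2 * I + 3, window = 15)) # 1
#' @export
lncc <- function(I, J, window = 45L) {
  if (is(I, "SectionImage")) I <- I@data
  if (is(J, "SectionImage")) J <- J@data
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  if (!all(dim(I) == dim(J))) stop("I and J must have identical dimensions")
  if (any(dim(I) < window)) stop("window larger than the image")
  n <- as.numeric(window)^2
  sI <- boxSum(I, window); sJ <- boxSum(J, window)
  sII <- boxSum(I * I, window); sJJ <- boxSum(J * J, window)
  sIJ <- boxSum(I * J, window)
  covIJ <- sIJ - sI * sJ / n
  varI <- pmax(sII - sI^2 / n, 0)
  varJ <- pmax(sJJ - sJ^2 / n, 0)
  # zero-variance guard: tolerance scaled to the window's magnitude so that
  # numerically-constant windows do not produce spurious correlations
  tolI <- 1e-12 * pmax(sII, 1e-300)
  tolJ <- 1e-12 * pmax(sJJ, 1e-300)
  den <- sqrt(varI * varJ)
  h <- abs(covIJ) / den
  h[varI <= tolI | varJ <= tolJ | den == 0] <- 0
  h <- pmin(h, 1)
  new("LNCCResult", heatmap = h, window = window, meanLNCC = mean(h),
      maxLNCC = max(h))
}

#' Sweep a registered section against every flat layer of a volume
#'
#' Validation of an extracted plane: the section is scored (LNCC mean)
#' against every z layer of the stack; a correctly localized horizontal
#' section scores highest at its true layer, and for a tilted cutting plane
#' the extracted oblique plane should beat every flat layer. Images of
#' unequal size are center-cropped to their common extent. Ties are broken
#' towards the first (lowest) layer.
#'
#' @param volume [VoxelVolume-class].
#' @param section numeric matrix or [SectionImage-class], at volume pixel
#'   scale.
#' @param window LNCC window, px (default 45).
#' @return list with `scores` (numeric, one per layer), `bestLayer`
#'   (0-based index of the maximum).
#' @export
lnccLayerSweep <- function(volume, section, window = 45L) {
  stopifnot(is(volume, "VoxelVolume"))
  if (is(section, "SectionImage")) section <- section@data
  d <- dim(volume@data)
  if (d[1] == 0) stop("empty volume")
  cr <- c(min(d[2], nrow(section)), min(d[3], ncol(section)))
  if (any(cr < window)) stop("common crop smaller than the LNCC window")
  centerCrop <- function(m, sz) {
    r0 <- (nrow(m) - sz[1]) %/% 2L
    c0 <- (ncol(m) - sz[2]) %/% 2L
    m[r0 + seq_len(sz[1]), c0 + seq_len(sz[2]), drop = FALSE]
  }
  sec <- centerCrop(section, cr)
  scores <- vapply(seq_len(d[1]), function(k) {
    lay <- centerCrop(volume@data[k, , ], cr)
    lncc(lay, sec, window)@meanLNCC
  }, numeric(1))
  list(scores = scores, bestLayer = which.max(scores) - 1L)
}

#' Checkerboard overlay of two images
#'
#' Builds the classic registration-inspection overlay: alternating
#' `tile x tile` blocks taken from `a` and `b`, with the top-left tile from
#' `a`.
#'
#' @param a,b numeric matrices of equal dimensions.
#' @param tile tile edge length, px.
#' @return numeric matrix.
#' @export
overlayCheckerboard <- function(a, b, tile) {
  if (is(a, "SectionImage")) a <- a@data
  if (is(b, "SectionImage")) b <- b@data
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  ri <- (seq_len(nrow(a)) - 1L) %/% tile
  ci <- (seq_len(ncol(a)) - 1L) %/% tile
  fromB <- outer(ri, ci, "+") %% 2L == 1L
  out <- a
  out[fromB] <- b[fromB]
  out
}
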