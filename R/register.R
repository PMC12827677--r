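#' Construct a 2D rigid transform
#'
#' @param rotation degrees counter-clockwise (default 0).
#' @param translation numeric(2) (tx, ty), px (default c(0, 0)).
#' @param scale isotropic scale factor (default 1; carried through but not
#'   optimized by [rigidRegister()]).
#' @return a [RigidTransform2D-class].
#' @export
rigidTransform2D <- function(rotation = 0, translation = c(0, 0), scale = 1) {
  new("RigidTransform2D", rotation = as.numeric(rotation),
      translation = as.numeric(translation), scale = as.numeric(scale))
}

#' Resample a moving image under a rigid transform
#'
#' Maps the moving image into the fixed frame under
#' \eqn{p' = s R(\theta)(p - c) + c + t} with `c` the image center, using
#' bilinear interpolation of the inverse mapping. Pixels mapping outside the
#' moving image become `NA` (or `fillValue` when given).
#'
#' @param moving numeric matrix `[y, x]` or [SectionImage-class].
#' @param transform [RigidTransform2D-class].
#' @param outDim integer(2) output (rows, cols); default `dim(moving)`.
#' @param fillValue value for unmapped pixels (default `NA`).
#' @return numeric matrix.
#' @export
applyRigidTransform <- function(moving, transform, outDim = NULL,
                                fillValue = NA_real_) {
  if (is(moving, "SectionImage")) moving <- moving@data
  if (is.null(outDim)) outDim <- dim(moving)
  th <- transform@rotation * pi / 180
  s <- transform@scale
  ctr <- (rev(outDim) - 1) / 2  # (x, y) center of the fixed frame
  mctr <- (rev(dim(moving)) - 1) / 2
  xs <- rep(seq_len(outDim[2]) - 1, each = outDim[1])
  ys <- rep(seq_len(outDim[1]) - 1, times = outDim[2])
  # inverse map: fixed (x,y) -> moving coordinates
  dx <- xs - ctr[1] - transform@translation[1]
  dy <- ys - ctr[2] - transform@translation[2]
  mx <- (cos(th) * dx + sin(th) * dy) / s + mctr[1]
  my <- (-sin(th) * dx + cos(th) * dy) / s + mctr[2]
  v <- bilinearSample(moving, cbind(mx, my))
  if (!is.na(fillValue)) v[is.na(v)] <- fillValue
  matrix(v, outDim[1], outDim[2])
}

# Mean squared intensity difference over the overlap; Inf when the overlap
# is below minOverlap of the fixed image.
rigidMSE <- function(par, moving, fixed, scale, minOverlap = 0.25) {
  tr <- new("RigidTransform2D", rotation = par[1],
            translation = par[2:3], scale = scale)
  w <- applyRigidTransform(moving, tr, outDim = dim(fixed))
  ok <- !is.na(w)
  if (mean(ok) < minOverlap) return(Inf)
  mean((w[ok] - fixed[ok])^2)
}

#' Rigid MSE registration of a section to an extracted plane
#'
#' Finds the rigid transform (rotation + translation; optional fixed scale
#' from `init`) minimizing the mean squared intensity difference over the
#' overlap region. Both images are min-max normalized internally so the
#' metric compares structure, not absolute intensity scales. The optimizer
#' is deterministic: a multi-resolution (coarse-to-fine) exhaustive grid
#' search around the initial transform followed by Nelder-Mead refinement at
#' full resolution. An optional `mask` restricts the metric to a region of
#' the fixed image (e.g. the tissue portion).
#'
#' @param moving,fixed numeric matrices or [SectionImage-class] objects.
#' @param init [RigidTransform2D-class] initial guess (default identity).
#' @param maxShift px, half-width of the translation search around `init`
#'   (default 12).
#' @param maxRotation degrees, half-width of the rotation search (default 6).
#' @param levels integer, number of resolution levels (default 3: factors
#'   4, 2, 1).
#' @param mask optional logical matrix (fixed frame); metric restricted to it.
#' @param polarity `"auto"` (default) registers both the moving image and its
#'   intensity inversion and keeps the lower-MSE result - histology and CT
#'   render the same structures with opposite contrast (bright vs dark
#'   markers), where raw MSE would be maximal at true alignment; `"as-is"`
#'   uses the moving image unchanged.
#' @return list with `transform` ([RigidTransform2D-class]), `mse` (final
#'   metric value), `inverted` (logical, moving polarity flipped) and
#'   `resampled` (moving image in the fixed frame, chosen polarity).
#' @export
rigidRegister <- function(moving, fixed, init = rigidTransform2D(),
                          maxShift = 12, maxRotation = 6, levels = 3L,
                          mask = NULL, polarity = c("auto", "as-is")) {
  if (is(moving, "SectionImage")) moving <- moving@data
  if (is(fixed, "SectionImage")) fixed <- fixed@data
  stopifnot(is.finite(init@rotation), all(is.finite(init@translation)))
  polarity <- match.arg(polarity)
  if (polarity == "auto") {
    a <- rigidRegister(moving, fixed, init, maxShift, maxRotation, levels,
                       mask, polarity = "as-is")
    b <- rigidRegister(max(moving) - moving, fixed, init, maxShift,
                       maxRotation, levels, mask, polarity = "as-is")
    out <- if (a$mse <= b$mse) a else b
    out$inverted <- b$mse < a$mse
    return(out)
  }
  # a light Gaussian prefilter counteracts the interpolation-smoothing bias
  # of MSE under noise (sub-pixel resampling smooths the moving image, which
  # would otherwise pull the optimum away from the true transform)
  mv <- normalize01(as.matrix(EBImage::gblur(moving, sigma = 0.8)))
  fx <- normalize01(as.matrix(EBImage::gblur(fixed, sigma = 0.8)))
  if (!is.null(mask)) fx[!mask] <- NA_real_
  scale <- init@scale

  mseAt <- function(par, mvL, fxL, scl) {
    tr <- new("RigidTransform2D", rotation = par[1], translation = par[2:3],
              scale = scl)
    w <- applyRigidTransform(mvL, tr, outDim = dim(fxL))
    ok <- !is.na(w) & !is.na(fxL)
    if (mean(ok) < 0.25) return(Inf)
    mean((w[ok] - fxL[ok])^2)
  }
  if (!is.finite(mseAt(c(init@rotation, init@translation), mv, fx, scale)))
    stop("empty overlap between the images at the initial transform")

  par <- c(init@rotation, init@translation)
  factors <- 2L^((levels - 1L):0L)
  rotSpan <- maxRotation; shiftSpan <- maxShift
  for (f in factors) {
    mvL <- downsampleMean(mv, f)
    fxL <- downsampleMean(fx, f)
    rotStep <- max(rotSpan / 4, 0.25)
    shiftStep <- max(shiftSpan / f / 4, 0.5)
    rots <- seq(par[1] - rotSpan, par[1] + rotSpan, by = rotStep)
    txs <- seq((par[2] - shiftSpan) / f, (par[2] + shiftSpan) / f,
               by = shiftStep)
    tys <- seq((par[3] - shiftSpan) / f, (par[3] + shiftSpan) / f,
               by = shiftStep)
    best <- c(par[1], par[2] / f, par[3] / f)
    bestVal <- mseAt(best, mvL, fxL, scale)
    for (r in rots) for (tx in txs) for (ty in tys) {
      v <- mseAt(c(r, tx, ty), mvL, fxL, scale)
      if (v < bestVal) { bestVal <- v; best <- c(r, tx, ty) }
    }
    par <- c(best[1], best[2] * f, best[3] * f)
    rotSpan <- max(2 * rotStep, 0.5)
    shiftSpan <- max(2 * shiftStep * f, 1.5)
  }
  opt <- stats::optim(par, mseAt, mvL = mv, fxL = fx, scl = scale,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  # one restart: re-expands the simplex, escaping premature contraction
  opt <- stats::optim(opt$par, mseAt, mvL = mv, fxL = fx, scl = scale,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  par <- opt$par
  tr <- rigidTransform2D(par[1], par[2:3], scale)
  list(transform = tr,
       mse = opt$value,
       inverted = FALSE,
       resampled = applyRigidTransform(normalize01(moving), tr,
                                       outDim = dim(fixed)))
}
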