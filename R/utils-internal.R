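# Internal numerical helpers shared across modules.

crossProduct3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Map 2D section points (n x 2, mm) through a PlaneEmbedding -> n x 3 mm.
applyEmbedding <- function(embedding, pts2d) {
  pts2d <- matrix(pts2d, ncol = 2)
  out <- cbind(
    embedding@origin[1] + pts2d[, 1] * embedding@basisU[1] + pts2d[, 2] * embedding@basisV[1],
    embedding@origin[2] + pts2d[, 1] * embedding@basisU[2] + pts2d[, 2] * embedding@basisV[2],
    embedding@origin[3] + pts2d[, 1] * embedding@basisU[3] + pts2d[, 2] * embedding@basisV[3]
  )
  colnames(out) <- c("x", "y", "z")
  out
}

# Min-max normalize to [0, 1]; constant input maps to 0.
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# Sliding-window sums over all fully interior w x w windows via an integral
# image. Returns a matrix of dims dim(m) - w + 1.
boxSum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(m, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  i <- seq_len(nr - w + 1L)
  j <- seq_len(nc - w + 1L)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# Trilinear interpolation of `arr` [z, y, x] at 0-based voxel coordinates
# `pts` (n x 3, columns z, y, x). Coordinates outside [0, dim-1] per axis get
# `fill`. Exact on lattice points and on globally trilinear fields.
trilinearSample <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  # snap near-integer coordinates so lattice points reproduce exactly even
  # after mm <-> voxel unit round trips
  snap <- round(pts)
  pts <- ifelse(abs(pts - snap) < 1e-9, snap, pts)
  z <- pts[, 1]; y <- pts[, 2]; x <- pts[, 3]
  inside <- z >= 0 & z <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    x >= 0 & x <= d[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  z <- z[inside]; y <- y[inside]; x <- x[inside]
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  # clamp the upper corner at the boundary (fraction is 0 there)
  z1 <- pmin(z0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  x1 <- pmin(x0 + 1, d[3] - 1)
  idx <- function(zz, yy, xx) (xx * d[2] + yy) * d[1] + zz + 1
  v000 <- arr[idx(z0, y0, x0)]; v001 <- arr[idx(z0, y0, x1)]
  v010 <- arr[idx(z0, y1, x0)]; v011 <- arr[idx(z0, y1, x1)]
  v100 <- arr[idx(z1, y0, x0)]; v101 <- arr[idx(z1, y0, x1)]
  v110 <- arr[idx(z1, y1, x0)]; v111 <- arr[idx(z1, y1, x1)]
  c00 <- v000 * (1 - fx) + v001 * fx
  c01 <- v010 * (1 - fx) + v011 * fx
  c10 <- v100 * (1 - fx) + v101 * fx
  c11 <- v110 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c01 * fy
  c1 <- c10 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Bilinear interpolation of matrix `img` [y, x] at 0-based pixel coordinates
# (n x 2, columns x, y). Outside coordinates -> NA.
bilinearSample <- function(img, xy) {
  d <- dim(img)
  x <- xy[, 1]; y <- xy[, 2]
  inside <- x >= 0 & x <= d[2] - 1 & y >= 0 & y <= d[1] - 1
  out <- rep(NA_real_, nrow(xy))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, d[2] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  idx <- function(yy, xx) xx * d[1] + yy + 1
  v00 <- img[idx(y0, x0)]; v01 <- img[idx(y0, x1)]
  v10 <- img[idx(y1, x0)]; v11 <- img[idx(y1, x1)]
  out[inside] <- (v00 * (1 - fx) + v01 * fx) * (1 - fy) +
    (v10 * (1 - fx) + v11 * fx) * fy
  out
}

# Block-mean downsampling of a matrix by an integer factor (trailing rows or
# columns that do not fill a block are dropped).
downsampleMean <- function(img, factor) {
  if (factor == 1L) return(img)
  nr <- (nrow(img) %/% factor) * factor
  nc <- (ncol(img) %/% factor) * factor
  m <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- array(m, dim = c(factor, nr %/% factor, factor, nc %/% factor))
  colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# formulation of the Fitzgibbon method) on n >= 5 boundary points.
# Returns the conic coefficients (A, B, C, D, E, F) with the ellipse
# constraint 4AC - B^2 > 0, or NULL when the fit degenerates.
fitConicLS <- function(x, y) {
  if (length(x) < 5L) return(NULL)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), .Machine$double.eps)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T0 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T0)) return(NULL)
  M <- S1 + S2 %*% T0
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- V[, ok[1]]
  coef <- c(a1, as.vector(T0 %*% a1))  # in scaled frame
  # un-scale: substitute xs = (x - mx)/sc, ys = (y - my)/sc
  A <- coef[1] / sc^2
  B <- coef[2] / sc^2
  C <- coef[3] / sc^2
  D <- coef[4] / sc - (2 * coef[1] * mx + coef[2] * my) / sc^2
  E <- coef[5] / sc - (2 * coef[3] * my + coef[2] * mx) / sc^2
  F <- coef[6] - (coef[4] * mx + coef[5] * my) / sc +
    (coef[1] * mx^2 + coef[2] * mx * my + coef[3] * my^2) / sc^2
  c(A, B, C, D, E, F)
}

# Conic coefficients -> list(cx, cy, major, minor, angle_deg) or NULL when
# the conic is not a real ellipse. Axes are full lengths.
conicToEllipse <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  den <- 4 * A * C - B^2
  if (!is.finite(den) || den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  f0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)
  lam <- ev$values  # decreasing
  if (any(-f0 / lam <= 0)) return(NULL)
  semi <- sqrt(-f0 / lam)          # smaller semi-axis first (larger lambda)
  major <- 2 * max(semi); minor <- 2 * min(semi)
  vmaj <- ev$vectors[, which.min(lam)]
  angle <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  if (angle < -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  list(cx = cx, cy = cy, major = major, minor = minor, angle = angle)
}

# Second-moment ellipse of a binary mask [y, x]: the solid ellipse with the
# same centroid and covariance. For a solid ellipse with semi-axes (a, b) the
# coordinate variance along each principal axis is a^2/4, b^2/4.
maskMoments <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(w)
  x <- w[, 2] - 1; y <- w[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  # 1/12 corrects for the extent of square pixels
  cxx <- mean((x - cx)^2) + 1 / 12
  cyy <- mean((y - cy)^2) + 1 / 12
  cxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  semi <- 2 * sqrt(pmax(ev$values, 0))
  vmaj <- ev$vectors[, 1]
  angle <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  if (angle < -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  list(cx = cx, cy = cy, major = 2 * semi[1], minor = 2 * semi[2],
       angle = angle, area = n)
}

shiftMat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, and hysteresis keeping
# weak-edge components connected to a strong edge. Thresholds are fractions
# of the maximum gradient magnitude, making the detector invariant to affine
# intensity rescaling of the input.
cannyEdges <- function(img, low = 0.1, high = 0.3, sigma = 1) {
  stopifnot(low < high)
  g <- as.matrix(EBImage::gblur(img, sigma = sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(g, kx))       # gradient along columns (x)
  gy <- as.matrix(EBImage::filter2(g, t(kx)))    # gradient along rows (y)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0:h 1:d1 2:v 3:d2
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # (dy, dx) per sector
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- shiftMat(mag, o[1], o[2])
    n2 <- shiftMat(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  nms <- mag * keep
  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(weak)
  good <- unique(lab[strong])
  good <- good[good > 0]
  matrix(lab %in% good, nrow(img), ncol(img))
}

# Fill a solid ellipse into a [y, x] logical matrix; parameters in 0-based px.
renderEllipseMask <- function(nrow, ncol, cx, cy, major, minor, angle = 0) {
  xs <- matrix(rep(seq_len(ncol) - 1, each = nrow), nrow, ncol)
  ys <- matrix(rep(seq_len(nrow) - 1, times = ncol), nrow, ncol)
  th <- angle * pi / 180
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (major / 2))^2 + (v / (minor / 2))^2 <= 1
}

# Deterministic local RNG: evaluate `expr` under a seed without disturbing
# the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
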