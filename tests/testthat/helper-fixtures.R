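# Fixtures are generated in code; expensive phantoms are built once per test
# session and cached here.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# standard asymmetric three-cone layout for a 12.7/12.8 mm block (mm)
testConeCenters <- function() {
  list(c(3.2, 3.2), c(9.4, 3.6), c(6.2, 9.8))
}

testPhantom <- function(noiseSigma = 0.025, seed = 42) {
  key <- sprintf("phantom_%g_%d", noiseSigma, seed)
  cachedFixture(key, function() {
    cones <- lapply(testConeCenters(), coneSpec)
    generatePhantomVolume(cones, shape = c(120, 128, 128), voxelSize = 0.1,
                          noiseSigma = noiseSigma, seed = seed)
  })
}

# acceptance-scale phantom: 256^3 at 0.05 mm, noise 5% of marker contrast
acceptancePhantom <- function() {
  cachedFixture("phantom_acceptance", function() {
    cones <- lapply(list(c(3.4, 3.4), c(9.4, 3.8), c(6.2, 9.6)), coneSpec)
    generatePhantomVolume(cones, shape = c(256, 256, 256), voxelSize = 0.05,
                          noiseSigma = 0.05 * 0.5, seed = 42)
  })
}

acceptanceCalibration <- function() {
  cachedFixture("calib_acceptance", function() {
    ph <- acceptancePhantom()
    dets <- detectConeSections(ph$volume, nSample = 100, seed = 7,
                               params = detectionParams(pixelSize = 0.05))
    calibrateCones(dets, pixelSize = 0.05)
  })
}

# independent rendering oracle (not the package's renderer): binary ellipse
renderEllipse <- function(nrow, ncol, cx, cy, a, b, angleDeg = 0) {
  xs <- matrix(rep(seq_len(ncol) - 1, each = nrow), nrow, ncol)
  ys <- matrix(rep(seq_len(nrow) - 1, times = ncol), nrow, ncol)
  th <- angleDeg * pi / 180
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

renderDisk <- function(nrow, ncol, cx, cy, r) {
  renderEllipse(nrow, ncol, cx, cy, r, r)
}

# literal per-window double-loop implementation of the absolute-value LNCC,
# the independent oracle for the vectorized path
lnccOracle <- function(I, J, w) {
  nr <- nrow(I) - w + 1L
  nc <- ncol(I) - w + 1L
  h <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- I[i:(i + w - 1L), j:(j + w - 1L)]
    b <- J[i:(i + w - 1L), j:(j + w - 1L)]
    da <- a - mean(a); db <- b - mean(b)
    va <- sum(da^2); vb <- sum(db^2)
    h[i, j] <- if (va <= 0 || vb <= 0) 0 else abs(sum(da * db)) / sqrt(va * vb)
  }
  h
}

# independent evaluation of a plane embedding at 2D mm points (n x 2) -> n x 3
applyEmbeddingForTest <- function(emb, pts2d) {
  t(apply(pts2d, 1, function(uv)
    emb@origin + uv[1] * emb@basisU + uv[2] * emb@basisV))
}

# analytic cone width (mm) at height h above the base
analyticWidth <- function(h, baseD = 3, apexD = 0.5, height = 11) {
  baseD - (baseD - apexD) * h / height
}
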