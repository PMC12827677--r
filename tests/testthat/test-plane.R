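# build a calibrated phantom + matched section once for the plane tests
planeFixture <- function(tiltDeg = 3) {
  cachedFixture(sprintf("planefix_%g", tiltDeg), function() {
    ph <- testPhantom(noiseSigma = 0.025, seed = 42)
    th <- tiltDeg * pi / 180
    plane <- planeFromNormal(c(0, 0, 5.5), c(0, sin(th), cos(th)))
    sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1, seed = 5)
    dets <- detectConeSections(ph$volume, nSample = 60, seed = 7,
                               params = detectionParams(pixelSize = 0.1))
    calib <- calibrateCones(dets, pixelSize = 0.1)
    sd <- detectSectionEllipses(sec$image, detectionParams(pixelSize = 0.1))
    layout <- do.call(rbind, lapply(calib$tracks, meanCenter))
    rownames(layout) <- vapply(calib$tracks, coneId, integer(1))
    mk <- matchToCones(sd, layout, pixelSize = 0.1)
    list(ph = ph, plane = plane, sec = sec, calib = calib, mk = mk)
  })
}

test_that("cone points recover the cutting heights from section widths", {
  fx <- planeFixture(0)  # horizontal truth plane at 5.5 mm
  pts <- locateConePoints(fx$mk, fx$calib$models, 0.1)
  # all three recovered z within 2 voxel-heights of 5.5 mm
  expect_true(all(abs(pts[, "z"] - 5.5) < 0.2))
  fxT <- planeFixture(3)  # tilt about x: z decreases with y
  ptsT <- locateConePoints(fxT$mk, fxT$calib$models, 0.1)
  ord <- order(ptsT[, "y"])
  expect_gt(ptsT[ord[1], "z"], ptsT[ord[3], "z"])
})

test_that("missing taper models are reported by cone id", {
  fx <- planeFixture(0)
  expect_error(locateConePoints(fx$mk, fx$calib$models[1:2], 0.1),
               "no taper model")
})

test_that("three-point embeddings solve the affine correspondence exactly", {
  # axis-aligned: 2D points equal the 3D (x, y), constant z
  s2 <- rbind(c(0, 0), c(4, 0), c(0, 6))
  p3 <- cbind(s2, 7)
  emb <- buildEmbedding(s2, p3)
  expect_equal(abs(emb@normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(emb@basisU, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(emb@basisV, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(emb@origin, c(0, 0, 7), tolerance = 1e-12)
  # known rotation about x
  th <- 23 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  p3r <- t(R %*% t(p3))
  embR <- buildEmbedding(s2, p3r)
  want <- as.vector(R %*% c(0, 0, 1))
  expect_lt(normalAngle(embR@normal, want), 1e-9)
  expect_error(buildEmbedding(rbind(c(0, 0), c(1, 1), c(2, 2)), p3),
               "collinear")
  expect_error(buildEmbedding(s2, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("axis-aligned extraction reproduces a volume slice exactly", {
  set.seed(21)
  vol <- voxelVolume(array(runif(30 * 40 * 50), c(30, 40, 50)), 0.1)
  k <- 12
  emb <- planeFromNormal(c(0, 0, k * 0.1), c(0, 0, 1))
  sl <- extractObliqueSlice(vol, emb, outShape = c(40, 50))
  expect_identical(imageData(sl), vol@data[k + 1, , ])
})

test_that("half-slice extraction of a z-linear volume averages neighbors", {
  arr <- array(rep(seq_len(20) * 0.01, 16 * 16), c(20, 16, 16))
  vol <- voxelVolume(arr, 0.1)
  emb <- planeFromNormal(c(0, 0, 7.5 * 0.1), c(0, 0, 1))
  sl <- extractObliqueSlice(vol, emb, outShape = c(16, 16))
  expect_equal(imageData(sl),
               (arr[8, , ] + arr[9, , ]) / 2, tolerance = 1e-12)
})

test_that("trilinear sampling is exact for globally trilinear fields", {
  d <- c(12, 14, 16)
  co <- runif(8, -2, 2)
  f <- function(x, y, z) co[1] + co[2] * x + co[3] * y + co[4] * z +
    co[5] * x * y + co[6] * x * z + co[7] * y * z + co[8] * x * y * z
  arr <- array(0, d)
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3])
    arr[k, j, i] <- f(i - 1, j - 1, k - 1)
  vol <- voxelVolume(arr - min(arr), 1)  # keep values finite/positive
  off <- min(arr)
  set.seed(5)
  emb <- planeFromNormal(c(4.3, 5.1, 3.7), c(0.2, -0.3, 0.93))
  sl <- imageData(extractObliqueSlice(vol, emb, outShape = c(5, 5), pitch = 0.7))
  for (i in 1:5) for (j in 1:5) {
    p <- emb@origin + (j - 1) * 0.7 * emb@basisU + (i - 1) * 0.7 * emb@basisV
    expect_equal(sl[i, j], f(p[1], p[2], p[3]) - off, tolerance = 1e-9)
  }
})

test_that("out-of-volume plane regions take the fill value", {
  vol <- voxelVolume(array(1, c(10, 32, 32)), 1)
  emb <- planeFromNormal(c(0, 0, 8), c(0, sin(0.3), cos(0.3)))
  sl <- imageData(extractObliqueSlice(vol, emb, outShape = c(32, 32),
                                      fillValue = -7))
  # the plane exits through the top of the volume as v grows: z = 8 - tan(...)
  expect_true(any(sl == -7))
  expect_true(all(sl %in% c(1, -7)))
  expect_true(all(sl[1, ] == 1))
})

test_that("plane recovery is equivariant under in-plane rotation of the section", {
  fx <- planeFixture(3)
  pts <- locateConePoints(fx$mk, fx$calib$models, 0.1)
  s2 <- cbind(fx$mk@ellipses$cx[fx$mk@assignment],
              fx$mk@ellipses$cy[fx$mk@assignment]) * 0.1
  emb1 <- buildEmbedding(s2, pts)
  phi <- 40 * pi / 180
  R <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  emb2 <- buildEmbedding(s2 %*% t(R), pts)
  expect_lt(normalAngle(emb1@normal, emb2@normal), 1e-9)
})

test_that("end-to-end plane recovery meets the angular and distance budget", {
  fx <- planeFixture(3)
  pts <- locateConePoints(fx$mk, fx$calib$models, 0.1)
  s2 <- cbind(fx$mk@ellipses$cx[fx$mk@assignment],
              fx$mk@ellipses$cy[fx$mk@assignment]) * 0.1
  emb <- buildEmbedding(s2, pts)
  expect_lt(normalAngle(emb@normal, fx$plane@normal), 2.5)
  g <- as.matrix(expand.grid(seq(0, 12.7, by = 0.25), seq(0, 12.7, by = 0.25)))
  P <- applyEmbeddingForTest(emb, g)
  dist <- abs((P - matrix(fx$plane@origin, nrow(P), 3, byrow = TRUE)) %*%
                fx$plane@normal)
  expect_lt(mean(dist) / 0.1, 2)
})
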