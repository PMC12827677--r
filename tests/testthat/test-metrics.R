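test_that("vectorized LNCC equals the literal per-window double loop", {
  set.seed(31)
  for (w in c(15, 45)) {
    I <- matrix(rnorm(64 * 72), 64, 72)
    J <- matrix(rnorm(64 * 72), 64, 72)
    r <- lncc(I, J, w)
    expect_lt(max(abs(heatmap2(r) - lnccOracle(I, J, w))), 1e-6)
    expect_equal(dim(heatmap2(r)), dim(I) - w + 1)
  }
})

test_that("LNCC analytic properties hold", {
  set.seed(32)
  I <- matrix(rnorm(60 * 60), 60, 60)
  expect_equal(meanLNCC(lncc(I, I, 15)), 1)
  expect_equal(maxLNCC(lncc(I, I, 15)), 1)
  # invariance to linear intensity maps, including inversion
  expect_equal(meanLNCC(lncc(I, -2 * I + 3, 15)), 1)
  expect_equal(meanLNCC(lncc(I, 0.5 * I - 1, 15)), 1)
  # zero-variance windows contribute 0
  I2 <- I
  I2[1:30, 1:30] <- 0.42
  r <- lncc(I2, I, 15)
  expect_identical(heatmap2(r)[1, 1], 0)
  # symmetry and bounds
  J <- matrix(rnorm(60 * 60), 60, 60)
  expect_equal(meanLNCC(lncc(I, J, 15)), meanLNCC(lncc(J, I, 15)),
               tolerance = 1e-12)
  r2 <- lncc(I, J, 15)
  expect_gte(meanLNCC(r2), 0)
  expect_lte(meanLNCC(r2), maxLNCC(r2))
  expect_lte(maxLNCC(r2), 1)
})

test_that("LNCC input contracts are enforced", {
  I <- matrix(0, 32, 32)
  expect_error(lncc(I, matrix(0, 32, 33), 15), "identical dimensions")
  expect_error(lncc(I, I, 45), "larger than the image")
  expect_error(lncc(I, I, 14), "odd")
})

test_that("layer sweep finds the true cutting layer and honors ties", {
  ph <- testPhantom(noiseSigma = 0.025, seed = 42)
  kstar <- 55
  plane <- planeFromNormal(c(0, 0, kstar * 0.1), c(0, 0, 1))
  sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1, seed = 5)
  sw <- lnccLayerSweep(ph$volume, sec$image, window = 45)
  expect_equal(sw$bestLayer, kstar)
  # identical layers: all scores equal, argmax falls on the first layer
  arr <- array(0, c(5, 64, 64))
  for (k in 1:5) arr[k, , ] <- matrix(sin(seq_len(64^2)), 64)
  sw2 <- lnccLayerSweep(voxelVolume(arr, 1), arr[1, , ], window = 15)
  expect_equal(length(unique(round(sw2$scores, 12))), 1)
  expect_equal(sw2$bestLayer, 0L)
})

test_that("a tilted cutting plane beats every flat layer", {
  ph <- testPhantom(noiseSigma = 0.025, seed = 42)
  th <- 3 * pi / 180
  plane <- planeFromNormal(c(0, 6.35, 5.5), c(0, sin(th), cos(th)))
  sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1, seed = 5)
  sw <- lnccLayerSweep(ph$volume, sec$image, window = 45)
  ext <- extractObliqueSlice(ph$volume, plane,
                             outShape = dim(imageData(sec$image)))
  sc <- meanLNCC(lncc(imageData(ext), imageData(sec$image), 45))
  expect_gte(sc, max(sw$scores))
})

test_that("checkerboard overlay alternates tiles as enumerated", {
  a <- matrix(1, 4, 4)
  b <- matrix(2, 4, 4)
  cb <- overlayCheckerboard(a, b, tile = 2)
  expect_equal(cb, rbind(c(1, 1, 2, 2), c(1, 1, 2, 2),
                         c(2, 2, 1, 1), c(2, 2, 1, 1)))
  expect_equal(overlayCheckerboard(a, a, 2), a)
  expect_equal(overlayCheckerboard(a, b, 10), a)  # single tile: all from a
  expect_error(overlayCheckerboard(a, matrix(0, 3, 4), 2), "dimensions")
})

test_that("rigid registration recovers planted transforms under noise", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  plane <- planeFromNormal(c(0, 0, 5.5), c(0, 0, 1))
  sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1,
                            stainParams = list(noiseSigma = 0), seed = 5)
  img <- imageData(sec$image)
  rng <- diff(range(img))
  set.seed(33)
  cases <- list(c(0, 0, 0), c(4, 7, -5), c(-3, -8, 9))
  for (cs in cases) {
    tr <- rigidTransform2D(rotation = cs[1], translation = cs[2:3])
    mov <- applyRigidTransform(img, tr, fillValue = 0)
    movN <- mov + rnorm(length(mov), 0, 0.1 * rng)   # 10% noise
    fixN <- img + rnorm(length(img), 0, 0.1 * rng)
    reg <- rigidRegister(fixN, matrix(movN, nrow(img)),
                         init = rigidTransform2D())
    # small 128 px sections: the noise-perturbed MSE minimum itself moves by
    # a few tenths of a degree; the full-size recovery bound is checked on
    # the larger sections in the acceptance suite
    expect_lt(abs(reg$transform@rotation - cs[1]), 0.4)
    expect_lt(sqrt(sum((reg$transform@translation - cs[2:3])^2)), 0.5)
  }
  # moving == fixed: identity within tolerance and near-zero MSE
  regId <- rigidRegister(img, img)
  expect_lt(abs(regId$transform@rotation), 0.1)
  expect_lt(sqrt(sum(regId$transform@translation^2)), 0.1)
  expect_lt(regId$mse, 1e-4)
})

test_that("registration rejects empty initial overlap", {
  img <- matrix(runif(64^2), 64)
  expect_error(
    rigidRegister(img, img, init = rigidTransform2D(translation = c(500, 0))),
    "overlap")
})
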