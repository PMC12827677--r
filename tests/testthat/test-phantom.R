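test_that("analytic taper: 1.75 mm width at 5.5 mm height is 35 voxels of 0.05 mm", {
  cone <- coneSpec(c(2, 2))
  ph <- generatePhantomVolume(list(cone), shape = c(224, 80, 80),
                              voxelSize = 0.05, tissueParams = NULL,
                              noiseSigma = 0, seed = 1)
  # slice index 110 -> h = 5.5 mm
  expect_equal(ph$truth@trueWidths[111, 1], 1.75)
  expect_equal(ph$truth@trueWidths[111, 1] / 0.05, 35)
  expect_equal(ph$truth@trueWidths[1, 1], 3)
  h <- (0:220) * 0.05
  expect_equal(ph$truth@trueWidths[1:221, 1], analyticWidth(h))
})

test_that("noiseless tissue-free phantom is exactly binary (plus sedimentation)", {
  cone <- coneSpec(c(2, 2), height = 5, attenuation = 1,
                   sedimentationSlope = 0)
  ph <- generatePhantomVolume(list(cone), shape = c(60, 44, 44),
                              voxelSize = 0.1, mediumValue = 0,
                              tissueParams = NULL, noiseSigma = 0, seed = 1)
  vals <- unique(as.vector(imageData(ph$volume)))
  expect_setequal(vals, c(0, 1))
  # with sedimentation, in-marker values are attenuation + slope * h exactly
  cone2 <- coneSpec(c(2, 2), height = 5, attenuation = 1,
                    sedimentationSlope = -0.05)
  ph2 <- generatePhantomVolume(list(cone2), shape = c(60, 44, 44),
                               voxelSize = 0.1, mediumValue = 0,
                               tissueParams = NULL, noiseSigma = 0, seed = 1)
  arr <- imageData(ph2$volume)
  k <- 31  # z index 30 -> h = 3 mm
  marker <- arr[k, , ][arr[k, , ] > 0]
  expect_true(all(abs(marker - (1 - 0.05 * 3)) < 1e-12))
})

test_that("volume generation is deterministic given a seed", {
  cones <- lapply(testConeCenters(), coneSpec, height = 3)
  a <- generatePhantomVolume(cones, shape = c(40, 128, 128), voxelSize = 0.1,
                             noiseSigma = 0.03, seed = 9)
  b <- generatePhantomVolume(cones, shape = c(40, 128, 128), voxelSize = 0.1,
                             noiseSigma = 0.03, seed = 9)
  expect_identical(imageData(a$volume), imageData(b$volume))
  d <- generatePhantomVolume(cones, shape = c(40, 128, 128), voxelSize = 0.1,
                             noiseSigma = 0.03, seed = 10)
  expect_false(identical(imageData(a$volume), imageData(d$volume)))
})

test_that("half-contrast thresholding reproduces the analytic width within 1 voxel", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  arr <- imageData(ph$volume)
  truth <- ph$truth
  cut <- (truth@mediumValue + truth@coneSpecs[[1]]@attenuation) / 2
  for (k in c(1, 26, 56, 86, 111)) {
    bw <- arr[k, , ] > cut
    for (j in seq_along(truth@coneSpecs)) {
      w <- truth@trueWidths[k, j]
      if (is.na(w)) next
      cx <- truth@trueCenters$cx[k, j]
      cy <- truth@trueCenters$cy[k, j]
      row <- bw[round(cy) + 1L, ]
      # horizontal extent through the cone center, excluding tissue runs
      run <- range(which(row & abs(seq_along(row) - 1 - cx) < w / 0.1))
      measured <- (run[2] - run[1] + 1) * 0.1
      expect_lt(abs(measured - w), 0.1 + 1e-9)
    }
  }
})

test_that("ill-posed cone layouts are rejected with informative errors", {
  expect_error(
    generatePhantomVolume(list(coneSpec(c(1, 1))), shape = c(120, 128, 128),
                          voxelSize = 0.1, seed = 1),
    "cone 1 extends outside")
  expect_error(
    generatePhantomVolume(list(coneSpec(c(5, 5)), coneSpec(c(6, 5))),
                          shape = c(120, 128, 128), voxelSize = 0.1, seed = 1),
    "cones 1 and 2 overlap")
})

test_that("horizontal section matches the analytic circular footprint", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  h <- 5.5
  plane <- planeFromNormal(c(0, 0, h), c(0, 0, 1))
  sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1, seed = 3)
  expect_equal(nrow(sec$ellipses), 3)
  wpx <- analyticWidth(h) / 0.1
  for (i in 1:3) {
    expect_equal(sec$ellipses$major[i], wpx, tolerance = 1e-9)
    expect_equal(sec$ellipses$minor[i], wpx, tolerance = 1e-9)
    # centers coincide with the volume-slice centers (same frame, 0.5 px)
    expect_lt(abs(sec$ellipses$cx[i] - ph$truth@trueCenters$cx[56, i]), 0.5)
    expect_lt(abs(sec$ellipses$cy[i] - ph$truth@trueCenters$cy[56, i]), 0.5)
  }
})

test_that("section eccentricity grows with plane tilt", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  ecc <- vapply(c(0, 2, 4), function(deg) {
    th <- deg * pi / 180
    plane <- planeFromNormal(c(0, 0, 5.5), c(0, sin(th), cos(th)))
    e <- sampleSectionImage(ph$truth, plane, pixelSize = 0.1, seed = 3)$ellipses
    max(sqrt(1 - (e$minor / e$major)^2))
  }, numeric(1))
  expect_lt(ecc[1], 1e-6)          # no tilt: circles
  expect_true(all(diff(ecc) > 0))  # monotone in tilt
})

test_that("binary stain map yields three marker components plus tissue", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  plane <- planeFromNormal(c(0, 0, 5.5), c(0, 0, 1))
  sec <- sampleSectionImage(
    ph$truth, plane, pixelSize = 0.1, seed = 3,
    stainParams = list(background = 0, tissueLow = 0, tissueHigh = 0,
                       marker = 1, noiseSigma = 0))
  img <- imageData(sec$image)
  expect_setequal(unique(as.vector(img)), c(0, 1))
  lab <- EBImage::bwlabel(img == 1)
  expect_equal(max(lab), 3)
})

test_that("a plane missing a cone names the cones that are cut", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  plane <- planeFromNormal(c(0, 0, 11.5), c(0, 0, 1))  # above every apex
  expect_error(sampleSectionImage(ph$truth, plane, pixelSize = 0.1),
               "plane misses cone")
})
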