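test_that("slice sampling is unique, sorted, in range and deterministic", {
  idx <- sampleSliceIndices(1982, 500, seed = 7)
  expect_length(idx, 500)
  expect_false(any(duplicated(idx)))
  expect_true(all(idx >= 0 & idx <= 1981))
  expect_identical(idx, sort(idx))
  expect_identical(idx, sampleSliceIndices(1982, 500, seed = 7))
  expect_false(identical(idx, sampleSliceIndices(1982, 500, seed = 8)))
  expect_identical(sampleSliceIndices(10, 10, seed = 1), 0:9)
  expect_error(sampleSliceIndices(10, 11, seed = 1), "nSample")
})

test_that("a rendered disk is detected with sub-pixel center accuracy", {
  img <- matrix(0.1, 160, 160)
  img[renderDisk(160, 160, cx = 70.5, cy = 88.5, r = 25)] <- 0.9
  det <- detectEllipsesSlice(img, detectionParams())
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$cx - 70.5), 1)
  expect_lt(abs(det$cy - 88.5), 1)
  expect_lt(abs(det$major - 50), 2)
  expect_lt(abs(det$minor - 50), 2)
})

test_that("structure-free images yield no detections", {
  expect_equal(nrow(detectEllipsesSlice(matrix(0.5, 128, 128),
                                        detectionParams())), 0)
})

test_that("the eccentricity filter rejects elongated fits", {
  img <- matrix(0, 160, 160)
  img[renderEllipse(160, 160, 80, 80, a = 40, b = 12)] <- 1  # ecc ~ 0.954
  strict <- detectionParams(maxEccentricity = 0.9)
  loose <- detectionParams(maxEccentricity = 0.99)
  expect_equal(nrow(detectEllipsesSlice(img, strict)), 0)
  expect_equal(nrow(detectEllipsesSlice(img, loose)), 1)
})

test_that("detection is invariant under affine intensity rescaling", {
  img <- matrix(0.1, 160, 160)
  img[renderDisk(160, 160, 70, 90, 20)] <- 0.8
  d1 <- detectEllipsesSlice(img, detectionParams())
  d2 <- detectEllipsesSlice(1000 * img - 37, detectionParams())
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("images smaller than the threshold block are rejected", {
  expect_error(detectEllipsesSlice(matrix(0, 32, 32), detectionParams()),
               "block size")
})

test_that("the built-in backend segments prompted disks and drops background prompts", {
  img <- matrix(0, 128, 128)
  disk <- renderDisk(128, 128, 40, 40, 18)
  img[disk] <- 1
  m <- segmentWithBackend(img, rbind(c(40, 40)))
  expect_length(m, 1)
  # mask equals the disk within a 1 px boundary band
  dil <- as.matrix(EBImage::dilate(disk + 0, EBImage::makeBrush(3, "disc"))) > 0
  ero <- as.matrix(EBImage::erode(disk + 0, EBImage::makeBrush(3, "disc"))) > 0
  expect_true(all(m[[1]][ero]))
  expect_true(all(dil[m[[1]]]))
  # background prompt -> empty result
  expect_length(segmentWithBackend(img, rbind(c(100, 100))), 0)
  # two disks, two prompts -> two disjoint masks
  img2 <- img
  img2[renderDisk(128, 128, 90, 90, 14)] <- 1
  m2 <- segmentWithBackend(img2, rbind(c(40, 40), c(90, 90)))
  expect_length(m2, 2)
  expect_equal(sum(m2[[1]] & m2[[2]]), 0)
})

test_that("a failing external backend falls back to the built-in one", {
  img <- matrix(0, 64, 64)
  img[renderDisk(64, 64, 32, 32, 10)] <- 1
  expect_warning(
    m <- segmentWithBackend(img, rbind(c(32, 32)),
                            backend = function(...) stop("no GPU")),
    "falling back")
  expect_length(m, 1)
})

test_that("mask moments recover disk and ellipse axes", {
  disk <- renderDisk(128, 128, 64, 64, 20)
  d <- maskToEllipse(disk, sliceIndex = 5L)
  expect_equal(d$slice_index, 5L)
  expect_lt(abs(d$major - 40), 1)
  expect_lt(abs(d$minor - 40), 1)
  ell <- renderEllipse(128, 128, 64, 64, a = 20, b = 10, angleDeg = 30)
  e <- maskToEllipse(ell)
  expect_lt(abs(e$major - 40), 2)
  expect_lt(abs(e$minor - 20), 2)
  expect_lt(abs(e$angle - 30), 3)
  one <- matrix(FALSE, 16, 16); one[8, 8] <- TRUE
  expect_error(maskToEllipse(one), "too small")
})

test_that("rule-based and backend measurements agree on clean disks", {
  img <- matrix(0, 160, 160)
  img[renderDisk(160, 160, 80, 80, 22)] <- 1
  rule <- detectEllipsesSlice(img, detectionParams())
  m <- segmentWithBackend(img, rbind(c(80, 80)))
  backend <- maskToEllipse(m[[1]])
  expect_lt(abs(rule$major - backend$major), 2)
})

test_that("all in-view cross-sections are detected on noiseless phantom slices", {
  ph <- testPhantom(noiseSigma = 0, seed = 42)
  truth <- ph$truth
  idx <- sampleSliceIndices(120, 40, seed = 3)
  dets <- detectConeSections(ph$volume, nSample = 40, seed = 3,
                             params = detectionParams(pixelSize = 0.1))
  for (k in idx[idx <= 110]) for (j in 1:3) {
    dd <- dets[dets$slice_index == k, ]
    d2 <- sqrt((dd$cx - truth@trueCenters$cx[k + 1, j])^2 +
                 (dd$cy - truth@trueCenters$cy[k + 1, j])^2)
    expect_gte(nrow(dd), 1)
    i <- which.min(d2)
    expect_lt(d2[i], 1)
    expect_lt(abs(dd$major[i] - truth@trueWidths[k + 1, j] / 0.1), 2)
  }
})
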