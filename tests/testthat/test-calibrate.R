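# synthetic detection table: one detection per slice per listed center,
# width following the analytic taper (in px at `pixelSize`)
syntheticDetections <- function(centers, slices, pixelSize = 0.05,
                                widthNoise = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(centers), function(j) {
    w <- analyticWidth(slices * pixelSize) / pixelSize
    data.frame(slice_index = slices,
               cx = centers[[j]][1] + rnorm(length(slices), 0, 0.05),
               cy = centers[[j]][2] + rnorm(length(slices), 0, 0.05),
               major = w + rnorm(length(slices), 0, widthNoise),
               minor = w, angle = 0, source = "rule",
               stringsAsFactors = FALSE)
  }))
}

test_that("well-separated detections cluster into accurate tracks", {
  centers <- list(c(40, 40), c(180, 50), c(110, 190))
  dets <- syntheticDetections(centers, 0:49)
  tracks <- clusterDetections(dets, nCones = 3)
  expect_length(tracks, 3)
  got <- do.call(rbind, lapply(tracks, meanCenter))
  want <- do.call(rbind, centers[order(sapply(centers, `[`, 1))])
  expect_true(all(sqrt(rowSums((got - want)^2)) < 1))
})

test_that("single-cluster and outlier cases behave per contract", {
  dets <- syntheticDetections(list(c(64, 64)), 0:19)
  tr <- clusterDetections(dets, nCones = 1)
  expect_length(tr, 1)
  expect_equal(nrow(detections(tr[[1]])), 20)
  # a far-away false positive is left unassigned
  far <- dets[1, ]; far$cx <- 5000; far$cy <- 5000
  tr2 <- clusterDetections(rbind(dets, far), nCones = 1,
                           distanceThreshold = 50)
  expect_equal(nrow(detections(tr2[[1]])), 20)
  expect_error(clusterDetections(dets[dets$slice_index == 0, ], nCones = 1),
               "distinct slices")
})

test_that("filterOutliers flags displaced and mis-sized detections", {
  dets <- syntheticDetections(list(c(64, 64)), 0:19)
  tr <- clusterDetections(dets, nCones = 1)[[1]]
  det <- detections(tr)
  det$cx[5] <- det$cx[5] + 500  # 10x any sensible threshold
  tr2 <- new("ConeTrack", coneId = 1L, detections = det,
             inlier = rep(TRUE, nrow(det)), meanCenter = meanCenter(tr))
  out <- filterOutliers(tr2, distanceThreshold = 50)
  expect_equal(which(!inliers(out)), 5L)
  # identical detections: none flagged
  same <- det[rep(1, 10), ]
  tr3 <- new("ConeTrack", coneId = 1L, detections = same,
             inlier = rep(TRUE, 10), meanCenter = c(same$cx[1], same$cy[1]))
  expect_true(all(inliers(filterOutliers(tr3, distanceThreshold = 1))))
  # width bound below every width: error
  expect_error(filterOutliers(tr2, widthBounds = c(0, 1)), "outliers")
})

test_that("two-pass taper fit recovers an exact line to 1e-9", {
  pixelSize <- 0.05
  dets <- syntheticDetections(list(c(64, 64)), seq(0, 196, by = 4), pixelSize)
  dets$cx <- 64; dets$cy <- 64  # exact line, no jitter
  tr <- clusterDetections(dets, nCones = 1)[[1]]
  m <- fitTaper(tr, pixelSize)
  trueSlope <- -(3 - 0.5) / 11 * pixelSize  # mm per slice index
  expect_equal(m@slope, trueSlope, tolerance = 1e-9)
  expect_equal(m@intercept, 3, tolerance = 1e-9)
})

test_that("pass 2 shrugs off planted gross outliers", {
  pixelSize <- 0.05
  dets <- syntheticDetections(list(c(64, 64)), 0:49, pixelSize,
                              widthNoise = 0.1, seed = 4)
  dets$major[c(7, 23, 41)] <- dets$major[c(7, 23, 41)] + c(15, -20, 25)
  tr <- clusterDetections(dets, nCones = 1)[[1]]
  m <- fitTaper(tr, pixelSize)
  trueSlope <- -(3 - 0.5) / 11 * pixelSize
  expect_lt(abs((m@slope - trueSlope) / trueSlope), 0.005)
})

test_that("two points give the exact interpolating line", {
  dets <- data.frame(slice_index = c(0L, 100L), cx = c(10, 10), cy = c(10, 10),
                     major = c(60, 38), minor = c(60, 38), angle = 0,
                     source = "rule")
  tr <- new("ConeTrack", coneId = 1L, detections = dets,
            inlier = c(TRUE, TRUE), meanCenter = c(10, 10))
  m <- fitTaper(tr, pixelSize = 0.05)
  expect_equal(widthAt(m, 0), 3, tolerance = 1e-12)
  expect_equal(widthAt(m, 100), 1.9, tolerance = 1e-12)
})

test_that("width-height lookup inverts the calibration", {
  pixelSize <- 0.05
  dets <- syntheticDetections(list(c(64, 64)), seq(0, 196, by = 4), pixelSize)
  dets$cx <- 64; dets$cy <- 64
  m <- fitTaper(clusterDetections(dets, nCones = 1)[[1]], pixelSize)
  # 1.75 mm on the analytic model sits at slice index 110 (h = 5.5 mm)
  expect_equal(widthToHeight(m, 1.75), 110, tolerance = 1e-6)
  expect_equal(widthToHeight(m, m@intercept), 0, tolerance = 1e-9)
  for (z in c(3.3, 77.7, 141)) {
    expect_equal(widthToHeight(m, widthAt(m, z)), z, tolerance = 1e-9)
  }
  expect_warning(widthToHeight(m, 10), "extrapolating")
})

test_that("calibration on the phantom matches the analytic taper within 3%", {
  ph <- testPhantom(noiseSigma = 0.025, seed = 42)  # 5% of marker contrast
  dets <- detectConeSections(ph$volume, nSample = 60, seed = 7,
                             params = detectionParams(pixelSize = 0.1))
  calib <- calibrateCones(dets, pixelSize = 0.1)
  trueSlope <- -(3 - 0.5) / 11 * 0.1
  for (m in calib$models) {
    expect_lt(abs((m@slope - trueSlope) / trueSlope), 0.03)
    # apex position: width = 0.5 mm at slice 110
    expect_lt(abs(suppressWarnings(widthToHeight(m, 0.5)) - 110), 2)
  }
})
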