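test_that("thresholding and 8-connected labeling count constructed beads", {
  set.seed(5)
  centers <- cbind(x = seq(10, 110, by = 11), y = seq(10, 110, by = 11))[1:10, ]
  img <- renderSquareBeads(128, centers, halfWidth = 1, value = 1000)
  seg <- segmentSpots(img, method = "fixed", threshold = 500)
  expect_equal(beadCount(seg), 10)
  # centroids sit at the bead centres (symmetric squares, centre of pixel
  # c is at x = c - 0.5)
  cen <- beadCentroids(seg)
  expect_equal(sort(cen$x), sort(centers[, 1] - 0.5))

  # blank noise image with a threshold above the noise ceiling
  noise <- matrix(abs(rnorm(64 * 64, 10, 3)), 64)
  seg0 <- segmentSpots(noise, method = "fixed", threshold = 100)
  expect_equal(beadCount(seg0), 0)

  # two beads 1 px apart merge into one component
  img2 <- matrix(0, 32, 32)
  img2[10:12, 10:12] <- 800
  img2[10:12, 14:16] <- 800  # gap column 13
  expect_equal(beadCount(segmentSpots(img2, "fixed", threshold = 400)), 2)
  img2[10:12, 13] <- 800     # close the gap
  expect_equal(beadCount(segmentSpots(img2, "fixed", threshold = 400)), 1)

  # diagonal contact is 8-connected: still one component
  img3 <- matrix(0, 16, 16)
  img3[4, 4] <- 900; img3[5, 5] <- 900
  expect_equal(beadCount(segmentSpots(img3, "fixed", threshold = 400)), 1)
})

test_that("otsu threshold separates bright beads from background", {
  set.seed(9)
  centers <- cbind(x = c(20, 50, 80), y = c(30, 60, 90))
  img <- renderSquareBeads(110, centers, halfWidth = 2, value = 3000) +
    matrix(abs(rnorm(110 * 110, 100, 20)), 110)
  seg <- segmentSpots(img, method = "otsu")
  expect_equal(beadCount(seg), 3)
  expect_gt(beadThreshold(seg), 200)
  expect_error(segmentSpots(img, method = "fixed"), "threshold")
})

test_that("region counting uses the centroid rule", {
  centers <- cbind(x = c(10, 30, 50, 70, 90, 15, 35, 55, 75, 95),
                   y = c(10, 10, 10, 10, 10, 60, 60, 60, 60, 60))
  img <- renderSquareBeads(110, centers, halfWidth = 1, value = 1000)
  seg <- segmentSpots(img, "fixed", threshold = 500)
  roiMask <- matrix(TRUE, 110, 110)
  bandMask <- matrix(FALSE, 110, 110); bandMask[1:20, ] <- TRUE  # y <= 20
  cnt <- countInRegions(seg, roiMask, bandMask)
  expect_equal(cnt$n_total_in_roi, 10)
  expect_equal(cnt$n_in_band, 5)

  # empty segmentation
  seg0 <- segmentSpots(matrix(0, 20, 20), "fixed", threshold = 10)
  cnt0 <- countInRegions(seg0, matrix(TRUE, 20, 20), matrix(TRUE, 20, 20))
  expect_equal(unlist(cnt0), c(n_total_in_roi = 0L, n_in_band = 0L))

  expect_error(countInRegions(seg, matrix(TRUE, 5, 5), bandMask), "mismatch")
})

test_that("fraction within the membrane band counts centroids with the closed tie rule", {
  roi <- cellROI(cbind(c(0, 300, 300, 0), c(0, 0, 300, 300)), 0.03)
  # distances to the left edge: 10 px = 300 nm etc.
  cen <- cbind(x = c(10, 20, 23, 150), y = rep(150, 4))
  expect_equal(fractionWithinBoundary(cen, roi, bandNm = 700), 0.75)
  expect_equal(fractionWithinBoundary(cen[1:3, ], roi, bandNm = 700), 1.0)
  # exactly on the 700 nm edge: 700/30 px from the boundary -> counted in
  onEdge <- cbind(x = 700 / 30, y = 150)
  expect_equal(fractionWithinBoundary(onEdge, roi, bandNm = 700), 1.0)
  outside <- cbind(x = -5, y = -5)
  expect_error(fractionWithinBoundary(outside, roi), "no centroid")
})

test_that("uptake curves collate frames and reject unsorted input", {
  df <- data.frame(frame_time_min = c(20, 50, 80),
                   n_total = c(0, 0, 0), n_in_band = c(0, 0, 0))
  uc <- uptakeCurve(df)
  expect_equal(uc$curve$n_total, c(0, 0, 0))
  expect_equal(uc$first$frame_time_min, 20)
  expect_equal(uc$last$frame_time_min, 80)

  one <- df[2, ]
  uc1 <- uptakeCurve(one)
  expect_equal(uc1$first, uc1$last)

  expect_error(uptakeCurve(df[c(2, 1, 3), ]), "sorted")
})

test_that("segmentation recovers well-separated synthetic beads with high recall and precision", {
  hits <- 0; total <- 0; spurious <- 0
  for (seed in 1:25) {
    set.seed(seed)
    # >= 4 sigma separation on a grid, SNR >= 5 over Gaussian noise
    gx <- seq(15, 113, by = 14)
    grid <- as.matrix(expand.grid(x = gx, y = gx))
    keep <- grid[runif(nrow(grid)) < 0.5, , drop = FALSE]
    if (!nrow(keep)) next
    img <- renderSquareBeads(128, keep, halfWidth = 1, value = 500) +
      matrix(abs(rnorm(128 * 128, 50, 10)), 128)
    seg <- segmentSpots(img, method = "otsu")
    total <- total + nrow(keep)
    hits <- hits + min(beadCount(seg), nrow(keep))
    spurious <- spurious + max(0, beadCount(seg) - nrow(keep))
  }
  expect_gte(hits / total, 0.99)
  expect_lte(spurious / max(1, hits), 0.01)
})

test_that("segment-and-count recovers time-lapse ground truth for non-overlapping beads", {
  checked <- 0
  for (seed in 17:22) {
    tl <- generateTimelapse(cellSpec(imageSize = 192, seed = seed,
                                     spotSigmaNm = 45),
                            nFrames = 3, frameIntervalMin = 60,
                            uptakeRate = 0.5, capacity = 8)
    for (f in tl) {
      truthN <- f$nBeads
      if (truthN == 0) next
      # only assert exact recovery when the ground truth is pairwise
      # separated by > 6 px (touching beads merge by design)
      xy <- as.matrix(f$truth[, c("x_px", "y_px")])
      if (truthN > 1 && min(dist(xy)) <= 6) next
      # beads grazing the membrane (< 1 px) can rasterize their centroid
      # pixel outside the ROI mask; the centroid-in-ROI rule excludes them
      if (min(f$truth$distance_nm) < pixelSize(f$roi) * 1000) next
      corrected <- subtractBackground(targetChannel(f$images))
      seg <- segmentSpots(corrected, method = "otsu")
      mask <- polygonToMask(f$roi, c(192, 192))
      cnt <- countInRegions(seg, mask, mask)
      expect_equal(cnt$n_total_in_roi, truthN)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 3)
})
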