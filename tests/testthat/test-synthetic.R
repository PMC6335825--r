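test_that("spec validation rejects impossible cells", {
  expect_error(cellSpec(clusteringFraction = 1.2), "clusteringFraction")
  expect_error(cellSpec(spotSigmaNm = 0), "spotSigmaNm")
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0)) + 20
  expect_error(cellSpec(membranePolygon = bowtie), "self-intersecting")
  # area too small for the spot load
  tiny <- cbind(c(20, 24, 24, 20), c(20, 20, 24, 24))
  expect_error(generateCell(cellSpec(imageSize = 64, membranePolygon = tiny,
                                     nSpots = 100L)),
               "too small")
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- cellSpec(imageSize = 192, nSpots = 30L, seed = 99L)
  a <- generateCell(spec)
  b <- generateCell(spec)
  expect_identical(targetChannel(a$images), targetChannel(b$images))
  expect_identical(membraneChannel(a$images), membraneChannel(b$images))
  expect_identical(a$truth, b$truth)
  expect_identical(roiPolygon(a$roi), roiPolygon(b$roi))
})

test_that("phi = 1 confines every ground-truth spot to the proximal band", {
  for (seed in c(2L, 3L, 4L)) {
    sim <- generateCell(cellSpec(imageSize = 256, nSpots = 60L,
                                 clusteringFraction = 1, seed = seed))
    expect_true(all(sim$truth$distance_nm <= 700))
    expect_true(all(sim$truth$label == "proximal"))
  }
})

test_that("phi = 0 spots are uniform: band occupancy matches the area fraction", {
  # oracle: area fraction of the <=700 nm band from the distance transform
  nIn <- 0; nTot <- 0; fracArea <- numeric(0)
  for (seed in 1:20) {
    sim <- generateCell(cellSpec(imageSize = 256, nSpots = 100L,
                                 clusteringFraction = 0, seed = seed))
    mask <- polygonToMask(sim$roi, c(256, 256))
    sh <- inwardShells(mask, pixelSize(sim$roi))
    lab <- shellLabels(sh)
    fracArea <- c(fracArea, sum(lab >= 1 & lab <= 4) / sum(lab >= 1))
    nIn <- nIn + sum(sim$truth$distance_nm <= 700)
    nTot <- nTot + nrow(sim$truth)
  }
  p <- mean(fracArea)
  expect_lt(abs(nIn / nTot - p), 3 * sqrt(p * (1 - p) / nTot))
})

test_that("all spot centres fall inside the polygon and rendering stays within 3 sigma of it", {
  sim <- generateCell(cellSpec(imageSize = 256, nSpots = 80L,
                               clusteringFraction = 0.5, seed = 31L,
                               noiseBackgroundMean = 0, noiseGaussianSd = 0))
  poly <- roiPolygon(sim$roi)
  inside <- phagostate:::.pointsInPolygon(
    as.matrix(sim$truth[, c("x_px", "y_px")]), poly)
  expect_true(all(inside))
  # pixels farther than 3 sigma outside the polygon carry only Poisson
  # residue of the Gaussian tail (well under 2% of the amplitude)
  mask <- polygonToMask(sim$roi, c(256, 256))
  dOut <- EBImage::distmap((!mask) * 1)
  sigmaPx <- 60 / (0.03 * 1000)
  far <- !mask & dOut > 3 * sigmaPx
  expect_lt(max(targetChannel(sim$images)[far]), 0.02 * 8000)
})

test_that("uptake time courses follow the saturating model", {
  spec <- cellSpec(imageSize = 160, seed = 7L)
  # rate zero: no beads in any frame
  tl0 <- generateTimelapse(spec, nFrames = 4, frameIntervalMin = 30,
                           uptakeRate = 0, capacity = 50)
  expect_true(all(sapply(tl0, `[[`, "nBeads") == 0))
  expect_true(all(sapply(tl0, function(f) nrow(f$truth)) == 0))

  # per-realization persistence: counts non-decreasing for every seed
  for (seed in 1:6) {
    tl <- generateTimelapse(cellSpec(imageSize = 160, seed = seed),
                            nFrames = 6, frameIntervalMin = 30,
                            uptakeRate = 2.3, capacity = 120)
    counts <- sapply(tl, `[[`, "nBeads")
    expect_true(all(diff(counts) >= 0))
    expect_true(all(counts <= 120))
    expect_equal(sapply(tl, `[[`, "timeMin"), seq(20, 170, by = 30))
  }

  expect_error(generateTimelapse(spec, 3, 30, uptakeRate = 1, capacity = 0),
               "capacity")
  expect_error(generateTimelapse(spec, 0, 30, uptakeRate = 1, capacity = 10),
               "nFrames")
})

test_that("mean first/last-frame counts match the closed-form expectation", {
  # capacity 120, rate 2.285/min: expectation 38.0 at 20 min, 115.3 at
  # 170 min (oracle: C * (1 - exp(-r t / C)))
  C <- 120; r <- 2.285; tt <- c(20, 170)
  expected <- C * (1 - exp(-r * tt / C))
  first <- numeric(0); last <- numeric(0)
  for (seed in 1:50) {
    tl <- generateTimelapse(cellSpec(imageSize = 128, seed = seed,
                                     nSpots = 1L),
                            nFrames = 6, frameIntervalMin = 30,
                            uptakeRate = r, capacity = C)
    counts <- sapply(tl, `[[`, "nBeads")
    first <- c(first, counts[1]); last <- c(last, counts[6])
  }
  expect_lt(abs(mean(first) - expected[1]) / expected[1], 0.10)
  expect_lt(abs(mean(last) - expected[2]) / expected[2], 0.10)
})
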