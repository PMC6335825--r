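test_that("8-bit quantization maps the window endpoints, midpoint and clips", {
  q <- quantizeTo8bit(matrix(c(0, 8000, 16000, 20000), 2), c(0, 16000))
  expect_identical(as.vector(q), c(0L, 127L, 255L, 255L))
  # general floor mapping
  v <- matrix(seq(0, 16000, by = 500), 3)
  q2 <- quantizeTo8bit(v, c(0, 16000))
  expect_identical(as.vector(q2), as.integer(floor(255 * v / 16000)))
  # window offset
  expect_identical(quantizeTo8bit(matrix(100), c(100, 200))[1, 1], 0L)
  expect_error(quantizeTo8bit(matrix(1), c(5, 5)), "window")
})

test_that("background subtraction removes a constant and keeps spots additive", {
  expect_true(all(subtractBackground(matrix(50, 8, 8)) == 0))
  img <- matrix(50, 8, 8); img[3, 4] <- 250
  out <- subtractBackground(img, "mode")
  expect_equal(out[3, 4], 200)
  expect_equal(sum(out), 200)  # only the spot survives
  # percentile tie on a two-valued histogram breaks toward the lower value
  img2 <- matrix(c(rep(0, 10), rep(100, 10)), 4)
  out2 <- subtractBackground(img2, "percentile", param = 50)
  expect_equal(attr(out2, "background"), 0)
  expect_error(subtractBackground(img2, "percentile", param = 120),
               "percentile")
  # background estimated outside the ROI when a mask is given
  img3 <- matrix(10, 6, 6); img3[3:4, 3:4] <- 500
  roi <- matrix(FALSE, 6, 6); roi[3:4, 3:4] <- TRUE
  expect_equal(attr(subtractBackground(img3, roiMask = roi), "background"),
               10)
})

test_that("co-occurrence counting matches hand-enumerated pairs", {
  img <- rbind(c(0L, 0L), c(255L, 255L))
  m <- computeGLCM(img, offset = c(1L, 0L))
  expect_equal(glcmPairCount(m), 2)
  p <- glcmProbabilities(m)
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[256, 256], 0.5)
  expect_equal(sum(p), 1)

  z <- matrix(0L, 3, 3)
  mz <- computeGLCM(z, offset = c(1L, 0L))
  expect_equal(glcmPairCount(mz), 6)
  expect_equal(glcmProbabilities(mz)[1, 1], 1)

  mask <- matrix(FALSE, 4, 4); mask[, 2] <- TRUE
  expect_error(computeGLCM(matrix(0L, 4, 4), mask, offset = c(1L, 0L)),
               "degenerate")
})

test_that("directed counting is asymmetric and symmetrization averages it", {
  img <- rbind(c(0L, 10L), c(0L, 10L))
  m <- computeGLCM(img, offset = c(1L, 0L))
  p <- glcmProbabilities(m)
  expect_equal(p[1, 11], 1)   # 0 -> 10 only, directed
  expect_equal(p[11, 1], 0)
  ms <- computeGLCM(img, offset = c(1L, 0L), symmetric = TRUE)
  ps <- glcmProbabilities(ms)
  expect_equal(ps[1, 11], 0.5)
  expect_equal(ps[11, 1], 0.5)
})

test_that("texture statistics match closed forms", {
  p <- matrix(0, 256, 256); p[1, 1] <- 0.5; p[256, 256] <- 0.5
  f <- textureFeatures(p)
  expect_equal(unname(f["asm"]), 0.5)
  expect_equal(unname(f["idm"]), 1.0)
  expect_equal(unname(f["entropy"]), log(2))

  d <- matrix(0, 256, 256); d[1, 1] <- 1
  fd <- textureFeatures(d)
  expect_equal(unname(fd[c("asm", "idm", "entropy")]), c(1, 1, 0))

  o <- matrix(0, 256, 256); o[1, 256] <- 1
  expect_equal(unname(textureFeatures(o)["idm"]), 1 / (1 + 255^2))

  bad <- matrix(0, 256, 256); bad[1, 1] <- 0.9
  expect_error(textureFeatures(bad), "sum to 1")
})

test_that("GLCM matches the brute-force pair oracle on random images", {
  set.seed(101)
  for (rep in 1:25) {
    img <- matrix(sample(c(0L, 85L, 170L, 255L), 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) < 0.8, 8, 8)
    off <- sample(list(c(1L, 0L), c(0L, 1L), c(1L, 1L)), 1)[[1]]
    ref <- oracleGLCM(img, mask, off)
    if (ref$n < 1) next
    m <- computeGLCM(img, mask, off)
    expect_equal(glcmProbabilities(m), ref$p)
    expect_equal(glcmPairCount(m), ref$n)
    expect_equal(unname(textureFeatures(m)[c("asm", "idm", "entropy")]),
                 unname(oracleTexture(ref$p)))
  }
})

test_that("normalization, bounds and the uniform-image limit hold", {
  set.seed(7)
  for (rep in 1:10) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    m <- computeGLCM(img, offset = c(1L, 0L))
    expect_equal(sum(glcmProbabilities(m)), 1, tolerance = 1e-12)
    f <- textureFeatures(m)
    expect_gt(f[["asm"]], 0); expect_lte(f[["asm"]], 1)
    expect_gt(f[["idm"]], 0); expect_lte(f[["idm"]], 1)
    expect_gte(f[["entropy"]], 0)
    expect_lte(f[["entropy"]], log(sum(glcmProbabilities(m) > 0)) + 1e-12)
  }
  u <- matrix(42L, 9, 9)
  fu <- textureFeatures(computeGLCM(u))
  expect_equal(unname(fu[c("asm", "idm", "entropy")]), c(1, 1, 0))
})

test_that("clustered two-level images are more homogeneous than spread multi-level ones", {
  # 64x64 test pair: one dark cluster on white vs. additional mid-gray
  # clusters; homogeneity statistics must order clustered > spread
  img1 <- matrix(255L, 64, 64); img1[20:40, 20:40] <- 0L
  img2 <- img1
  img2[5:15, 5:15] <- 212L
  img2[50:60, 10:20] <- 130L
  img2[45:60, 45:60] <- 130L
  f1 <- textureFeatures(computeGLCM(img1))
  f2 <- textureFeatures(computeGLCM(img2))
  expect_gt(f1[["asm"]], f2[["asm"]])
  expect_gt(f1[["idm"]], f2[["idm"]])
  expect_lt(f1[["entropy"]], f2[["entropy"]])
})
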