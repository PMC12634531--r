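# Depth preprocessing: floor plane, normalization, enhancement, segmentation.

planeDepth <- function(H, W, a, b, c) {
  xg <- matrix(rep(0:(W - 1), each = H), H)
  yg <- matrix(rep(0:(H - 1), times = W), H)
  a * xg + b * yg + c
}

test_that("RANSAC recovers planes exactly without noise", {
  z <- planeDepth(100, 120, 0, 0.5, 1000)
  fm <- fitFloorRansac(z, cfg = depthPreprocConfig(seed = 0))
  expect_equal(c(fm@a, fm@b, fm@c), c(0, 0.5, 1000), tolerance = 1e-6)

  # a point generated on the plane has zero residual
  expect_equal(abs(z[13, 7] - (fm@a * 6 + fm@b * 12 + fm@c)), 0, tolerance = 1e-9)

  expect_error(fitFloorRansac(matrix(0, 10, 10)), "3 valid")
})

test_that("RANSAC is seed-deterministic and robust to body outliers", {
  set.seed(0)
  z <- planeDepth(100, 120, 0.2, 0.5, 1500) + matrix(rnorm(12000, 0, 5), 100)
  out <- sample(12000, 3600)
  z[out] <- z[out] - 800
  cfg <- depthPreprocConfig(seed = 0)
  f1 <- fitFloorRansac(z, matrix(255, 100, 120), cfg)
  f2 <- fitFloorRansac(z, matrix(255, 100, 120), cfg)
  expect_identical(c(f1@a, f1@b, f1@c), c(f2@a, f2@b, f2@c))
  expect_lt(abs(f1@a - 0.2), 0.05)
  expect_lt(abs(f1@b - 0.5), 0.05)
  expect_lt(abs(f1@c - 1500), 5)

  # inlier count is non-decreasing in epsilon
  counts <- vapply(c(5, 10, 20, 40), function(eps)
    fitFloorRansac(z, matrix(255, 100, 120),
                   depthPreprocConfig(epsilon = eps, seed = 0))@inlierCount,
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("floor removal zeroes residuals strictly below epsilon", {
  fm <- new("FloorModel", a = 0, b = 0, c = 1000, epsilon = 15,
            inlierCount = 1L)
  d <- matrix(c(1000, 1014.9, 1015, 1016), 2, 2)
  out <- removeFloor(d, fm)
  expect_equal(as.numeric(out), c(0, 0, 1015, 1016))  # exactly-eps kept

  # synthetic frame: all pure-floor pixels removed, body untouched
  fr <- renderFrame(samplePose("idle", 0, seed = 4), testScene(noise = 0))
  dp <- depthMap(fr); m <- silhouette(fr)
  fit <- fitFloorRansac(dp, cfg = depthPreprocConfig(seed = 2))
  dr <- removeFloor(dp, fit)
  expect_true(all(dr[m == 0] == 0))
  expect_identical(dr[m > 0], dp[m > 0])
})

test_that("min-max normalization maps valid depth to 0..255", {
  d <- matrix(c(1000, 2000, 1500, 0), 2, 2)
  out <- normalizeMinMax(d)
  expect_equal(as.numeric(out), c(0, 255, 128, 0))  # 127.5 rounds half-up

  expect_warning(out2 <- normalizeMinMax(matrix(c(5, 5, 0, 5), 2, 2)), "constant")
  expect_true(all(out2 == 0))
  expect_error(normalizeMinMax(matrix(0, 3, 3)), "valid")

  # monotone on valid pixels
  set.seed(1)
  d2 <- matrix(runif(400, 500, 3000), 20, 20)
  n2 <- normalizeMinMax(d2)
  o <- order(d2)
  expect_true(all(diff(n2[o]) >= 0))
})

test_that("enhancement preserves constants and smooths noise edge-aware", {
  cfg <- depthPreprocConfig()
  ci <- matrix(100L, 24, 24)
  e <- enhanceDepth(ci, cfg)
  expect_equal(stats::sd(e), 0, tolerance = 1e-10)
  expect_identical(e[, , 1], e[, , 2])
  expect_identical(e[, , 2], e[, , 3])

  # noisy step edge: bilateral output reduces within-region variance while
  # keeping the step sharper than a plain Gaussian blur of equal support
  set.seed(7)
  step <- matrix(60, 40, 40); step[, 21:40] <- 200
  noisy <- step + matrix(rnorm(1600, 0, 8), 40)
  bf <- rgbdpose:::.bilateral(noisy, 9, 3, 25)
  gb <- rgbdpose:::.gblur(noisy, 2)
  expect_lt(stats::var(as.numeric(bf[, 5:16])), stats::var(as.numeric(noisy[, 5:16])))
  # edge contrast across the step survives better than under the blur oracle
  expect_gt(mean(bf[, 23:26]) - mean(bf[, 15:18]),
            mean(gb[, 23:26]) - mean(gb[, 15:18]))
})

test_that("depth segmentation reproduces the generator silhouette", {
  fr <- renderFrame(samplePose("idle", 0, seed = 5), testScene(noise = 0))
  dp <- depthMap(fr); m <- silhouette(fr)
  fit <- fitFloorRansac(dp, cfg = depthPreprocConfig(seed = 1))
  dr <- removeFloor(dp, fit)
  en <- enhanceDepth(normalizeMinMax(dr), depthPreprocConfig(bilateral_diameter = 5))
  mask <- segmentDepth(en, thresholdBackend((dr > 0) * 255))
  expect_lte(maskBoundaryDistance(mask, m), 2.9)
  expect_equal(max(floodFillComponents(mask)), 1)

  expect_error(segmentDepth(en, thresholdBackend(matrix(0, nrow(m), ncol(m)))),
               "no person")
})
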