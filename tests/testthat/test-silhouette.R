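# RGB-stream silhouette extraction chain.

test_that("preprocessing normalizes per channel on the [0,1] scale", {
  img <- array(runif(10 * 8 * 3, 0, 255), c(10, 8, 3))
  # identity statistics at source size: output equals input / 255
  ni <- preprocessRgb(img, mean = 0, std = 1)
  expect_equal(ni$values, img / 255)

  # a pixel whose scaled value equals mu maps to 0 in every channel
  img2 <- img; img2[3, 4, ] <- 0.5 * 255
  ni2 <- preprocessRgb(img2, mean = 0.5, std = 0.25)
  expect_equal(as.numeric(ni2$values[3, 4, ]), c(0, 0, 0))

  # constant image: closed form at any target size
  img3 <- array(120, c(9, 7, 3))
  ni3 <- preprocessRgb(img3, mean = 0.3, std = 0.2, targetSize = c(16L, 12L))
  expect_equal(dim(ni3$values), c(16L, 12L, 3L))
  expect_equal(max(abs(ni3$values - (120 / 255 - 0.3) / 0.2)), 0, tolerance = 1e-8)

  expect_error(preprocessRgb(img, std = 0), "std")

  # BGR input is converted to RGB
  nb <- preprocessRgb(img[, , 3:1], colorOrder = "BGR")
  expect_equal(nb$values, img / 255)
})

test_that("argmax segmentation follows the scores and the tie rule", {
  disc <- matrix(0, 20, 20)
  xg <- matrix(rep(1:20, each = 20), 20); yg <- matrix(rep(1:20, 20), 20)
  disc[(xg - 10)^2 + (yg - 10)^2 <= 25] <- 255
  be <- thresholdBackend(disc)
  ni <- preprocessRgb(array(rep(disc, 3), c(20, 20, 3)))
  lab <- segmentPerson(ni, be)
  expect_equal((lab == be$personClass) * 255, disc, ignore_attr = TRUE)

  # equal scores everywhere resolve to class 0
  flat <- scoreBackend(function(img) array(0.5, c(dim(img$values)[1:2], 2)), 1L)
  expect_true(all(segmentPerson(ni, flat) == 0L))

  bad <- scoreBackend(function(img) array(NaN, c(dim(img$values)[1:2], 2)), 1L)
  expect_error(segmentPerson(ni, bad), "finite")
})

test_that("largest-component selection matches a flood-fill oracle", {
  lab <- matrix(0L, 30, 30)
  lab[5:12, 5:12] <- 1L      # 64 px blob
  lab[20:22, 20:22] <- 1L    # 9 px blob
  m <- largestComponentMask(lab, 1L)
  oracle <- floodFillComponents((lab == 1L) * 255)
  sizes <- tabulate(oracle[oracle > 0])
  expect_equal((m > 0), (oracle == which.max(sizes)))
  expect_equal(sum(m > 0), 64)

  # single blob is unchanged
  single <- matrix(0L, 10, 10); single[2:5, 3:7] <- 1L
  expect_equal(largestComponentMask(single, 1L), (single == 1L) * 255)

  # 8-connectivity: a diagonal chain is one component
  diagm <- matrix(0L, 8, 8); for (i in 1:6) diagm[i, i] <- 1L
  diagm[8, 1] <- 1L
  expect_equal(sum(largestComponentMask(diagm, 1L) > 0), 6)

  expect_error(largestComponentMask(matrix(0L, 5, 5), 1L), "no person")
})

test_that("morphological refinement opens then closes with a 5x5 element", {
  a <- matrix(0, 20, 20); a[10, 10] <- 255
  expect_true(all(refineMask(a) == 0))

  b <- matrix(0, 30, 30); b[5:24, 5:24] <- 255; b[12, 12] <- 0
  rb <- refineMask(b)
  expect_equal(rb[12, 12], 255)

  # idempotence on random blobs
  for (s in 1:4) {
    m <- randomBlob(s)
    r1 <- refineMask(m)
    expect_identical(refineMask(r1), r1)
    # never grows farther than 2 px from original foreground
    if (any(r1 > 0)) {
      grown <- which(r1 > 0 & m == 0, arr.ind = TRUE)
      if (nrow(grown) > 0) {
        orig <- which(m > 0, arr.ind = TRUE)
        dmin <- vapply(seq_len(nrow(grown)), function(i)
          sqrt(min((grown[i, 1] - orig[, 1])^2 + (grown[i, 2] - orig[, 2])^2)),
          numeric(1))
        expect_lte(max(dmin), 2 * sqrt(2))
      }
    }
  }
})

test_that("mask alignment uses floor-indexed nearest neighbour", {
  frame <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  m255 <- matrix(255, 2, 2)
  expect_equal(alignAndApply(m255, frame), frame)
  m0 <- matrix(0, 2, 2)
  expect_true(all(alignAndApply(m0, frame) == 0))

  mask <- matrix(c(255, 0, 0, 255), 2, 2)
  out <- alignAndApply(mask, frame)
  # index-by-index oracle: source pixel = (floor(y*H'/H), floor(x*W'/W))
  for (y in 0:3) for (x in 0:3) {
    src <- mask[floor(y * 2 / 4) + 1, floor(x * 2 / 4) + 1]
    if (src == 255) expect_equal(out[y + 1, x + 1, ], frame[y + 1, x + 1, ])
    else expect_equal(as.numeric(out[y + 1, x + 1, ]), c(0, 0, 0))
  }
})

test_that("the full chain reproduces the generator silhouette", {
  # default sensor-scale scene: limbs are wider than the 5x5 kernel, so
  # morphology only nibbles boundary pixels
  fr <- renderFrame(samplePose("arm_raise", 0.3, seed = 2), sceneConfig())
  sil <- silhouette(fr)
  ni <- preprocessRgb(array(rep(sil, 3), c(dim(sil), 3)))
  lab <- segmentPerson(ni, thresholdBackend(sil))
  mask <- refineMask(largestComponentMask(lab, 1L))
  # nonzero only where the mask is set (exact application rule)
  applied <- alignAndApply(mask, array(rep(sil, 3), c(dim(sil), 3)))
  expect_true(all(applied[, , 1][mask == 0] == 0))
  # morphology may move the boundary by at most ~2 px
  expect_lte(maskBoundaryDistance(mask, sil), 2)
})
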