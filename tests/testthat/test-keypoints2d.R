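# Classical keypoint detector bank on binary silhouettes.

test_that("perpendicular distance follows the closed form", {
  expect_equal(perpendicularDistance(c(0, 1), c(-1, 0), c(1, 0)), 1.0)
  expect_equal(perpendicularDistance(c(0.5, 0.5), c(0, 0), c(2, 2)), 0)
  p0 <- c(3, -2); p1 <- c(-1, 4); p2 <- c(5, 1)
  expect_equal(perpendicularDistance(p0, p1, p2),
               perpendicularDistance(p0, p2, p1))
  expect_error(perpendicularDistance(c(0, 0), c(1, 1), c(1, 1)), "distinct")
})

test_that("contour simplification is tolerance-faithful and monotone", {
  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 255
  v <- approxContour(sq, 2)
  expect_equal(nrow(v), 4)
  # all boundary pixels lie within epsilon+1 of the simplified 4-gon
  bd <- which(sq > 0 & (rgbdpose:::.shiftMat(sq, 1, 0) == 0 |
                        rgbdpose:::.shiftMat(sq, -1, 0) == 0 |
                        rgbdpose:::.shiftMat(sq, 0, 1) == 0 |
                        rgbdpose:::.shiftMat(sq, 0, -1) == 0), arr.ind = TRUE)
  pts <- cbind(bd[, 2] - 1, bd[, 1] - 1)
  expect_lte(max(maxDistanceToPolygon(pts, v)), 2)

  for (s in 1:4) {
    m <- randomBlob(s)
    full <- approxContour(m, 0)
    expect_identical(full, rgbdpose:::.traceBoundary(m))
    # epsilon-tolerance property against brute force on every contour pixel
    v2 <- approxContour(m, 2)
    expect_lte(max(maxDistanceToPolygon(full, v2)), 2)
    # vertex count non-increasing in epsilon
    counts <- vapply(c(0, 1, 2, 4, 8), function(e) nrow(approxContour(m, e)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("Harris response behaves like the eigenvalue analysis predicts", {
  expect_error(harrisResponse(matrix(1, 5, 5), k = 0), "k must be")
  # constant image: zero gradients, zero response
  expect_true(all(harrisResponse(matrix(7, 12, 12)) == 0))

  sq <- matrix(0, 40, 40); sq[11:30, 11:30] <- 1
  img <- rgbdpose:::.gblur(sq, 1)
  R <- harrisResponse(img, 0.04, 2)
  # corner pixel: both eigenvalues positive -> positive response
  expect_gt(R[11, 11], 0)
  # midpoint of a long straight edge: rank-one M -> det = 0, R <= 0
  expect_lte(R[20, 11], 0)
  # direct eigenvalue oracle at those pixels
  st <- rgbdpose:::.structureTensor(img, 2)
  for (px in list(c(11, 11), c(20, 11))) {
    M <- matrix(c(st$xx[px[1], px[2]], st$xy[px[1], px[2]],
                  st$xy[px[1], px[2]], st$yy[px[1], px[2]]), 2, 2)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(R[px[1], px[2]], prod(ev) - 0.04 * sum(ev)^2, tolerance = 1e-9)
  }
  # intensity negation leaves the response unchanged
  expect_equal(harrisResponse(1 - img, 0.04, 2), R, tolerance = 1e-12)
})

test_that("the detector bank is deterministic and finds square corners", {
  cfg <- detectorConfig()
  expect_error(detectKeypoints(matrix(0, 5, 5), "surf", cfg), "valid")

  empty <- matrix(0, 10, 10)
  for (id in c("harris", "orb", "sift", "skeleton"))
    expect_equal(nrow(detectKeypoints(empty, id, cfg)$points), 0)

  sq <- matrix(0, 50, 50); sq[6:45, 6:45] <- 255
  st <- detectKeypoints(sq, "shi_tomasi", cfg)
  corners <- rbind(c(5, 5), c(44, 5), c(5, 44), c(44, 44))
  for (k in 1:4) {
    d <- sqrt((st$points$x - corners[k, 1])^2 + (st$points$y - corners[k, 2])^2)
    expect_lte(min(d), 2)
  }

  fr <- renderFrame(samplePose("squat", 0.4, seed = 9), testScene())
  m <- silhouette(fr)
  for (id in rgbdpose:::.detectorIds()) {
    k1 <- detectKeypoints(m, id, cfg)
    k2 <- detectKeypoints(m, id, cfg)
    expect_identical(k1, k2, label = id)
    expect_lte(nrow(k1$points), cfg$max_points)
    if (nrow(k1$points) > 1) {
      o <- order(k1$points$y, k1$points$x)
      expect_identical(o, seq_along(o))
    }
  }
})

test_that("detectors are translation-covariant on border-free fixtures", {
  base <- matrix(0, 64, 64)
  base[21:40, 25:36] <- 255; base[15:20, 28:33] <- 255
  shifted <- rgbdpose:::.shiftMat(base, 6, 4)
  cfg <- detectorConfig()
  for (id in c("contour", "harris", "shi_tomasi", "orb", "skeleton")) {
    a <- detectKeypoints(base, id, cfg)$points
    b <- detectKeypoints(shifted, id, cfg)$points
    expect_equal(b$x, a$x + 4, label = id)
    expect_equal(b$y, a$y + 6, label = id)
  }
})

test_that("skeleton landmarks classify endpoints and branches", {
  bar <- matrix(0, 10, 40); bar[5, 6:35] <- 255
  sl <- skeletonLandmarks(bar)
  expect_equal(sum(sl$points$type == "endpoint"), 2)
  expect_equal(sum(sl$points$type == "branch"), 0)

  tee <- matrix(0, 40, 40); tee[10, 6:35] <- 255; tee[10:30, 20] <- 255
  sl2 <- skeletonLandmarks(tee)
  expect_equal(sum(sl2$points$type == "endpoint"), 3)
  expect_equal(sum(sl2$points$type == "branch"), 1)

  px <- matrix(0, 9, 9); px[5, 5] <- 255
  sl3 <- skeletonLandmarks(px)
  expect_equal(nrow(sl3$points), 1)
  expect_equal(sl3$points$type, "endpoint")

  expect_error(skeletonLandmarks(matrix(0, 5, 5)), "empty")
})

test_that("fixed-length encoding normalizes, pads and stays pure", {
  mk <- function(id, x, y) structure(list(detectorId = id,
                                          points = data.frame(x = x, y = y,
                                                              response = seq_along(x))),
                                     class = "KeypointSet")
  bbox <- list(top = 0, left = 0, h = 40, w = 40)
  # hand-normalized example: points (y, x) = (10, 10) and (20, 30)
  enc <- encodeKeypoints(list(mk("harris", c(10, 30), c(10, 20))), bbox, 2)
  expect_equal(enc, c(0.25, 0.25, 0.75, 0.5))

  emptySet <- mk("sift", numeric(0), numeric(0))
  enc2 <- encodeKeypoints(list(emptySet), bbox, 3)
  expect_equal(enc2, rep(-1, 6))

  sets <- list(mk("harris", 5, 5), mk("contour", c(1, 2), c(3, 4)))
  enc3 <- encodeKeypoints(sets, bbox, 4)
  expect_length(enc3, 2 * 4 * 2)
  expect_true(all(enc3[enc3 != -1] >= 0 & enc3[enc3 != -1] <= 1))
  # byte-identical on identical input
  expect_identical(enc3, encodeKeypoints(sets, bbox, 4))

  expect_error(encodeKeypoints(sets, list(top = 0, left = 0, h = 0, w = 10), 4),
               "positive area")
})
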