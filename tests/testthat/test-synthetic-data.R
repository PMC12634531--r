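# Synthetic RGB-D generator: pose sampling, rendering, dataset assembly.

test_that("pose sampling is deterministic, bounded and class-aware", {
  expect_error(samplePose("jumping_jack", 0.5), "valid classes")
  expect_error(samplePose("idle", 1.5), "\\[0, 1\\]")

  p1 <- samplePose("squat", 0.3, seed = 7)
  p2 <- samplePose("squat", 0.3, seed = 7)
  expect_identical(p1@jointAngles, p2@jointAngles)
  expect_identical(p1@rootPosition, p2@rootPosition)

  idle <- samplePose("idle", 0.4, seed = 3)
  expect_lt(max(abs(idle@jointAngles)), 0.05)

  # distinct classes produce distinct joint trajectories (mid-rep phase)
  for (cl in setdiff(exerciseClasses(), "idle")) {
    pc <- samplePose(cl, 0.25)
    expect_gt(max(abs(pc@jointAngles - samplePose("idle", 0.25)@jointAngles)),
              0.1, label = cl)
  }
})

test_that("an arm raise lifts the wrists above the head in image rows", {
  fr <- renderFrame(samplePose("arm_raise", 0.5), testScene())
  j <- gtJoints2d(fr)
  expect_lt(j["wrist_l", "y"], j["head", "y"])
  expect_lt(j["wrist_r", "y"], j["head", "y"])
})

test_that("rendered frames satisfy the scene geometry", {
  sc <- testScene(noise = 0)
  fr <- renderFrame(samplePose("idle", 0), sc)
  m <- silhouette(fr)
  d <- depthMap(fr)
  H <- nrow(m); W <- ncol(m)
  xg <- matrix(rep(0:(W - 1), each = H), H)
  yg <- matrix(rep(0:(H - 1), times = W), H)
  plane <- sc@floorPlane[1] * xg + sc@floorPlane[2] * yg + sc@floorPlane[3]

  # non-body pixels carry the exact floor plane
  expect_equal(max(abs(d[m == 0] - plane[m == 0])), 0)
  # body depth is positive and strictly nearer than the floor
  expect_true(all(d[m > 0] > 0))
  expect_true(all(d[m > 0] < plane[m > 0]))

  # one connected component (flood-fill oracle)
  expect_equal(max(floodFillComponents(m)), 1)

  # joints fall on (or next to) the silhouette
  j <- gtJoints2d(fr)
  on <- sum(m[cbind(round(j[, 2]) + 1, round(j[, 1]) + 1)] > 0)
  expect_gte(on, 22)
  bb <- maskBbox(m)
  expect_true(all(j[, 1] >= bb$left & j[, 1] <= bb$left + bb$w))
  expect_true(all(j[, 2] >= bb$top & j[, 2] <= bb$top + bb$h))

  # a refit plane on floor pixels recovers (a, b, c) exactly
  sel <- which(m == 0)
  co <- qr.solve(cbind(xg[sel], yg[sel], 1), d[sel])
  expect_equal(as.numeric(co), sc@floorPlane, tolerance = 1e-9)
})

test_that("mirror-symmetric poses produce mirror-symmetric ground truth", {
  fr <- renderFrame(samplePose("idle", 0), testScene())
  j <- gtJoints2d(fr)
  cx <- (ncol(silhouette(fr)) - 1) / 2
  pairs <- rbind(c("wrist_l", "wrist_r"), c("ankle_l", "ankle_r"),
                 c("shoulder_l", "shoulder_r"), c("knee_l", "knee_r"))
  for (k in seq_len(nrow(pairs))) {
    expect_equal(j[pairs[k, 1], "x"] - cx, cx - j[pairs[k, 2], "x"],
                 tolerance = 1e-9)
    expect_equal(j[pairs[k, 1], "y"], j[pairs[k, 2], "y"], tolerance = 1e-9)
  }
})

test_that("out-of-frame poses are rejected with actionable advice", {
  sc <- sceneConfig(imageSize = c(60L, 40L), cameraScale = 23)
  expect_error(renderFrame(samplePose("idle", 0), sc), "cameraScale")
})

test_that("dataset generation is balanced, reproducible and well counted", {
  expect_error(generateDataset(10, 0, scene = testScene()), "T must be")
  expect_error(generateDataset(3, 2, scene = testScene()), "nSequences")

  d1 <- generateDataset(10, 3, scene = testScene(noise = 5), seed = 5)
  expect_equal(unname(table(d1$manifest$class_id)), rep(2L, 5),
               ignore_attr = TRUE)
  expect_equal(nrow(d1$manifest), 10)
  expect_equal(sum(vapply(d1$sequences, function(s) length(frames(s)),
                          integer(1))), 30)

  d2 <- generateDataset(10, 3, scene = testScene(noise = 5), seed = 5)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(depthMap(frames(d1$sequences[[4]])[[2]]),
                   depthMap(frames(d2$sequences[[4]])[[2]]))

  # different seed changes the rendered data
  d3 <- generateDataset(10, 3, scene = testScene(noise = 5), seed = 6)
  expect_false(identical(depthMap(frames(d1$sequences[[1]])[[1]]),
                         depthMap(frames(d3$sequences[[1]])[[1]])))
})

test_that("sequences round-trip to disk as plain image formats", {
  td <- withr::local_tempdir()
  d <- generateDataset(5, 2, scene = testScene(noise = 0), seed = 2, dir = td)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  fr <- frames(d$sequences[[1]])[[1]]
  m <- png::readPNG(file.path(td, "seq0001", "masks", "0001.png")) * 255
  expect_equal(m, unname(silhouette(fr)))
  dp <- tiff::readTIFF(file.path(td, "seq0001", "depth", "0001.tif")) * 65535
  expect_lt(max(abs(dp - depthMap(fr))), 0.51)  # 16-bit mm quantization
})
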