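# Rule-based 24-point extraction: mode selection, the two scan pipelines,
# and depth lifting.

test_that("mode selection separates lowered from raised arms", {
  sc <- testScene()
  expect_equal(selectMode(silhouette(renderFrame(samplePose("idle", 0.2, seed = 1), sc))),
               "LOWERED")
  expect_equal(selectMode(silhouette(renderFrame(samplePose("squat", 0.5, seed = 1), sc))),
               "LOWERED")
  expect_equal(selectMode(silhouette(renderFrame(samplePose("arm_raise", 0.5, seed = 1), sc))),
               "RAISED")
  expect_equal(selectMode(silhouette(renderFrame(samplePose("lateral_bar_shift", 0.7, seed = 1), sc))),
               "RAISED")

  # a torso-only rectangle has no super-neck width excess
  rect <- matrix(0, 60, 40); rect[11:50, 16:25] <- 255
  expect_equal(selectMode(rect), "LOWERED")
  expect_error(selectMode(matrix(0, 5, 5)), "empty")
})

test_that("the lowered-arm pipeline follows the scan rules literally", {
  # silhouette: rectangle body occupying rows 8..88 (top 8, h 80), W = 128
  m <- matrix(0, 100, 128)
  m[9:89, 40:90] <- 255
  kp <- extractLowered(m)
  expect_identical(rownames(kp), jointNames24())
  expect_equal(unname(kp["head", ]), c(128 %/% 2, 8))       # (width/2, top)
  expect_equal(unname(kp["neck", "y"]), 8 + 80 %/% 8)       # head_y + h/8
  # shoulders: neck-row extremes inset by 5
  expect_equal(unname(kp["shoulder_l", "x"]), 39 + 5)
  expect_equal(unname(kp["shoulder_r", "x"]), 89 - 5)
  # collarbones 15 px inward of the shoulders
  expect_equal(unname(kp["collar_l", "x"]), 39 + 5 + 15)
  expect_equal(unname(kp["collar_r", "x"]), 89 - 5 - 15)
  # hip band rows top + [3h/5, 2h/3]; pelvis averages hips and the band
  expect_equal(unname(kp["pelvis", "y"]), (8 + 48 + 8 + 53) %/% 2)
  expect_equal(unname(kp["pelvis", "x"]), (39 + 89) %/% 2)
  # ankles at the bottom row; heels h/40 above
  expect_equal(unname(kp["ankle_l", "y"]), 88)
  expect_equal(unname(kp["foot_l", "y"]), 88 - 80 %/% 40)
  # synthesized knees at row top + 3h/4 inset by 7
  expect_equal(unname(kp["knee_l", ]), c(39 + 7, 8 + 60))
  expect_equal(unname(kp["knee_r", ]), c(89 - 7, 8 + 60))

  expect_error(extractLowered(matrix(0, 5, 5)), "empty")
})

test_that("the raised-arm pipeline follows the scan rules literally", {
  # body column rows 12..92 around x = 60..70, arms as thin columns to the
  # sides reaching above the head
  m <- matrix(0, 110, 130)
  m[13:93, 56:76] <- 255        # torso+head column (top 12, bottom 92)
  m[6:40, 26:30] <- 255         # left arm column, top 5
  m[6:40, 101:105] <- 255       # right arm column
  kp <- extractRaised(m)
  bb <- maskBbox(m)
  h <- bb$h                     # 92 - 5
  expect_identical(rownames(kp), jointNames24())
  # head: first nonzero row of the central body column (x = pelvis_x)
  expect_equal(unname(kp["head", "y"]), 12)
  expect_equal(unname(kp["neck", "y"]), 12 + h %/% 12)
  # hands at the extreme nonzero columns, wrists 10 px below
  expect_equal(unname(kp["hand_l", "x"]), 25)
  expect_equal(unname(kp["hand_r", "x"]), 104)
  expect_equal(unname(kp["wrist_l", "y"]), unname(kp["hand_l", "y"]) + 10)
  # knees at row top + 3h/4 inset by 7
  expect_equal(unname(kp["knee_l", "y"]), bb$top + (3 * h) %/% 4)
  # heels h/30 above the bottom row
  expect_equal(unname(kp["foot_r", "y"]), (bb$top + h) - h %/% 30)
})

test_that("keypoints mirror within 1 px on mirror-symmetric silhouettes", {
  fr <- renderFrame(samplePose("idle", 0), testScene())
  m <- silhouette(fr)
  mirrored <- m[, ncol(m):1]
  for (fun in list(extractLowered)) {
    a <- fun(m); b <- fun(mirrored)
    swap <- jointNames24()
    swap <- ifelse(grepl("_l$", swap), sub("_l$", "_r", swap),
                   ifelse(grepl("_r$", swap), sub("_r$", "_l", swap), swap))
    bSwapped <- b[swap, , drop = FALSE]
    expect_lte(max(abs((ncol(m) - 1 - bSwapped[, "x"]) - a[, "x"])), 1)
    expect_lte(max(abs(bSwapped[, "y"] - a[, "y"])), 1)
  }
})

test_that("depth lifting uses the window median with nearest fallback", {
  kp2d <- extractLowered(silhouette(renderFrame(samplePose("idle", 0, seed = 2),
                                                testScene())))
  # uniform body depth
  d <- matrix(1500, 120, 112)
  k3 <- liftTo3d(kp2d, d)
  expect_true(all(keypointMatrix(k3)[, "z"] == 1500))
  expect_identical(rownames(keypointMatrix(k3)), jointNames24())

  # invalid speckle under a keypoint falls back to the surrounding ring
  d2 <- d
  d2[round(kp2d[1, 2]) + 1, round(kp2d[1, 1]) + 1] <- 0
  expect_equal(keypointMatrix(liftTo3d(kp2d, d2))[1, "z"], 1500)

  # all-invalid depth errors
  expect_error(liftTo3d(kp2d, matrix(0, 120, 112)), "valid")

  # z agrees with generator ground truth within the noise level
  sc <- testScene(noise = 3)
  fr <- renderFrame(samplePose("idle", 0, seed = 6), sc, seed = 6)
  m <- silhouette(fr); dp <- depthMap(fr)
  body <- dp; body[m == 0] <- 0
  kk <- extractKeypoints24(m, body)
  gt <- gtJoints3d(fr)
  on <- m[cbind(round(keypointMatrix(kk)[, 2]) + 1,
                round(keypointMatrix(kk)[, 1]) + 1)] > 0
  dz <- abs(keypointMatrix(kk)[on, "z"] - gt[on, 3])
  # window medians sit on the same limb surface as the ground truth for
  # most joints; allow the capsule-offset spread across adjacent parts
  expect_lt(stats::median(dz), 3 * 3 + 1)
})

test_that("both pipelines stay within the expanded silhouette bbox", {
  sc <- testScene()
  for (cls in c("idle", "arm_raise")) {
    fr <- renderFrame(samplePose(cls, 0.5, seed = 11), sc, seed = 11)
    m <- silhouette(fr)
    kp <- if (selectMode(m) == "RAISED") extractRaised(m) else extractLowered(m)
    bb <- maskBbox(m)
    expect_true(all(kp[, "x"] >= bb$left - 5 & kp[, "x"] <= bb$left + bb$w + 5))
    expect_true(all(kp[, "y"] >= bb$top - 5 & kp[, "y"] <= bb$top + bb$h + 5))
    expect_equal(nrow(kp), 24)
  }
})
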