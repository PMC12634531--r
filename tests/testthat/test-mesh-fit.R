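# Parametric body model, loss terms, gradients and sequence fitting.

mod <- toyBodyModel()

test_that("the body model satisfies its structural contracts", {
  expect_equal(dim(mod@skinWeights), c(nrow(mod@templateVertices), 24L))
  expect_lt(max(abs(rowSums(mod@skinWeights) - 1)), 1e-9)
  expect_equal(dim(mod@shapeBasis), c(3L * nrow(mod@templateVertices), 10L))
  expect_equal(max(abs(sqrt(colSums(mod@shapeBasis^2)) - 1)), 0, tolerance = 1e-6)
  expect_equal(mod@kinematicTree[1], 0L)
  expect_true(all(mod@kinematicTree[-1] < seq_len(23L) + 1L))
})

test_that("the LBS forward pass is exact at rest and under rigid motion", {
  fw <- lbsForward(mod, numeric(72))
  expect_equal(fw$vertices, mod@templateVertices)
  expect_equal(fw$joints, mod@restJoints, ignore_attr = TRUE)

  # pure global rotation moves every joint rigidly about the root
  th <- numeric(72); th[1:3] <- c(0.4, -0.2, 0.7)
  R <- rgbdpose:::.rodrigues(th[1:3])
  fw2 <- lbsForward(mod, th, withVertices = FALSE)
  pred <- t(R %*% (t(mod@restJoints) - mod@restJoints[1, ]) + mod@restJoints[1, ])
  expect_equal(fw2$joints, pred, tolerance = 1e-10, ignore_attr = TRUE)

  # leg-length mode moves the knee-ankle distance linearly
  d <- vapply(0:2, function(b) {
    j <- lbsForward(mod, numeric(72), beta = c(0, 0, b, rep(0, 7)),
                    withVertices = FALSE)$joints
    sqrt(sum((j[5, ] - j[8, ])^2))
  }, numeric(1))
  expect_lt(abs((d[3] - d[2]) - (d[2] - d[1])), 1e-8)
})

test_that("loss terms match their closed forms", {
  J <- matrix(rnorm(72), 24, 3)
  expect_equal(jointLoss(J, J), 0)
  J2 <- J; J2[5, 1] <- J2[5, 1] + 1
  expect_equal(jointLoss(J2, J), 1.0)
  w <- runif(24, 0.5, 2)
  expect_equal(jointLoss(J2, J, 2 * w), 2 * jointLoss(J2, J, w))
  expect_error(jointLoss(J[1:3, ], J), "dimensions")

  expect_equal(shapeReg(numeric(10)), 0)
  expect_equal(shapeReg(c(1, rep(0, 9))), 1)

  Jseq <- array(rep(J, 3), c(3, 24, 3))
  for (t in 1:3) Jseq[t, , ] <- J
  expect_equal(smoothReg(Jseq), 0)
  expect_equal(smoothReg(array(J, c(1, 24, 3))), 0)
  Jseq[2, , ] <- J + 1
  expect_equal(smoothReg(Jseq), 2 * sum((J + 1 - J)^2))

  # Laplacian term: translation invariance and a 5-vertex path hand check
  adj <- meshAdjacency(mod@faces, nrow(mod@templateVertices))
  v <- mod@templateVertices
  expect_equal(meshReg(v + 50, adj), meshReg(v, adj), tolerance = 1e-8)

  pathFaces <- rbind(c(1, 2, 2), c(2, 3, 3), c(3, 4, 4), c(4, 5, 5))
  pathAdj <- meshAdjacency(pathFaces, 5L)
  chain <- cbind(0:4, 0, 0)          # uniform straight chain
  # interior vertices equal their neighbour means; only the endpoints count
  expect_equal(meshReg(chain, pathAdj), 2 * 1^2)
})

test_that("the pose priors evaluate exact densities", {
  g <- standardGaussianPrior()
  expect_equal(posePrior(numeric(72), g), 36 * log(2 * pi))
  expect_lt(posePrior(numeric(72), g), posePrior(rep(2, 72), g))
  expect_error(posePrior(numeric(72), list(type = "gauss")), "fitted")

  # two-component toy mixture: NLL equals the hand-computed density
  prior <- structure(list(type = "gmm", weights = c(0.3, 0.7),
                          means = cbind(rep(0, 72), rep(0.5, 72)),
                          vars = cbind(rep(1, 72), rep(0.25, 72))),
                     class = "posePrior")
  th <- rep(0.2, 72)
  dens <- 0.3 * prod(stats::dnorm(th, 0, 1)) +
    0.7 * prod(stats::dnorm(th, 0.5, 0.5))
  expect_equal(posePrior(th, prior), -log(dens), tolerance = 1e-8)

  # mixture fitted on samples reproduces high density near cluster centres
  set.seed(3)
  lib <- rbind(matrix(rnorm(60 * 72, 0, 0.05), 60),
               matrix(rnorm(60 * 72, 1, 0.05), 60))
  fitted <- fitPosePrior(lib, G = 2)
  expect_lt(posePrior(rep(0, 72), fitted), posePrior(rep(0.5, 72), fitted))
  expect_lt(posePrior(rep(1, 72), fitted), posePrior(rep(0.5, 72), fitted))
})

test_that("analytic gradients match central finite differences", {
  set.seed(4)
  T <- 2
  Jt <- array(0, c(T, 24, 3))
  for (t in 1:T)
    Jt[t, , ] <- lbsForward(mod, rnorm(72, 0, 0.1), withVertices = FALSE)$joints +
      rnorm(72, 0, 15)
  cfg <- fitConfig()
  layout <- list(T = T,
                 thetaIdx = lapply(1:T, function(t) (t - 1) * 75 + 1:72),
                 transIdx = lapply(1:T, function(t) (t - 1) * 75 + 73:75),
                 betaIdx = T * 75 + 1:10)
  adj <- meshAdjacency(mod@faces, nrow(mod@templateVertices))
  set.seed(5)
  par <- c(rnorm(T * 75, 0, 0.1), rnorm(10, 0, 0.3))
  ob <- rgbdpose:::.seqObjective(par, layout, Jt, mod, cfg, adj, needGrad = TRUE)
  idx <- c(1, 3, 25, 47, 73, 74, 75, 76, 100, 148, 149, 150, 151, 154, 158, 160)
  fd <- vapply(idx, function(i) {
    h <- 1e-5 * max(1, abs(par[i]))
    p1 <- par; p1[i] <- p1[i] + h
    p2 <- par; p2[i] <- p2[i] - h
    (rgbdpose:::.seqObjective(p1, layout, Jt, mod, cfg, adj, needGrad = FALSE)$value -
       rgbdpose:::.seqObjective(p2, layout, Jt, mod, cfg, adj, needGrad = FALSE)$value) /
      (2 * h)
  }, numeric(1))
  rel <- abs(ob$grad[idx] - fd) / pmax(abs(fd), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("joint targets from the model itself are recovered", {
  set.seed(11)
  thStar <- rnorm(72, 0, 0.15); thStar[1:3] <- c(0.2, -0.3, 0.4)
  Jt <- array(lbsForward(mod, thStar, translation = c(100, -50, 2000),
                         withVertices = FALSE)$joints, c(1, 24, 3))
  cfg <- fitConfig(lambdas = c(1, 0, 0, 0, 0),
                   iters = c(global = 60, pose = 150, pose_shape = 0),
                   polish = TRUE, polishIters = 250)
  fit <- fitSequence(Jt, mod, cfg)
  tr <- lossTrace(fit)
  expect_lt(tail(tr$joint, 1) / 24, 1e-2)           # < 1e-2 mm^2 per joint
  expect_lte(tail(tr$total, 1), tr$total[1])        # descent sanity
  expect_equal(ncol(fittedTheta(fit)), 72L)
  expect_length(fittedBeta(fit), 10L)

  # every term is non-negative at arbitrary parameters
  adj <- meshAdjacency(mod@faces, nrow(mod@templateVertices))
  base <- rgbdpose:::.seqObjective(numeric(85),
                                   list(T = 1, thetaIdx = list(1:72),
                                        transIdx = list(73:75), betaIdx = 76:85),
                                   Jt, mod, fitConfig(), adj, needGrad = FALSE)
  expect_true(all(base$terms >= 0))
})

test_that("joint mapping converts units and inverts depth", {
  kp <- liftTo3d(matrix(rep(c(10, 20, 1500), 24), 24, 3, byrow = TRUE)[, 1:2],
                 matrix(1500, 50, 50))
  arr <- mapJoints(kp, cameraScale = 2)
  expect_equal(dim(arr), c(1L, 24L, 3L))
  expect_equal(unname(arr[1, 1, ]), c(20, 40, -1500))
  # involution of the depth inversion
  arr2 <- arr; arr2[, , 3] <- -arr2[, , 3]
  expect_equal(unname(arr2[1, 1, 3]), 1500)
})
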