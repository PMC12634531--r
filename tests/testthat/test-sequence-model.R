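# Fusion and the Transformer sequence classifier.

smallConfig <- function(classes = 3, seed = 1) {
  transformerConfig(d_model = 16L, heads = 4L, layers = 2L, ffn_dim = 32L,
                    classes = classes, max_len = 24L, seed = seed)
}

test_that("fusion concatenates blocks recoverably", {
  f <- fuseFeatures(1:5, 6:8, 9:12)
  expect_length(f, 12)
  expect_equal(attr(f, "blocks"), c(k = 5L, b = 3L, m = 4L))
  # blocks recoverable by slicing
  expect_equal(as.numeric(f[1:5]), 1:5)
  expect_equal(as.numeric(f[9:12]), 9:12)
  # zero-length blocks are permitted
  expect_length(fuseFeatures(numeric(0), 1:3, numeric(0)), 3)

  rows <- list(fuseFeatures(1:2, 3:4, 5:6), fuseFeatures(1:2, 3:4, 5:7))
  expect_error(featureMatrix(rows), "drift.*m")
})

test_that("positional encodings follow the sinusoidal closed form", {
  cfg <- smallConfig()
  mod <- transformerInit(6, cfg)
  P <- rgbdpose:::.posEncoding(cfg$max_len, cfg$d_model)
  expect_equal(P[1, seq(1, 16, 2)], rep(0, 8))  # sin(0)
  expect_equal(P[1, seq(2, 16, 2)], rep(1, 8))  # cos(0)
  # distinct positions get distinct encodings
  expect_equal(nrow(unique(round(P, 10))), cfg$max_len)

  # zero projection: embeddings equal the positional encodings alone
  mod$params$Win[] <- 0; mod$params$bin[] <- 0
  F <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(embedSequence(F, mod), P[1:5, ])
  expect_error(embedSequence(matrix(0, 30, 6), mod), "max_len")
})

test_that("attention is row-stochastic and matches a naive two-loop oracle", {
  set.seed(2)
  for (rep in 1:3) {
    Q <- matrix(rnorm(5 * 8), 5, 8); K <- matrix(rnorm(5 * 8), 5, 8)
    V <- matrix(rnorm(5 * 8), 5, 8)
    at <- attention(Q, K, V)
    expect_lt(max(abs(rowSums(at$weights) - 1)), 1e-12)
    expect_lt(max(abs(at$output - naiveAttention(Q, K, V))), 1e-6)
  }
  # identical keys: uniform weights, output rows equal the V mean
  K1 <- matrix(1, 4, 8)[rep(1, 4), ]
  V1 <- matrix(rnorm(32), 4, 8)
  at1 <- attention(matrix(rnorm(24), 3, 8), K1, V1)
  expect_equal(at1$output, matrix(colMeans(V1), 3, 8, byrow = TRUE),
               tolerance = 1e-10)
})

test_that("the encoder preserves shape and normalizes rows", {
  cfg <- smallConfig()
  mod <- transformerInit(6, cfg)
  F <- matrix(rnorm(7 * 6), 7, 6)
  fw <- rgbdpose:::.transformerForward(F, mod)
  expect_equal(dim(fw$Z), c(7L, 16L))
  # LayerNorm contract: unit moments before the affine gain/bias
  ln <- rgbdpose:::.layerNorm(matrix(rnorm(40, 3, 5), 5, 8), rep(1, 8), rep(0, 8))
  expect_lt(max(abs(rowMeans(ln$out))), 1e-10)
  expect_equal(apply(ln$out, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-3)
  # probabilities form a distribution; constant logit shifts cancel
  expect_equal(sum(fw$probs), 1, tolerance = 1e-12)
  mod2 <- mod; mod2$params$bc <- mod$params$bc + 5
  fw2 <- rgbdpose:::.transformerForward(F, mod2)
  expect_equal(fw2$probs, fw$probs, tolerance = 1e-9)

  # single-head attention equals one attention call followed by Wo
  cfg1 <- transformerConfig(d_model = 16L, heads = 1L, layers = 1L,
                            ffn_dim = 32L, classes = 3, max_len = 24L, seed = 2)
  m1 <- transformerInit(6, cfg1)
  Z <- embedSequence(F, m1)
  at <- attention(Z %*% m1$params$layers[[1]]$Wq, Z %*% m1$params$layers[[1]]$Wk,
                  Z %*% m1$params$layers[[1]]$Wv)
  S <- at$output %*% m1$params$layers[[1]]$Wo
  fw1 <- rgbdpose:::.transformerForward(F, m1)
  ln <- rgbdpose:::.layerNorm(Z + S, m1$params$layers[[1]]$g1,
                              m1$params$layers[[1]]$be1)
  expect_equal(fw1$caches[[1]]$ln1$out, ln$out, tolerance = 1e-10)
})

test_that("padding rows change nothing", {
  cfg <- smallConfig()
  mod <- transformerInit(6, cfg)
  F <- matrix(rnorm(8 * 6), 8, 6)
  p1 <- classifySequence(F, mod)$probs
  Fpad <- rbind(F, matrix(0, 4, 6))
  p2 <- classifySequence(Fpad, mod, padMask = c(rep(FALSE, 8), rep(TRUE, 4)))$probs
  expect_lt(max(abs(p1 - p2)), 1e-6)
  expect_error(rgbdpose:::.transformerForward(F, mod, padMask = rep(TRUE, 8)),
               "padding")
})

test_that("training separates synthetic classes and reproduces under a seed", {
  set.seed(20)
  mk <- function(mu, n) lapply(1:n, function(i) matrix(rnorm(10 * 6, mu), 10, 6))
  feats <- c(mk(0, 12), mk(1.5, 12), mk(3, 12))
  labs <- rep(c("a", "b", "c"), each = 12)
  expect_error(trainTransformer(feats[1:12], labs[1:12], smallConfig()),
               "2 classes")

  tr1 <- trainTransformer(feats, labs, smallConfig(), epochs = 6,
                          batchSize = 8, lr = 2e-3, seed = 3)
  expect_lt(tail(tr1$history$loss, 1), tr1$history$loss[1])
  expect_gte(evaluateClassifier(tr1$model, feats, labs)$accuracy, 0.9)

  tr2 <- trainTransformer(feats, labs, smallConfig(), epochs = 6,
                          batchSize = 8, lr = 2e-3, seed = 3)
  expect_identical(rgbdpose:::.flattenParams(tr1$model$params),
                   rgbdpose:::.flattenParams(tr2$model$params))

  # evaluation is invariant to sequence order within the batch
  perm <- sample(length(feats))
  ev <- evaluateClassifier(tr1$model, feats[perm], labs[perm])
  expect_equal(ev$accuracy, evaluateClassifier(tr1$model, feats, labs)$accuracy)
  # confusion rows sum to the class counts; row-normalized rows sum to 1
  expect_equal(unname(rowSums(ev$confusion)), unname(table(labs)[rownames(ev$confusion)]),
               ignore_attr = TRUE)
  rn <- ev$confusion / rowSums(ev$confusion)
  expect_equal(unname(rowSums(rn)), rep(1, 3))
})
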