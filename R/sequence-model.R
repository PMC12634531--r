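# Feature fusion and the Transformer encoder classifier: per-frame affine
# embedding plus fixed sinusoidal positional encodings, stacked post-norm
# encoder blocks (multi-head self-attention -> add & LayerNorm ->
# position-wise feed-forward -> add & LayerNorm), masked mean pooling over
# time and a softmax classification head, trained with cross-entropy and
# Adam. Forward and backward passes are implemented with plain matrix
# algebra; everything is deterministic under a fixed seed.

#' Fuse per-frame feature blocks
#'
#' Concatenates the 2D-keypoint block, the part-contour block and the mesh
#' block (pose, shape, fitted joints) of one frame, in that order.
#'
#' @param k,b,m numeric vectors (any may be length 0).
#' @return Numeric vector of length P + Q + S with a "blocks" attribute
#'   recording the layout.
#' @export
fuseFeatures <- function(k, b, m) {
  out <- c(k, b, m)
  attr(out, "blocks") <- c(k = length(k), b = length(b), m = length(m))
  out
}

#' Assemble a per-sequence feature matrix
#'
#' Stacks per-frame fused vectors; all rows must agree in length and block
#' layout.
#'
#' @param featureRows list of vectors from \code{\link{fuseFeatures}}.
#' @return M x (P+Q+S) matrix with the block layout attribute.
#' @export
featureMatrix <- function(featureRows) {
  lens <- vapply(featureRows, length, integer(1))
  if (length(unique(lens)) != 1) {
    bl <- lapply(featureRows, attr, "blocks")
    drift <- which(lens != lens[1])[1]
    blk <- "unknown"
    if (!is.null(bl[[1]]) && !is.null(bl[[drift]]))
      blk <- paste(names(which(bl[[1]] != bl[[drift]])), collapse = ", ")
    stop("feature length drift at frame ", drift, " (block: ", blk, ")",
         call. = FALSE)
  }
  F <- do.call(rbind, lapply(featureRows, as.numeric))
  attr(F, "blocks") <- attr(featureRows[[1]], "blocks")
  F
}

#' Transformer configuration
#'
#' Defaults follow the reference encoder of the pipeline: 4 layers, 8
#' heads, 512 model dimensions with a 2048-unit feed-forward inner layer.
#'
#' @param d_model model width (divisible by \code{heads}).
#' @param heads attention heads.
#' @param layers encoder blocks.
#' @param ffn_dim feed-forward inner width.
#' @param classes number of output classes K.
#' @param dropout dropout probability during training.
#' @param max_len maximum sequence length (positional encoding table size).
#' @param seed integer seed for parameter initialization.
#' @return Named list.
#' @export
transformerConfig <- function(d_model = 512L, heads = 8L, layers = 4L,
                              ffn_dim = 2048L, classes, dropout = 0,
                              max_len = 512L, seed = 0L) {
  if (d_model %% heads != 0) stop("d_model must be divisible by heads", call. = FALSE)
  list(d_model = as.integer(d_model), heads = as.integer(heads),
       layers = as.integer(layers), ffn_dim = as.integer(ffn_dim),
       classes = as.integer(classes), dropout = dropout,
       max_len = as.integer(max_len), seed = as.integer(seed))
}

# Sinusoidal positional encoding table (max_len x d): even dimensions
# sin(pos / 10000^(2i/d)), odd dimensions cos of the same argument.
.posEncoding <- function(maxLen, d) {
  pos <- 0:(maxLen - 1)
  P <- matrix(0, maxLen, d)
  for (i in 0:(d %/% 2 - 1)) {
    arg <- pos / 10000^(2 * i / d)
    P[, 2 * i + 1] <- sin(arg)
    if (2 * i + 2 <= d) P[, 2 * i + 2] <- cos(arg)
  }
  P
}

#' Initialize a Transformer classifier
#'
#' Xavier-uniform initialization of all projection, attention,
#' feed-forward and classifier weights, seeded from the configuration.
#'
#' @param inputDim fused feature dimension (P+Q+S).
#' @param config a \code{\link{transformerConfig}}.
#' @return A "TransformerModel": list(params, config, inputDim,
#'   standardization = NULL).
#' @export
transformerInit <- function(inputDim, config) {
  d <- config$d_model; f <- config$ffn_dim
  xav <- function(nin, nout) matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)),
                                    nin, nout)
  params <- .withSeed(config$seed, {
    p <- list(Win = xav(inputDim, d), bin = numeric(d),
              Wc = xav(d, config$classes), bc = numeric(config$classes),
              layers = vector("list", config$layers))
    for (l in seq_len(config$layers)) {
      p$layers[[l]] <- list(
        Wq = xav(d, d), Wk = xav(d, d), Wv = xav(d, d), Wo = xav(d, d),
        W1 = xav(d, f), b1 = numeric(f), W2 = xav(f, d), b2 = numeric(d),
        g1 = rep(1, d), be1 = numeric(d), g2 = rep(1, d), be2 = numeric(d))
    }
    p
  })
  structure(list(params = params, config = config, inputDim = inputDim,
                 standardization = NULL, classLabels = NULL),
            class = "TransformerModel")
}

#' Scaled dot-product attention
#'
#' softmax(Q K^T / sqrt(d_k)) V with a row-wise stable softmax; optional
#' key padding mask.
#'
#' @param Q,K,V matrices with matching inner dimensions.
#' @param padMask logical vector over key rows (TRUE = padding, excluded).
#' @return list(output, weights).
#' @export
attention <- function(Q, K, V, padMask = NULL) {
  dk <- ncol(K)
  S <- Q %*% t(K) / sqrt(dk)
  if (!is.null(padMask) && any(padMask)) S[, padMask] <- -Inf
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  list(output = A %*% V, weights = A)
}

.layerNorm <- function(U, g, b, eps = 1e-5) {
  mu <- rowMeans(U)
  xc <- U - mu
  va <- rowMeans(xc^2)
  xhat <- xc / sqrt(va + eps)
  list(out = sweep(xhat * rep(g, each = nrow(U)), 2, b, `+`),
       xhat = xhat, inv = 1 / sqrt(va + eps))
}

.layerNormBack <- function(dOut, cacheLN, g) {
  dxhat <- dOut * rep(g, each = nrow(dOut))
  xhat <- cacheLN$xhat
  du <- cacheLN$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dU = du, dg = colSums(dOut * xhat), db = colSums(dOut))
}

#' Embed a feature sequence
#'
#' Per-row affine projection into the model width plus the fixed
#' sinusoidal positional encoding.
#'
#' @param F M x D feature matrix.
#' @param model a TransformerModel.
#' @return M x d_model embedded sequence.
#' @export
embedSequence <- function(F, model) {
  if (nrow(F) > model$config$max_len)
    stop("sequence length ", nrow(F), " exceeds max_len ", model$config$max_len,
         call. = FALSE)
  E <- F %*% model$params$Win + rep(model$params$bin, each = nrow(F))
  E + .posEncoding(model$config$max_len, model$config$d_model)[seq_len(nrow(F)), , drop = FALSE]
}

# full forward pass with caches for backprop
.transformerForward <- function(F, model, padMask = NULL, dropSeed = NULL) {
  cfg <- model$config
  p <- model$params
  M <- nrow(F)
  if (is.null(padMask)) padMask <- rep(FALSE, M)
  if (all(padMask)) stop("sequence consists only of padding", call. = FALSE)
  Z <- embedSequence(F, model)
  drop <- cfg$dropout > 0 && !is.null(dropSeed)
  caches <- vector("list", cfg$layers)
  h <- cfg$heads; dk <- cfg$d_model %/% h
  for (l in seq_len(cfg$layers)) {
    lp <- p$layers[[l]]
    Zin <- Z
    Q <- Zin %*% lp$Wq; K <- Zin %*% lp$Wk; V <- Zin %*% lp$Wv
    heads <- vector("list", h)
    concat <- matrix(0, M, cfg$d_model)
    for (hh in seq_len(h)) {
      sl <- ((hh - 1) * dk + 1):(hh * dk)
      at <- attention(Q[, sl, drop = FALSE], K[, sl, drop = FALSE],
                      V[, sl, drop = FALSE], padMask)
      heads[[hh]] <- at
      concat[, sl] <- at$output
    }
    S <- concat %*% lp$Wo
    if (drop) {
      keep <- .withSeed(dropSeed + 101 * l, matrix(runif(M * cfg$d_model) >= cfg$dropout,
                                                   M, cfg$d_model))
      S <- S * keep / (1 - cfg$dropout)
    } else keep <- NULL
    ln1 <- .layerNorm(Zin + S, lp$g1, lp$be1)
    Z1 <- ln1$out
    F1 <- Z1 %*% lp$W1 + rep(lp$b1, each = M)
    R <- pmax(F1, 0)
    F2 <- R %*% lp$W2 + rep(lp$b2, each = M)
    ln2 <- .layerNorm(Z1 + F2, lp$g2, lp$be2)
    Z <- ln2$out
    caches[[l]] <- list(Zin = Zin, Q = Q, K = K, V = V, heads = heads,
                        concat = concat, ln1 = ln1, Z1 = Z1, F1 = F1, R = R,
                        ln2 = ln2, keep = keep)
    if (!all(is.finite(Z))) stop("non-finite activations in encoder layer ", l,
                                 call. = FALSE)
  }
  valid <- !padMask
  zagg <- colSums(Z[valid, , drop = FALSE]) / sum(valid)
  logits <- as.numeric(zagg %*% p$Wc + p$bc)
  logits <- logits - max(logits)
  probs <- exp(logits) / sum(exp(logits))
  list(Z = Z, zagg = zagg, probs = probs, caches = caches, padMask = padMask)
}

# backward pass; dLogits = dLoss/dlogits. Returns gradients with the
# parameter structure of model$params.
.transformerBackward <- function(F, model, fw, dLogits) {
  cfg <- model$config
  p <- model$params
  M <- nrow(F)
  h <- cfg$heads; dk <- cfg$d_model %/% h
  g <- list(Win = matrix(0, nrow(p$Win), ncol(p$Win)), bin = numeric(cfg$d_model),
            Wc = matrix(0, cfg$d_model, cfg$classes), bc = numeric(cfg$classes),
            layers = vector("list", cfg$layers))
  g$Wc <- outer(fw$zagg, dLogits)
  g$bc <- dLogits
  valid <- !fw$padMask
  dZ <- matrix(0, M, cfg$d_model)
  dzagg <- as.numeric(p$Wc %*% dLogits)
  dZ[valid, ] <- matrix(dzagg / sum(valid), sum(valid), cfg$d_model, byrow = TRUE)
  for (l in rev(seq_len(cfg$layers))) {
    lp <- p$layers[[l]]
    ca <- fw$caches[[l]]
    lb2 <- .layerNormBack(dZ, ca$ln2, lp$g2)
    dU2 <- lb2$dU
    dZ1 <- dU2
    dF2 <- dU2
    dW2 <- crossprod(ca$R, dF2)
    db2 <- colSums(dF2)
    dR <- tcrossprod(dF2, lp$W2)
    dF1 <- dR * (ca$F1 > 0)
    dW1 <- crossprod(ca$Z1, dF1)
    db1 <- colSums(dF1)
    dZ1 <- dZ1 + tcrossprod(dF1, lp$W1)
    lb1 <- .layerNormBack(dZ1, ca$ln1, lp$g1)
    dU <- lb1$dU
    dS <- dU
    if (!is.null(ca$keep)) dS <- dS * ca$keep / (1 - cfg$dropout)
    dZin <- dU
    dWo <- crossprod(ca$concat, dS)
    dConcat <- tcrossprod(dS, lp$Wo)
    dQ <- matrix(0, M, cfg$d_model); dK <- dQ; dV <- dQ
    for (hh in seq_len(h)) {
      sl <- ((hh - 1) * dk + 1):(hh * dk)
      A <- ca$heads[[hh]]$weights
      dH <- dConcat[, sl, drop = FALSE]
      dA <- tcrossprod(dH, ca$V[, sl, drop = FALSE])
      dV[, sl] <- crossprod(A, dH)
      dScores <- A * (dA - rowSums(dA * A))
      dQ[, sl] <- dScores %*% ca$K[, sl, drop = FALSE] / sqrt(dk)
      dK[, sl] <- crossprod(dScores, ca$Q[, sl, drop = FALSE]) / sqrt(dk)
    }
    gl <- list(Wq = crossprod(ca$Zin, dQ), Wk = crossprod(ca$Zin, dK),
               Wv = crossprod(ca$Zin, dV), Wo = dWo,
               W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
               g1 = lb1$dg, be1 = lb1$db, g2 = lb2$dg, be2 = lb2$db)
    dZin <- dZin + tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
      tcrossprod(dV, lp$Wv)
    g$layers[[l]] <- gl
    dZ <- dZin
  }
  g$Win <- crossprod(F, dZ)
  g$bin <- colSums(dZ)
  g
}

#' Classify a feature sequence
#'
#' Runs the encoder with masked attention and masked mean pooling over the
#' non-padding rows, then the softmax classification head.
#'
#' @param F M x D feature matrix (raw; the model's stored standardization
#'   is applied).
#' @param model a trained TransformerModel.
#' @param padMask logical vector (TRUE = padding row).
#' @return list(probs = class probabilities, predicted = label index (or
#'   label if the model stores labels)).
#' @export
classifySequence <- function(F, model, padMask = NULL) {
  F <- .applyStandardization(F, model$standardization)
  fw <- .transformerForward(F, model, padMask)
  pred <- which.max(fw$probs)
  lab <- if (!is.null(model$classLabels)) model$classLabels[pred] else pred
  list(probs = fw$probs, predicted = lab)
}

.applyStandardization <- function(F, st) {
  if (is.null(st)) return(F)
  sweep(sweep(F, 2, st$mean, `-`), 2, st$sd, `/`)
}

# flatten/unflatten parameter lists for the Adam state
.flattenParams <- function(p) {
  unlist(list(p$Win, p$bin, p$Wc, p$bc,
              lapply(p$layers, function(l) unlist(l))), use.names = FALSE)
}

.unflattenParams <- function(vec, tmpl) {
  out <- tmpl; k <- 0
  put <- function(x) {
    n <- length(x)
    v <- vec[(k + 1):(k + n)]; k <<- k + n
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  out$Win <- put(tmpl$Win); out$bin <- put(tmpl$bin)
  out$Wc <- put(tmpl$Wc); out$bc <- put(tmpl$bc)
  for (l in seq_along(tmpl$layers))
    out$layers[[l]] <- lapply(tmpl$layers[[l]], put)
  out
}

#' Train the Transformer classifier
#'
#' Mini-batch Adam on the cross-entropy loss with seeded initialization
#' and shuffling; per-dimension z-scoring is fitted on the training set
#' and stored in the model. Deterministic for a fixed seed in a
#' single-threaded session.
#'
#' @param features list of M x D feature matrices (one per sequence).
#' @param labels factor or character vector of class labels (>= 2 classes).
#' @param config a \code{\link{transformerConfig}} (classes may be omitted
#'   and is inferred).
#' @param epochs training epochs.
#' @param batchSize sequences per mini-batch.
#' @param lr Adam learning rate.
#' @param seed integer seed for shuffling and dropout.
#' @param validation optional list(features, labels) evaluated per epoch.
#' @return list(model, history = per-epoch data.frame(epoch, loss,
#'   accuracy, val_accuracy)).
#' @export
trainTransformer <- function(features, labels, config, epochs = 15,
                             batchSize = 16, lr = 1e-3, seed = 0L,
                             validation = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training needs at least 2 classes", call. = FALSE)
  config$classes <- length(classes)
  y <- match(labels, classes)
  D <- ncol(features[[1]])
  allRows <- do.call(rbind, features)
  st <- list(mean = colMeans(allRows), sd = pmax(apply(allRows, 2, stats::sd), 1e-8))
  features <- lapply(features, .applyStandardization, st = st)
  model <- transformerInit(D, config)
  model$standardization <- st
  model$classLabels <- classes
  par <- .flattenParams(model$params)
  mAd <- numeric(length(par)); vAd <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- length(features)
  hist <- NULL
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- .withSeed(seed + ep, sample.int(n))
    epLoss <- 0; epCorrect <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / batchSize))) {
      gAcc <- NULL
      bLoss <- 0
      for (si in bs) {
        F <- features[[si]]
        fw <- .transformerForward(F, model, dropSeed = if (config$dropout > 0)
          seed + 7919 * si + ep else NULL)
        pr <- fw$probs
        bLoss <- bLoss - log(max(pr[y[si]], 1e-12))
        if (which.max(pr) == y[si]) epCorrect <- epCorrect + 1
        dLogits <- pr
        dLogits[y[si]] <- dLogits[y[si]] - 1
        gr <- .transformerBackward(F, model, fw, dLogits)
        gv <- .flattenParams(gr)
        gAcc <- if (is.null(gAcc)) gv else gAcc + gv
      }
      gAcc <- gAcc / length(bs)
      epLoss <- epLoss + bLoss
      step <- step + 1
      mAd <- b1 * mAd + (1 - b1) * gAcc
      vAd <- b2 * vAd + (1 - b2) * gAcc^2
      par <- par - lr * (mAd / (1 - b1^step)) / (sqrt(vAd / (1 - b2^step)) + eps)
      model$params <- .unflattenParams(par, model$params)
    }
    valAcc <- NA
    if (!is.null(validation)) {
      pv <- vapply(validation$features, function(F)
        classifySequence(F, model)$predicted, character(1))
      valAcc <- mean(pv == as.character(validation$labels))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / n,
                                   accuracy = epCorrect / n, val_accuracy = valAcc))
  }
  list(model = model, history = hist)
}

#' Evaluate a classifier on labelled sequences
#'
#' @param model a trained TransformerModel.
#' @param features list of feature matrices.
#' @param labels true labels.
#' @return list(accuracy, confusion = K x K count matrix (rows = truth),
#'   perClass = data.frame(class, precision, recall, f1)).
#' @export
evaluateClassifier <- function(model, features, labels) {
  labels <- as.character(labels)
  classes <- model$classLabels
  pred <- vapply(features, function(F) classifySequence(F, model)$predicted,
                 character(1))
  conf <- table(factor(labels, levels = classes), factor(pred, levels = classes))
  conf <- matrix(conf, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(pred == labels), confusion = conf,
       perClass = data.frame(class = classes, precision = as.numeric(prec),
                             recall = as.numeric(rec), f1 = as.numeric(f1)))
}
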