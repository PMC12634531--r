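# Independent oracles and small fixtures shared across the suite. These
# deliberately avoid the package's own implementations.

# Breadth-first flood fill: connected components of a binary matrix.
floodFillComponents <- function(mask, connectivity = 8) {
  fg <- mask > 0
  lab <- matrix(0L, nrow(fg), ncol(fg))
  nb <- if (connectivity == 8)
    expand.grid(dy = -1:1, dx = -1:1)[-5, ] else
      data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      px <- queue[1]; queue <- queue[-1]
      r <- (px - 1) %% nrow(fg) + 1
      c <- (px - 1) %/% nrow(fg) + 1
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb$dy[k]; cc <- c + nb$dx[k]
        if (rr >= 1 && rr <= nrow(fg) && cc >= 1 && cc <= ncol(fg) &&
            fg[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- c(queue, (cc - 1) * nrow(fg) + rr)
        }
      }
    }
  }
  lab
}

# Point-to-segment distance used for brute-force polyline tolerance checks.
pointSegmentDistance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((p - (a + t * ab))^2))
}

# Distance of every foreground boundary pixel of a mask to a polygon.
maxDistanceToPolygon <- function(points, polygon) {
  apply(points, 1, function(p) {
    dmin <- Inf
    n <- nrow(polygon)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      dmin <- min(dmin, pointSegmentDistance(p, polygon[i, ], polygon[j, ]))
    }
    dmin
  })
}

# Two-loop scaled dot-product attention.
naiveAttention <- function(Q, K, V) {
  out <- matrix(0, nrow(Q), ncol(V))
  dk <- ncol(K)
  for (i in seq_len(nrow(Q))) {
    s <- vapply(seq_len(nrow(K)), function(j) sum(Q[i, ] * K[j, ]) / sqrt(dk),
                numeric(1))
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# directed Hausdorff distance between the foreground pixel sets of two masks
maskBoundaryDistance <- function(a, b) {
  pa <- which(a > 0, arr.ind = TRUE)
  pb <- which(b > 0, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  d1 <- max(vapply(seq_len(nrow(pa)), function(i)
    sqrt(min((pa[i, 1] - pb[, 1])^2 + (pa[i, 2] - pb[, 2])^2)), numeric(1)))
  d2 <- max(vapply(seq_len(nrow(pb)), function(i)
    sqrt(min((pb[i, 1] - pa[, 1])^2 + (pb[i, 2] - pa[, 2])^2)), numeric(1)))
  max(d1, d2)
}

# small scene used throughout the unit tests (fast to render)
testScene <- function(noise = 0, seed = 1L) {
  sceneConfig(imageSize = c(120L, 112L), cameraScale = 23,
              depthNoiseSd = noise, seed = seed)
}

# random blob mask fixture
randomBlob <- function(seed, size = 48L) {
  set.seed(seed)
  m <- matrix(0, size, size)
  for (k in 1:4) {
    cx <- runif(1, 12, size - 12); cy <- runif(1, 12, size - 12)
    r <- runif(1, 4, 9)
    xg <- matrix(rep(1:size, each = size), size)
    yg <- matrix(rep(1:size, size), size)
    m[(xg - cx)^2 + (yg - cy)^2 <= r^2] <- 255
  }
  # keep the largest 8-connected component only, so fixtures are single blobs
  lab <- floodFillComponents(m)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    m <- (lab == which.max(sizes)) * 255
  }
  m
}
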