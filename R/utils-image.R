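# Internal raster helpers.
#
# Convention used throughout the package: an image is a base R matrix with
# rows indexing y (top to bottom) and columns indexing x (left to right);
# pixel coordinates are 0-based and pixel-centred, so pixel (x, y) lives at
# m[y + 1, x + 1]. Binary masks take values in {0, 255}.

#' @import methods
#' @importFrom stats rnorm runif median setNames optim dist sd quantile
#' @importFrom utils head tail write.csv read.csv
NULL

.assertMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 255)))
    stop("mask must be binary with values in {0, 255}", call. = FALSE)
  invisible(TRUE)
}

# Shift a matrix by (dy, dx), padding with `fill`. Used to vectorize
# neighbourhood operations (thinning, FAST tests, bilateral filter).
.shiftMat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

# 8-connected labelling of a binary mask. EBImage::bwlabel is 4-connected,
# so labels touching diagonally are merged through a label-level union.
.labelComponents8 <- function(mask) {
  bin <- (mask > 0) * 1
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.numeric(lab), nrow(bin), ncol(bin))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # collect label pairs adjacent across the two diagonal directions
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nrow(lab) - 1), , drop = FALSE]
    b <- lab[2:nrow(lab), , drop = FALSE]
    if (d[2] == 1) {
      a <- a[, 1:(ncol(a) - 1), drop = FALSE]
      b <- b[, 2:ncol(b), drop = FALSE]
    } else {
      a <- a[, 2:ncol(a), drop = FALSE]
      b <- b[, 1:(ncol(b) - 1), drop = FALSE]
    }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  # union-find over the (small) set of labels
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, numeric(1))
  # compact label ids
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Outer boundary trace (Moore neighbourhood, via EBImage::ocontour) of the
# largest 8-connected component of a binary mask. Returns an n x 2 matrix of
# 0-based (x, y) pixel coordinates, ordered clockwise in image coordinates
# (y pointing down) and starting at the topmost-then-leftmost boundary pixel.
.traceBoundary <- function(mask) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot trace boundary of an empty mask", call. = FALSE)
  lab <- .labelComponents8(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- (lab == which.max(sizes)) * 1
  if (sum(big) == 1L) {
    idx <- which(big == 1, arr.ind = TRUE)
    return(cbind(x = idx[1, 2] - 1L, y = idx[1, 1] - 1L))
  }
  oc <- EBImage::ocontour(big)[[1]]
  # matrices are stored rows = y, so ocontour's first column is y
  pts <- cbind(x = oc[, 2], y = oc[, 1])
  if (nrow(pts) > 1) {
    # enforce clockwise orientation in image coordinates (y down):
    # visually-clockwise corresponds to positive shoelace area here
    xs <- pts[, 1]; ys <- pts[, 2]
    x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
    if (sum(xs * y2 - x2 * ys) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
    # rotate to the deterministic start pixel
    ymin <- min(pts[, 2])
    cand <- which(pts[, 2] == ymin)
    s <- cand[which.min(pts[cand, 1])]
    if (s > 1) pts <- pts[c(s:nrow(pts), 1:(s - 1)), , drop = FALSE]
  }
  rownames(pts) <- NULL
  pts
}

# Zhang-Suen thinning to a 1-px-wide medial axis; vectorized over the image.
.thinMask <- function(mask) {
  p <- mask > 0
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- .shiftMat(p, 1, 0, FALSE);  p3 <- .shiftMat(p, 1, -1, FALSE)
      p4 <- .shiftMat(p, 0, -1, FALSE); p5 <- .shiftMat(p, -1, -1, FALSE)
      p6 <- .shiftMat(p, -1, 0, FALSE); p7 <- .shiftMat(p, -1, 1, FALSE)
      p8 <- .shiftMat(p, 0, 1, FALSE);  p9 <- .shiftMat(p, 1, 1, FALSE)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) a <- a + (!seq9[[i]] & seq9[[i + 1]])
      if (phase == 1) {
        cond <- p & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { p[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  p * 255
}

# Bounding box of mask foreground: list(top, left, h, w) in 0-based coords,
# with h = bottom - top and w = right - left (row/column spans).
.maskBbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box", call. = FALSE)
  list(top = min(idx[, 1]) - 1L, left = min(idx[, 2]) - 1L,
       h = diff(range(idx[, 1])), w = diff(range(idx[, 2])))
}

# Separable Gaussian blur that falls back to identity for sigma <= 0.
# Small images use direct shift-based separable convolution (cheaper than
# FFT dispatch); larger ones go through EBImage.
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  if (length(m) <= 40000) return(.gblurSmall(m, sigma))
  matrix(as.numeric(EBImage::gblur(m, sigma = sigma)), nrow(m), ncol(m))
}

# Shift with edge replication (clamped indexing): out[y, x] = m[y - dy, x - dx]
# with source coordinates clamped to the image.
.shiftClamp <- function(m, dy, dx) {
  ys <- pmin(pmax(seq_len(nrow(m)) - dy, 1L), nrow(m))
  xs <- pmin(pmax(seq_len(ncol(m)) - dx, 1L), ncol(m))
  m[ys, xs, drop = FALSE]
}

# Direct bilinear resize for small images (index arithmetic, no dispatch).
.resizeBilinearSmall <- function(m, h, w) {
  ys <- (0:(h - 1) + 0.5) * nrow(m) / h - 0.5
  xs <- (0:(w - 1) + 0.5) * ncol(m) / w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), nrow(m) - 1); y1 <- pmin(y0 + 1, nrow(m) - 1)
  x0 <- pmin(pmax(floor(xs), 0), ncol(m) - 1); x1 <- pmin(x0 + 1, ncol(m) - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c2 <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c2 + wx * d)
}

.gblurSmall <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # replicate-pad via clamped shifts, rows then columns
  outR <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    d <- i - r - 1L
    sh <- .shiftMat(m, d, 0, NA)
    if (d > 0) sh[seq_len(d), ] <- matrix(m[1, ], d, ncol(m), byrow = TRUE)
    if (d < 0) sh[nrow(m) + d + seq_len(-d), ] <- matrix(m[nrow(m), ], -d, ncol(m), byrow = TRUE)
    outR <- outR + k[i] * sh
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    d <- i - r - 1L
    sh <- .shiftMat(outR, 0, d, NA)
    if (d > 0) sh[, seq_len(d)] <- outR[, 1]
    if (d < 0) sh[, ncol(m) + d + seq_len(-d)] <- outR[, ncol(m)]
    out <- out + k[i] * sh
  }
  out
}
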