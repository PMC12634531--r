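# 2D keypoint feature bank on binary silhouettes: Douglas-Peucker contour
# vertices, Harris and Shi-Tomasi corners, FAST-based (ORB-style) and
# multi-scale FAST (BRISK-style) corners, difference-of-Gaussian (SIFT-style)
# and nonlinear-diffusion Hessian (AKAZE-style) blobs, and medial-axis
# skeleton landmarks, with a fixed-length bbox-normalized encoding.
#
# Detectors run on the binary silhouette lightly Gaussian-blurred (sigma 1)
# so gradient-based operators see finite gradients on the textureless mask.

.detectorIds <- function() {
  c("contour", "harris", "shi_tomasi", "orb", "brisk", "sift", "akaze", "skeleton")
}

#' Detector bank configuration
#'
#' @param harris_k Harris sensitivity k of R = det(M) - k * trace(M)^2.
#' @param harris_window Gaussian integration scale of the second-moment
#'   matrix (pixels).
#' @param dp_epsilon Douglas-Peucker tolerance (pixels).
#' @param max_points points kept per detector (K).
#' @param blur_sigma pre-blur applied to the mask before gradient-based
#'   detectors (pixels).
#' @param fast_threshold FAST intensity-difference threshold on the [0, 1]
#'   scale.
#' @param response_frac local-maximum acceptance threshold as a fraction of
#'   the maximum response.
#' @return A named list of detector settings.
#' @export
detectorConfig <- function(harris_k = 0.04, harris_window = 2, dp_epsilon = 2,
                           max_points = 32L, blur_sigma = 1,
                           fast_threshold = 0.08, response_frac = 0.01) {
  stopifnot(harris_k > 0, dp_epsilon >= 0, max_points >= 1)
  list(harris_k = harris_k, harris_window = harris_window,
       dp_epsilon = dp_epsilon, max_points = as.integer(max_points),
       blur_sigma = blur_sigma, fast_threshold = fast_threshold,
       response_frac = response_frac)
}

#' Perpendicular distance of a point to a line
#'
#' Distance of p0 from the line through p1 and p2:
#' |(x2-x1)(y1-y0) - (x1-x0)(y2-y1)| / sqrt((x2-x1)^2 + (y2-y1)^2).
#'
#' @param p0,p1,p2 numeric (x, y) points; p1 must differ from p2.
#' @return The perpendicular distance.
#' @export
#' @examples
#' perpendicularDistance(c(0, 1), c(-1, 0), c(1, 0))  # 1
perpendicularDistance <- function(p0, p1, p2) {
  if (all(p1 == p2)) stop("p1 and p2 must be distinct", call. = FALSE)
  abs((p2[1] - p1[1]) * (p1[2] - p0[2]) - (p1[1] - p0[1]) * (p2[2] - p1[2])) /
    sqrt((p2[1] - p1[1])^2 + (p2[2] - p1[2])^2)
}

# Recursive Douglas-Peucker on an open polyline (rows = points, cols x/y).
# Returns the indices kept. The split point is the farthest point from the
# anchor segment (first index on ties), so the recursion tree is fixed and
# the output for a larger epsilon is a subset of that for a smaller one.
.dpIndices <- function(pts, i, j, epsilon) {
  if (j <= i + 1) return(c(i, j))
  seg <- (i + 1):(j - 1)
  dx <- pts[j, 1] - pts[i, 1]; dy <- pts[j, 2] - pts[i, 2]
  d <- abs(dx * (pts[i, 2] - pts[seg, 2]) - (pts[i, 1] - pts[seg, 1]) * dy) /
    sqrt(dx * dx + dy * dy)
  kmax <- seg[which.max(d)]
  if (max(d) > epsilon) {
    sort(unique(c(.dpIndices(pts, i, kmax, epsilon),
                  .dpIndices(pts, kmax, j, epsilon))))
  } else c(i, j)
}

#' Simplified outer contour of a silhouette
#'
#' Traces the outer boundary of the largest connected component and
#' simplifies the closed contour with the Douglas-Peucker algorithm: the
#' curve is anchored at the start pixel and at the boundary point farthest
#' from it, and each half is simplified recursively; every removed point
#' lies within \code{epsilon} of the simplified polyline. With
#' \code{epsilon = 0} the full traced contour is returned.
#'
#' @param mask binary mask (0/255).
#' @param epsilon tolerance in pixels (>= 0).
#' @return n x 2 matrix of (x, y) polygon vertices, a subsequence of the
#'   traced contour.
#' @export
approxContour <- function(mask, epsilon) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot approximate the contour of an empty mask", call. = FALSE)
  pts <- .traceBoundary(mask)
  n <- nrow(pts)
  if (epsilon == 0 || n <= 3) return(pts)
  # split the closed curve at the point farthest from the start vertex and
  # simplify both halves, wrapping the closure back to the start vertex
  d2 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  far <- which.max(d2)
  if (far == 1) return(pts[1, , drop = FALSE])
  closed <- rbind(pts, pts[1, , drop = FALSE])
  keep1 <- .dpIndices(closed, 1, far, epsilon)
  keep2 <- .dpIndices(closed, far, n + 1, epsilon)
  keep <- sort(unique(c(keep1, keep2)))
  keep <- keep[keep <= n]
  pts[keep, , drop = FALSE]
}

#' Harris corner response map
#'
#' Second-moment matrix M from Gaussian-weighted products of
#' central-difference gradients; response R = det(M) - k * trace(M)^2.
#'
#' @param image numeric intensity matrix.
#' @param k sensitivity (> 0).
#' @param window Gaussian integration scale in pixels.
#' @return Response matrix of the same size.
#' @export
harrisResponse <- function(image, k = 0.04, window = 2) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  M <- .structureTensor(image, window)
  M$xx * M$yy - M$xy^2 - k * (M$xx + M$yy)^2
}

.structureTensor <- function(image, window) {
  # edge-replicated central differences: constants stay gradient-free and
  # intensity negation flips gradients exactly, everywhere
  gx <- (.shiftClamp(image, 0, -1) - .shiftClamp(image, 0, 1)) / 2
  gy <- (.shiftClamp(image, -1, 0) - .shiftClamp(image, 1, 0)) / 2
  list(xx = .gblur(gx * gx, window), yy = .gblur(gy * gy, window),
       xy = .gblur(gx * gy, window))
}

.shiTomasiResponse <- function(image, window = 2) {
  M <- .structureTensor(image, window)
  h <- (M$xx + M$yy) / 2
  h - sqrt(pmax(0, ((M$xx - M$yy) / 2)^2 + M$xy^2))
}

# 3x3-neighbourhood local maxima above a threshold; returns (x, y, response).
.localMaxima <- function(resp, threshold) {
  best <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    best <- pmax(best, .shiftMat(resp, dy, dx, -Inf))
  }
  sel <- which(resp >= best & resp > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0) return(cbind(x = numeric(0), y = numeric(0), response = numeric(0)))
  cbind(x = sel[, 2] - 1, y = sel[, 1] - 1, response = resp[sel])
}

# FAST-9 segment-test corners on an intensity image; returns (x, y, score).
.fastCorners <- function(image, t) {
  circ <- matrix(c(0, -3, 1, -3, 2, -2, 3, -1, 3, 0, 3, 1, 2, 2, 1, 3,
                   0, 3, -1, 3, -2, 2, -3, 1, -3, 0, -3, -1, -2, -2, -1, -3),
                 ncol = 2, byrow = TRUE)  # (dx, dy)
  n <- nrow(circ)
  shifts <- lapply(seq_len(n), function(i)
    .shiftMat(image, -circ[i, 2], -circ[i, 1], NA))
  bright <- lapply(shifts, function(s) !is.na(s) & s > image + t)
  dark <- lapply(shifts, function(s) !is.na(s) & s < image - t)
  # cheap necessary condition (9 of 16 circle pixels) prunes the image to a
  # short candidate list before the exact contiguous-run test
  cntB <- Reduce(`+`, bright); cntD <- Reduce(`+`, dark)
  cand <- which(cntB >= 9 | cntD >= 9)
  if (length(cand) == 0)
    return(cbind(x = numeric(0), y = numeric(0), response = numeric(0)))
  runAtLeast <- function(lst, need) {
    M <- vapply(lst, function(b) b[cand], logical(length(cand)))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1)
    ok <- logical(length(cand))
    for (s in seq_len(n)) {
      cur <- M[, ((s - 1) %% n) + 1]
      for (kk in 1:(need - 1)) cur <- cur & M[, ((s + kk - 1) %% n) + 1]
      ok <- ok | cur
    }
    ok
  }
  corner <- matrix(FALSE, nrow(image), ncol(image))
  corner[cand] <- runAtLeast(bright, 9) | runAtLeast(dark, 9)
  if (!any(corner)) return(cbind(x = numeric(0), y = numeric(0), response = numeric(0)))
  score <- matrix(0, nrow(image), ncol(image))
  for (s in shifts) {
    d <- abs(s - image); d[is.na(d)] <- 0
    score <- score + pmax(0, d - t)
  }
  resp <- ifelse(corner, score, 0)
  .localMaxima(resp, 0)
}

# Difference-of-Gaussian scale-space extrema (SIFT-style detector core).
# The pyramid is built incrementally: each level blurs the previous one by
# the sigma increment, which keeps the convolution kernels short.
.dogExtrema <- function(image, nScales = 6, sigma0 = 1.6, contrast = 0.004) {
  sig <- sigma0 * 2^((0:(nScales - 1)) / 3)
  L <- vector("list", nScales)
  L[[1]] <- .gblur(image, sig[1])
  for (i in 2:nScales)
    L[[i]] <- .gblur(L[[i - 1]], sqrt(sig[i]^2 - sig[i - 1]^2))
  D <- lapply(seq_len(nScales - 1), function(i) L[[i + 1]] - L[[i]])
  out <- NULL
  for (i in 2:(length(D) - 1)) {
    cur <- D[[i]]
    mx <- cur; mn <- cur
    for (lvl in (i - 1):(i + 1)) for (dy in -1:1) for (dx in -1:1) {
      if (lvl == i && dy == 0 && dx == 0) next
      s <- .shiftMat(D[[lvl]], dy, dx, 0)
      mx <- pmax(mx, s); mn <- pmin(mn, s)
    }
    sel <- which((cur >= mx | cur <= mn) & abs(cur) > contrast, arr.ind = TRUE)
    if (nrow(sel) > 0)
      out <- rbind(out, cbind(x = sel[, 2] - 1, y = sel[, 1] - 1,
                              response = abs(cur[sel])))
  }
  if (is.null(out)) cbind(x = numeric(0), y = numeric(0), response = numeric(0)) else out
}

# Hessian-determinant extrema on a Perona-Malik nonlinear diffusion scale
# space (AKAZE-style detector core).
.diffusionHessianExtrema <- function(image, nLevels = 3, itersPerLevel = 4,
                                     kappa = 0.05, contrast = 1e-5) {
  lv <- vector("list", nLevels)
  u <- image
  for (l in seq_len(nLevels)) {
    for (it in seq_len(itersPerLevel)) {
      dn <- .shiftMat(u, -1, 0, NA) - u; ds <- .shiftMat(u, 1, 0, NA) - u
      de <- .shiftMat(u, 0, -1, NA) - u; dw <- .shiftMat(u, 0, 1, NA) - u
      g <- function(d) { d[is.na(d)] <- 0; d / (1 + (d / kappa)^2) }
      u <- u + 0.2 * (g(dn) + g(ds) + g(de) + g(dw))
    }
    lv[[l]] <- u
  }
  resp <- lapply(seq_len(nLevels), function(l) {
    m <- lv[[l]]
    dxx <- .shiftMat(m, 0, -1, 0) + .shiftMat(m, 0, 1, 0) - 2 * m
    dyy <- .shiftMat(m, -1, 0, 0) + .shiftMat(m, 1, 0, 0) - 2 * m
    dxy <- (.shiftMat(m, -1, -1, 0) + .shiftMat(m, 1, 1, 0) -
            .shiftMat(m, -1, 1, 0) - .shiftMat(m, 1, -1, 0)) / 4
    (l^2) * (dxx * dyy - dxy^2)
  })
  out <- NULL
  for (l in seq_len(nLevels)) {
    pts <- .localMaxima(resp[[l]], contrast)
    if (nrow(pts) > 0) out <- rbind(out, pts)
  }
  if (is.null(out)) cbind(x = numeric(0), y = numeric(0), response = numeric(0)) else out
}

#' Skeleton landmark keypoints
#'
#' Thins the silhouette to a 1-px medial axis (Zhang-Suen) and classifies
#' skeletal pixels by 8-neighbourhood connectivity: at most one foreground
#' neighbour marks an endpoint; a Rutovitz crossing number of three or more
#' (three distinct skeletal arcs meeting) marks a branch point.
#'
#' @param mask binary mask (0/255) with at least one foreground pixel.
#' @return A KeypointSet whose points carry a \code{type} column
#'   ("endpoint"/"branch"); response is the neighbour count.
#' @export
skeletonLandmarks <- function(mask) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot skeletonize an empty mask", call. = FALSE)
  # thin on a bbox crop (padded by 1) and shift coordinates back
  bb <- .maskBbox(mask)
  r0 <- max(1L, bb$top); r1 <- min(nrow(mask), bb$top + bb$h + 2L)
  c0 <- max(1L, bb$left); c1 <- min(ncol(mask), bb$left + bb$w + 2L)
  sk <- matrix(FALSE, nrow(mask), ncol(mask))
  sk[r0:r1, c0:c1] <- .thinMask(mask[r0:r1, c0:c1, drop = FALSE]) > 0
  # neighbour count and Rutovitz crossing number (0->1 transitions around
  # the 8-neighbourhood); the crossing number separates true junctions from
  # pixels merely diagonally adjacent to one
  circ <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1))
  nbv <- lapply(circ, function(d) .shiftMat(sk, d[1], d[2], FALSE))
  nb <- Reduce(`+`, nbv)
  cross <- matrix(0, nrow(sk), ncol(sk))
  for (i in 1:8) cross <- cross + (!nbv[[i]] & nbv[[(i %% 8) + 1]])
  isEnd <- sk & nb <= 1
  isBranch <- sk & cross >= 3
  sel <- which(isEnd | isBranch, arr.ind = TRUE)
  pts <- data.frame(x = sel[, 2] - 1, y = sel[, 1] - 1,
                    response = nb[sel],
                    type = ifelse(isEnd[sel], "endpoint", "branch"))
  pts <- pts[order(pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(detectorId = "skeleton", points = pts), class = "KeypointSet")
}

#' Run one detector of the keypoint bank
#'
#' Runs the named detector on a binary silhouette, keeps at most
#' \code{max_points} points by descending response (ties lexicographic by
#' (y, x)), and returns them sorted by (y, x). Deterministic for fixed
#' inputs and configuration.
#'
#' @param mask binary mask (0/255).
#' @param detectorId one of contour, harris, shi_tomasi, orb, brisk, sift,
#'   akaze, skeleton.
#' @param config a \code{\link{detectorConfig}}.
#' @return A KeypointSet: list(detectorId, points = data.frame(x, y,
#'   response)).
#' @export
detectKeypoints <- function(mask, detectorId, config = detectorConfig()) {
  ids <- .detectorIds()
  if (!detectorId %in% ids)
    stop("unknown detector '", detectorId, "'; valid: ",
         paste(ids, collapse = ", "), call. = FALSE)
  .assertMask(mask)
  empty <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0))
  if (!any(mask > 0))
    return(structure(list(detectorId = detectorId, points = empty),
                     class = "KeypointSet"))
  if (detectorId == "skeleton") {
    ks <- skeletonLandmarks(mask)
    ks$points <- .topK(ks$points, config$max_points)
    return(ks)
  }
  if (detectorId == "contour") {
    v <- approxContour(mask, config$dp_epsilon)
    pts <- data.frame(x = v[, 1], y = v[, 2], response = 0)
    return(structure(list(detectorId = "contour", points = .topK(pts, config$max_points)),
                     class = "KeypointSet"))
  }
  # gradient/intensity detectors operate on a bbox crop (translation-covariant)
  bb <- .maskBbox(mask)
  pad <- 8L
  r0 <- max(1L, bb$top + 1L - pad); r1 <- min(nrow(mask), bb$top + bb$h + 1L + pad)
  c0 <- max(1L, bb$left + 1L - pad); c1 <- min(ncol(mask), bb$left + bb$w + 1L + pad)
  img <- .gblur(mask[r0:r1, c0:c1, drop = FALSE] / 255, config$blur_sigma)
  pts <- switch(detectorId,
    harris = {
      R <- harrisResponse(img, config$harris_k, config$harris_window)
      .localMaxima(R, config$response_frac * max(R, 0))
    },
    shi_tomasi = {
      R <- .shiTomasiResponse(img, config$harris_window)
      .localMaxima(R, config$response_frac * max(R, 0))
    },
    orb = {
      fc <- .fastCorners(img, config$fast_threshold)
      if (nrow(fc) > 0) {  # ORB convention: rank FAST corners by Harris response
        R <- harrisResponse(img, config$harris_k, config$harris_window)
        fc[, "response"] <- R[cbind(fc[, "y"] + 1, fc[, "x"] + 1)]
      }
      fc
    },
    brisk = {
      out <- NULL
      for (sc in c(1, 1.5, 2)) {
        sm <- if (sc == 1) img else {
          d <- pmax(3L, round(dim(img) / sc))
          .resizeBilinearSmall(img, d[1], d[2])
        }
        fc <- .fastCorners(sm, config$fast_threshold)
        if (nrow(fc) > 0)
          out <- rbind(out, cbind(x = round(fc[, "x"] * sc), y = round(fc[, "y"] * sc),
                                  response = fc[, "response"]))
      }
      if (is.null(out)) cbind(x = numeric(0), y = numeric(0), response = numeric(0)) else out
    },
    sift = .dogExtrema(img),
    akaze = .diffusionHessianExtrema(img))
  pts <- as.data.frame(pts)
  if (nrow(pts) > 0) {
    pts$x <- pts$x + (c0 - 1L)
    pts$y <- pts$y + (r0 - 1L)
    # merge duplicate coordinates (multi-scale detectors), keep max response
    key <- paste(pts$x, pts$y)
    pts <- pts[order(key, -pts$response), , drop = FALSE]
    pts <- pts[!duplicated(paste(pts$x, pts$y)), , drop = FALSE]
  }
  structure(list(detectorId = detectorId, points = .topK(pts, config$max_points)),
            class = "KeypointSet")
}

# Keep top-K by response (ties by (y, x)), then order by (y, x).
.topK <- function(pts, K) {
  if (nrow(pts) > K) {
    ord <- order(-pts$response, pts$y, pts$x)
    pts <- pts[ord[seq_len(K)], , drop = FALSE]
  }
  pts <- pts[order(pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Fixed-length encoding of keypoint sets
#'
#' Per detector block: coordinates normalized to [0, 1] by the silhouette
#' bounding box, top-K by response, (y, x)-sorted, laid out as (x, y) pairs
#' and padded with -1 to 2K entries; blocks are concatenated in the fixed
#' detector order of the bank.
#'
#' @param sets list of KeypointSet objects (any subset of the bank).
#' @param bbox list(top, left, h, w) with h, w positive spans in pixels.
#' @param K points per detector block.
#' @return Numeric vector of length 2 * K * length(sets).
#' @export
encodeKeypoints <- function(sets, bbox, K) {
  if (bbox$h <= 0 || bbox$w <= 0)
    stop("bounding box must have positive area", call. = FALSE)
  ord <- order(match(vapply(sets, `[[`, "", "detectorId"), .detectorIds()))
  out <- numeric(0)
  for (s in sets[ord]) {
    pts <- .topK(s$points, K)
    block <- rep(-1, 2 * K)
    if (nrow(pts) > 0) {
      xs <- pmin(1, pmax(0, (pts$x - bbox$left) / bbox$w))
      ys <- pmin(1, pmax(0, (pts$y - bbox$top) / bbox$h))
      block[seq_len(2 * nrow(pts))] <- as.vector(rbind(xs, ys))
    }
    out <- c(out, block)
  }
  out
}

#' Silhouette bounding box
#'
#' @param mask binary mask (0/255) with at least one foreground pixel.
#' @return list(top, left, h, w) in 0-based pixel coordinates; h and w are
#'   the row/column spans (bottom - top, right - left).
#' @export
maskBbox <- function(mask) {
  bb <- .maskBbox(mask)
  list(top = bb$top, left = bb$left, h = bb$h, w = bb$w)
}
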