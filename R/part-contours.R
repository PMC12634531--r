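# Body-part label maps and colour-guided per-part contour point sampling.
# The bundled part taxonomy has 8 coarse groups in fixed encoding order:
# head, torso, left/right arm, left/right leg, left/right foot.

.partOrder <- function() {
  c("head", "torso", "arm_l", "arm_r", "leg_l", "leg_r", "foot_l", "foot_r")
}

#' Bundled body-part taxonomy
#' @return Character vector of the 8 part names in fixed encoding order;
#'   part ids in label maps are 1..8 in this order (0 = background).
#' @export
partOrder <- function() .partOrder()

#' Part-parsing backends
#'
#' Same pluggable contract as person segmentation, over N = 9 classes
#' (background + 8 parts). \code{partsBackend} builds the bundled synthetic
#' backend returning one-hot scores from a reference part-label map
#' (nearest-neighbour aligned to the requested size).
#'
#' @param labelMap integer matrix of part ids (0 = background, 1..8 parts).
#' @return A "SegmentationBackend" whose scores have 9 slices.
#' @export
partsBackend <- function(labelMap) {
  ref <- labelMap
  scoreFun <- function(image) {
    d <- dim(image$values)[1:2]
    Hs <- nrow(ref); Ws <- ncol(ref)
    ry <- floor((0:(d[1] - 1)) * Hs / d[1]) + 1
    rx <- floor((0:(d[2] - 1)) * Ws / d[2]) + 1
    al <- ref[ry, rx, drop = FALSE]
    sc <- array(0, c(d[1], d[2], 9))
    for (p in 0:8) sc[, , p + 1] <- (al == p) * 1
    sc
  }
  structure(list(scores = scoreFun, personClass = NA_integer_, nClasses = 9L),
            class = "SegmentationBackend")
}

#' Per-pixel part parsing by argmax
#'
#' Applies a part-parsing backend and assigns each pixel the class of
#' highest score, ties toward the lowest class index. Class ids are
#' 0-based (0 = background).
#'
#' @param image a NormalizedImage (see \code{\link{preprocessRgb}}).
#' @param backend a part-parsing SegmentationBackend.
#' @return list(labels = integer H x W part-id matrix, nParts = class count
#'   excluding background, partNames = \code{\link{partOrder}}).
#' @export
parseParts <- function(image, backend) {
  labels <- segmentPerson(image, backend)
  list(labels = labels, nParts = 8L, partNames = .partOrder())
}

#' Equal-arc-length contour points of one body part
#'
#' Isolates the part's binary mask, traces the outer boundary of its
#' largest component (Moore neighbour tracing, clockwise, starting at the
#' topmost-then-leftmost boundary pixel) and samples \code{n} points at
#' equal arc-length steps. A part absent from the map yields an empty
#' result; if \code{n} exceeds the boundary length, boundary points repeat.
#'
#' @param labels integer part-id matrix (0 = background).
#' @param partId part id (1-based).
#' @param n number of points (>= 1).
#' @return n x 2 matrix of (x, y) boundary points, or a 0 x 2 matrix.
#' @export
partContourPoints <- function(labels, partId, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  mask <- (labels == partId) * 255
  if (!any(mask > 0)) return(cbind(x = numeric(0), y = numeric(0)))
  pts <- .traceBoundary(mask)
  m <- nrow(pts)
  if (m == 1) return(pts[rep(1, n), , drop = FALSE])
  # cumulative Euclidean arc length along the closed boundary
  dxy <- diff(rbind(pts, pts[1, , drop = FALSE]))
  step <- sqrt(rowSums(dxy^2))
  s <- c(0, cumsum(step))        # s[i] = arc position of vertex i; s[m+1] = total
  total <- s[m + 1]
  targets <- (0:(n - 1)) * total / n
  idx <- vapply(targets, function(tg) which.min(abs(s[seq_len(m)] - tg)), integer(1))
  pts[idx, , drop = FALSE]
}

#' Sample contours for all parts of a label map
#'
#' @param labels integer part-id matrix.
#' @param n points per part.
#' @return A "PartContourSet": list(points = named list of n x 2 matrices
#'   in \code{\link{partOrder}} order, pointsPerPart = n).
#' @export
partContourSet <- function(labels, n = 16L) {
  pts <- lapply(seq_along(.partOrder()), function(p) partContourPoints(labels, p, n))
  names(pts) <- .partOrder()
  structure(list(points = pts, pointsPerPart = as.integer(n)),
            class = "PartContourSet")
}

#' Fixed-length encoding of part contours
#'
#' Per part, n (x, y) pairs normalized to [0, 1] by the silhouette bounding
#' box; parts absent from the frame are padded with -1. Parts are
#' concatenated in the fixed \code{\link{partOrder}}; total length is
#' 2 * n * 8.
#'
#' @param contours a PartContourSet.
#' @param bbox list(top, left, h, w) with positive spans.
#' @return Numeric vector of length 2 * pointsPerPart * 8.
#' @export
encodeParts <- function(contours, bbox) {
  if (bbox$h <= 0 || bbox$w <= 0)
    stop("bounding box must have positive area", call. = FALSE)
  n <- contours$pointsPerPart
  out <- numeric(0)
  for (nm in .partOrder()) {
    p <- contours$points[[nm]]
    block <- rep(-1, 2 * n)
    if (nrow(p) > 0) {
      xs <- pmin(1, pmax(0, (p[, 1] - bbox$left) / bbox$w))
      ys <- pmin(1, pmax(0, (p[, 2] - bbox$top) / bbox$h))
      block <- as.vector(rbind(xs, ys))
    }
    out <- c(out, block)
  }
  out
}
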