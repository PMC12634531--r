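# RGB-stream silhouette extraction: normalization, a pluggable person
# segmentation contract, largest-connected-component selection,
# morphological refinement, and application of the mask to the frame.
#
# Class labels in label maps are 0-based (label = score-slice index - 1),
# matching the package-wide 0-based pixel convention.

#' Normalize an RGB frame for a segmentation backend
#'
#' Resizes to the backend input size with bilinear interpolation, scales
#' intensities to [0, 1], then standardizes per channel: (I - mu) / sigma.
#'
#' @param frame H x W x 3 numeric array with intensities in 0..255, or an
#'   H x W matrix (replicated to 3 channels).
#' @param mean,std per-channel normalization statistics (length 1 or 3);
#'   all std components must be > 0.
#' @param targetSize integer (H', W') backend input size; defaults to the
#'   source size.
#' @param colorOrder "RGB" or "BGR"; BGR input is converted to RGB.
#' @return A "NormalizedImage": list(values = H' x W' x 3 array,
#'   mean, std, sourceSize).
#' @export
#' @examples
#' img <- array(runif(12 * 10 * 3, 0, 255), c(12, 10, 3))
#' str(preprocessRgb(img, mean = 0.5, std = 0.25), max.level = 1)
preprocessRgb <- function(frame, mean = c(0, 0, 0), std = c(1, 1, 1),
                          targetSize = NULL, colorOrder = "RGB") {
  if (is.matrix(frame)) frame <- array(rep(frame, 3), c(dim(frame), 3))
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  if (any(std <= 0)) stop("std components must be > 0", call. = FALSE)
  mean <- rep_len(mean, 3); std <- rep_len(std, 3)
  if (identical(toupper(colorOrder), "BGR")) frame <- frame[, , 3:1, drop = FALSE]
  src <- dim(frame)[1:2]
  if (is.null(targetSize)) targetSize <- src
  out <- array(0, c(targetSize[1], targetSize[2], 3))
  for (ch in 1:3) {
    m <- frame[, , ch] / 255
    if (!all(targetSize == src))
      m <- matrix(as.numeric(EBImage::resize(m, w = targetSize[1], h = targetSize[2],
                                             filter = "bilinear")),
                  targetSize[1], targetSize[2])
    out[, , ch] <- (m - mean[ch]) / std[ch]
  }
  structure(list(values = out, mean = mean, std = std, sourceSize = src),
            class = "NormalizedImage")
}

#' Segmentation backends
#'
#' A segmentation backend is the pluggable contract standing in for a dense
#' segmentation network: a function mapping a NormalizedImage to per-pixel
#' class scores (H' x W' x N array) together with the 0-based index of the
#' person class.
#'
#' \code{thresholdBackend} builds the bundled synthetic backend: person
#' score 1 where a reference mask (resized by nearest neighbour) is set,
#' background score 1 elsewhere. \code{scoreBackend} wraps an arbitrary
#' scoring function (e.g. an adapter around an external network) into the
#' same contract.
#'
#' @param mask reference binary mask (values 0/255) for the threshold
#'   backend, at any resolution.
#' @param scoreFun function(NormalizedImage) returning an H' x W' x N score
#'   array.
#' @param personClass 0-based index of the person class.
#' @return A "SegmentationBackend": list(scores = function, personClass,
#'   nClasses).
#' @export
#' @examples
#' m <- matrix(0, 8, 8); m[3:6, 3:6] <- 255
#' be <- thresholdBackend(m)
#' be$personClass
thresholdBackend <- function(mask) {
  .assertMask(mask)
  ref <- mask
  scoreFun <- function(image) {
    d <- dim(image$values)[1:2]
    al <- .alignMaskNn(ref, d)
    sc <- array(0, c(d[1], d[2], 2))
    sc[, , 1] <- (al == 0) * 1
    sc[, , 2] <- (al > 0) * 1
    sc
  }
  structure(list(scores = scoreFun, personClass = 1L, nClasses = 2L),
            class = "SegmentationBackend")
}

#' @rdname thresholdBackend
#' @export
scoreBackend <- function(scoreFun, personClass) {
  structure(list(scores = scoreFun, personClass = as.integer(personClass),
                 nClasses = NA_integer_),
            class = "SegmentationBackend")
}

# Nearest-neighbour mask alignment with floor indexing: the output pixel
# (x, y) of size (H, W) reads source pixel (floor(x*W'/W), floor(y*H'/H)).
.alignMaskNn <- function(mask, size) {
  Hs <- nrow(mask); Ws <- ncol(mask)
  H <- size[1]; W <- size[2]
  ry <- floor((0:(H - 1)) * Hs / H) + 1
  rx <- floor((0:(W - 1)) * Ws / W) + 1
  mask[ry, rx, drop = FALSE]
}

#' Per-pixel argmax person segmentation
#'
#' Applies the backend's scoring function and assigns each pixel the class
#' of highest score; ties break toward the lowest class index. Labels are
#' 0-based.
#'
#' @param image a NormalizedImage from \code{\link{preprocessRgb}}.
#' @param backend a SegmentationBackend.
#' @return Integer H' x W' label map (0-based class ids).
#' @export
segmentPerson <- function(image, backend) {
  sc <- backend$scores(image)
  if (!all(is.finite(sc))) stop("backend produced non-finite scores", call. = FALSE)
  d <- dim(sc)
  flat <- matrix(sc, d[1] * d[2], d[3])
  # ties.method = "first" realizes the lowest-class-index tie rule
  lab <- max.col(flat, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Largest person-labelled connected component
#'
#' Retains exactly the largest 8-connected component of pixels carrying the
#' person class; ties break by the smallest top-left bounding-box corner in
#' row-major order.
#'
#' @param labels integer label map (0-based class ids).
#' @param personClass 0-based person class id.
#' @return Binary mask (0/255) of the retained component.
#' @export
largestComponentMask <- function(labels, personClass) {
  person <- (labels == personClass) * 255
  if (!any(person > 0)) stop("no person detected", call. = FALSE)
  lab <- .labelComponents8(person)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # row-major top-left bounding-box corner
    corner <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      top <- min(idx[, 1]); left <- min(idx[idx[, 1] == top, 2])
      (top - 1) * ncol(lab) + (left - 1)
    }, numeric(1))
    best <- best[which.min(corner)]
  }
  (lab == best) * 255
}

#' Morphological mask refinement
#'
#' Opening followed by closing with a 5 x 5 square structuring element,
#' removing small artifacts and filling small holes.
#'
#' @param mask binary mask (0/255).
#' @return Refined binary mask (0/255).
#' @export
refineMask <- function(mask) {
  .assertMask(mask)
  k <- EBImage::makeBrush(5, shape = "box")
  bin <- (mask > 0) * 1
  out <- EBImage::closing(EBImage::opening(bin, k), k)
  matrix(as.numeric(out), nrow(mask), ncol(mask)) * 255
}

#' Align a mask to a frame and apply it
#'
#' Resizes the mask to the frame size by nearest-neighbour interpolation
#' with floor indexing, then keeps frame pixels where the mask is 255 and
#' zeroes all others.
#'
#' @param mask binary mask (0/255), any size.
#' @param frame H x W x 3 array or H x W matrix.
#' @return The silhouette frame (same shape as \code{frame}).
#' @export
alignAndApply <- function(mask, frame) {
  .assertMask(mask)
  d <- if (is.matrix(frame)) dim(frame) else dim(frame)[1:2]
  al <- .alignMaskNn(mask, d)
  if (is.matrix(frame)) {
    frame[al != 255] <- 0
    frame
  } else {
    for (ch in seq_len(dim(frame)[3])) {
      sl <- frame[, , ch]; sl[al != 255] <- 0; frame[, , ch] <- sl
    }
    frame
  }
}

# Full mask chain shared by the RGB and depth streams: scores -> argmax ->
# largest component -> morphology.
.silhouetteChain <- function(image, backend) {
  lab <- segmentPerson(image, backend)
  refineMask(largestComponentMask(lab, backend$personClass))
}
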