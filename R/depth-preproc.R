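# Depth-stream preprocessing: RANSAC floor-plane fitting and removal,
# min-max normalization to 8 bits, CLAHE contrast enhancement, replication
# to three channels, edge-preserving bilateral filtering, and depth-based
# person segmentation. Depth frames are matrices in millimetres with 0
# marking invalid range.

#' Depth preprocessing configuration
#'
#' All values the floor-removal and enhancement stages need, with the
#' package defaults: 15 mm inlier threshold, 100 RANSAC iterations on
#' 3-point samples, CLAHE clip 2.0 on an 8 x 8 tile grid, bilateral filter
#' of diameter 9 with spatial and range sigmas 75.
#'
#' @param ransac_iters number of random 3-point hypotheses.
#' @param ransac_sample_size minimal sample size (3 for a plane).
#' @param epsilon floor inlier/removal threshold in mm.
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid size.
#' @param bilateral_diameter,bilateral_sigma_space,bilateral_sigma_range
#'   bilateral filter window diameter (px) and Gaussian sigmas (px /
#'   intensity levels).
#' @param max_candidates cap on candidate pixels scored per RANSAC
#'   hypothesis (deterministic stride subsample; the final least-squares
#'   refit uses all inliers).
#' @param candidate_frac fraction of bottom image rows searched for floor
#'   candidates when no candidate mask is supplied.
#' @param seed integer seed for the RANSAC sampler.
#' @return Named list of settings.
#' @export
depthPreprocConfig <- function(ransac_iters = 100L, ransac_sample_size = 3L,
                               epsilon = 15, clahe_clip = 2, clahe_tiles = 8L,
                               bilateral_diameter = 9L, bilateral_sigma_space = 75,
                               bilateral_sigma_range = 75, max_candidates = 4000L,
                               candidate_frac = 0.4, seed = 1L) {
  stopifnot(ransac_iters > 0, ransac_sample_size == 3L, epsilon > 0,
            clahe_clip > 0, clahe_tiles > 0, bilateral_diameter > 0,
            bilateral_sigma_space > 0, bilateral_sigma_range > 0)
  list(ransac_iters = as.integer(ransac_iters), ransac_sample_size = 3L,
       epsilon = epsilon, clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
       bilateral_diameter = as.integer(bilateral_diameter),
       bilateral_sigma_space = bilateral_sigma_space,
       bilateral_sigma_range = bilateral_sigma_range,
       max_candidates = as.integer(max_candidates),
       candidate_frac = candidate_frac, seed = as.integer(seed))
}

#' Fit the floor plane of a depth frame by RANSAC
#'
#' Fits z = a*x + b*y + c (x, y 0-based pixel coordinates, z mm) to
#' candidate floor pixels: valid pixels (z > 0) of the candidate mask, or
#' of the bottom \code{candidate_frac} image rows when no mask is given.
#' The best of \code{ransac_iters} seeded random 3-point hypotheses by
#' inlier count (ties by lower mean inlier residual) is refit by least
#' squares on its inliers.
#'
#' @param depth depth matrix (mm, 0 invalid).
#' @param candidateMask optional binary mask (0/255) of candidate pixels.
#' @param cfg a \code{\link{depthPreprocConfig}}.
#' @return A \linkS4class{FloorModel}.
#' @export
fitFloorRansac <- function(depth, candidateMask = NULL, cfg = depthPreprocConfig()) {
  H <- nrow(depth); W <- ncol(depth)
  cand <- depth > 0
  if (!is.null(candidateMask)) {
    .assertMask(candidateMask)
    cand <- cand & candidateMask > 0
  } else {
    rows <- matrix(seq_len(H), H, W)
    cand <- cand & rows > (1 - cfg$candidate_frac) * H
  }
  idx <- which(cand)
  if (length(idx) < 3) stop("need at least 3 valid candidate points", call. = FALSE)
  xs <- ((idx - 1) %/% H)          # 0-based column
  ys <- ((idx - 1) %% H)           # 0-based row
  zs <- depth[idx]
  # deterministic stride subsample for hypothesis scoring
  sidx <- if (length(idx) > cfg$max_candidates)
    seq(1L, length(idx), length.out = cfg$max_candidates) else seq_along(idx)
  sxs <- xs[sidx]; sys <- ys[sidx]; szs <- zs[sidx]
  samples <- .withSeed(cfg$seed,
    replicate(cfg$ransac_iters, sample.int(length(idx), 3L)))
  best <- NULL
  for (it in seq_len(cfg$ransac_iters)) {
    s <- samples[, it]
    A <- cbind(xs[s], ys[s], 1)
    if (abs(det(A)) < 1e-9) next   # collinear sample
    coef <- solve(A, zs[s])
    res <- abs(szs - (coef[1] * sxs + coef[2] * sys + coef[3]))
    inl <- res < cfg$epsilon
    ninl <- sum(inl)
    mres <- if (ninl > 0) mean(res[inl]) else Inf
    if (is.null(best) || ninl > best$n || (ninl == best$n && mres < best$mres))
      best <- list(coef = coef, n = ninl, mres = mres)
  }
  if (is.null(best)) stop("all RANSAC samples were degenerate", call. = FALSE)
  # least-squares refit on all inliers of the winning hypothesis
  res <- abs(zs - (best$coef[1] * xs + best$coef[2] * ys + best$coef[3]))
  inl <- res < cfg$epsilon
  if (sum(inl) >= 3) {
    A <- cbind(xs[inl], ys[inl], 1)
    best$coef <- as.numeric(qr.solve(A, zs[inl]))
    res <- abs(zs - (best$coef[1] * xs + best$coef[2] * ys + best$coef[3]))
    inl <- res < cfg$epsilon
  }
  new("FloorModel", a = best$coef[1], b = best$coef[2], c = best$coef[3],
      epsilon = cfg$epsilon, inlierCount = as.integer(sum(inl)))
}

#' Remove floor pixels by plane residual
#'
#' Zeroes every pixel whose residual |z - (a*x + b*y + c)| is strictly
#' below the model's epsilon; all other pixels (including a residual of
#' exactly epsilon) are unchanged.
#'
#' @param depth depth matrix (mm).
#' @param model a \linkS4class{FloorModel}.
#' @return The floor-removed depth matrix.
#' @export
removeFloor <- function(depth, model) {
  H <- nrow(depth); W <- ncol(depth)
  xg <- matrix(rep(0:(W - 1), each = H), H)
  yg <- matrix(rep(0:(H - 1), times = W), H)
  res <- abs(depth - (model@a * xg + model@b * yg + model@c))
  depth[res < model@epsilon] <- 0
  depth
}

#' Min-max normalization of a depth frame to 8 bits
#'
#' (z - min) / (max - min) * 255 with min/max over valid pixels only;
#' invalid pixels (z = 0) map to 0; values are rounded half-up to the
#' nearest integer. A constant valid depth maps to 0 with a warning.
#'
#' @param depth depth matrix (mm, 0 invalid) with at least one valid pixel.
#' @return Integer matrix with values in 0..255.
#' @export
normalizeMinMax <- function(depth) {
  valid <- depth > 0
  if (!any(valid)) stop("no valid depth pixels to normalize", call. = FALSE)
  lo <- min(depth[valid]); hi <- max(depth[valid])
  out <- matrix(0L, nrow(depth), ncol(depth))
  if (hi == lo) {
    warning("constant valid depth; normalized image is all zero")
    return(out)
  }
  out[valid] <- as.integer(floor((depth[valid] - lo) / (hi - lo) * 255 + 0.5))
  out
}

# Edge-preserving bilateral filter on one channel (intensities 0..255).
.bilateral <- function(m, d, sigmaSpace, sigmaRange) {
  r <- d %/% 2
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  for (dy in -r:r) for (dx in -r:r) {
    gs <- exp(-(dy * dy + dx * dx) / (2 * sigmaSpace^2))
    sh <- .shiftMat(m, dy, dx, NA)
    gr <- exp(-((sh - m)^2) / (2 * sigmaRange^2))
    wgt <- gs * gr
    wgt[is.na(sh)] <- 0
    sh[is.na(sh)] <- 0
    num <- num + wgt * sh
    den <- den + wgt
  }
  num / pmax(den, .Machine$double.eps)
}

#' Contrast enhancement and 3-channel filtering of a normalized depth image
#'
#' CLAHE (clip limit and tile grid from the configuration), replication of
#' the single channel across three channels, and bilateral filtering with
#' the configured spatial/range sigmas.
#'
#' @param image single-channel integer image (0..255), e.g. from
#'   \code{\link{normalizeMinMax}}.
#' @param cfg a \code{\link{depthPreprocConfig}}.
#' @return H x W x 3 numeric array (0..255), channels identical.
#' @export
enhanceDepth <- function(image, cfg = depthPreprocConfig()) {
  if (!is.matrix(image)) stop("enhanceDepth expects a single-channel matrix", call. = FALSE)
  u <- image / 255
  if (stats::var(as.vector(u)) > 0) {
    nx <- min(cfg$clahe_tiles, max(2L, nrow(u) %/% 8L))
    ny <- min(cfg$clahe_tiles, max(2L, ncol(u) %/% 8L))
    u <- matrix(as.numeric(EBImage::clahe(u, nx = nx, ny = ny,
                                          limit = cfg$clahe_clip)),
                nrow(u), ncol(u))
  }
  ch <- .bilateral(u * 255, cfg$bilateral_diameter,
                   cfg$bilateral_sigma_space, cfg$bilateral_sigma_range)
  array(rep(ch, 3), c(dim(ch), 3))
}

#' Person segmentation on an enhanced depth image
#'
#' Resizes the 3-channel image to 256 x 256, scores it with the backend,
#' takes the per-pixel argmax, retains the largest 8-connected person
#' component with morphological refinement (the silhouette-stream chain),
#' and resizes the mask back to the source resolution.
#'
#' @param image H x W x 3 array (e.g. from \code{\link{enhanceDepth}}).
#' @param backend a SegmentationBackend.
#' @return Binary mask (0/255) at the source resolution.
#' @export
segmentDepth <- function(image, backend, inputSize = 256L) {
  src <- dim(image)[1:2]
  # the three channels are identical by construction; resize once
  ch <- if (length(dim(image)) == 3) image[, , 1] else image
  rs <- .resizeBilinearSmall(ch / 255, inputSize, inputSize)
  ni <- structure(list(values = array(rep(rs, 3), c(dim(rs), 3)),
                       mean = c(0, 0, 0), std = c(1, 1, 1), sourceSize = src),
                  class = "NormalizedImage")
  mask <- .silhouetteChain(ni, backend)
  if (!any(mask > 0)) stop("no person detected", call. = FALSE)
  out <- (.alignMaskNn(mask, src) > 0) * 255
  if (!any(out > 0)) stop("no person detected", call. = FALSE)
  # resampling to the source grid can fragment thin structures; keep the
  # largest component so the mask stays a single connected region
  lab <- .labelComponents8(out)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 255
}
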