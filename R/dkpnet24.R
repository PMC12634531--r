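# Rule-based dynamic 24-point keypoint extraction from binary silhouettes:
# arm-pose mode selection, the lowered-arm (L) and raised-arm (R) scan
# pipelines, and lifting to 3D with a floor-removed depth frame.
#
# All row/column arithmetic is in 0-based image coordinates with floor
# integer division; h is the silhouette row span (bottom - top).

#' Mode-selection configuration
#' @param raised_width_ratio silhouette-width threshold above the neck row
#'   relative to the estimated head width (> 1).
#' @return Named list.
#' @export
modeConfig <- function(raised_width_ratio = 1.8) {
  stopifnot(raised_width_ratio > 1)
  list(raised_width_ratio = raised_width_ratio)
}

# silhouette row extent helpers: first/last/width of foreground in a row.
.rowRange <- function(mask, row0) {
  r <- mask[row0 + 1, ]
  nz <- which(r > 0)
  if (length(nz) == 0) return(NULL)
  c(min(nz) - 1L, max(nz) - 1L)
}

#' Select the arm-pose pipeline
#'
#' RAISED iff the maximum silhouette row span over the rows above the
#' provisional neck row (top + h/8) exceeds \code{raised_width_ratio}
#' times the head width, estimated as the foreground pixel count of the
#' row top + h/16 (the count, unlike the span, stays head-sized when the
#' silhouette top is formed by raised hands flanking empty background);
#' otherwise LOWERED.
#'
#' @param mask binary silhouette (0/255), non-empty.
#' @param cfg a \code{\link{modeConfig}}.
#' @return "LOWERED" or "RAISED".
#' @export
selectMode <- function(mask, cfg = modeConfig()) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot select a mode for an empty mask", call. = FALSE)
  bb <- .maskBbox(mask)
  h <- bb$h
  neckRow <- bb$top + h %/% 8L
  headRow <- bb$top + h %/% 16L
  headWidth <- max(1L, sum(mask[headRow + 1L, ] > 0))
  rows <- bb$top:max(bb$top, neckRow - 1L)
  widths <- vapply(rows, function(r) {
    rr <- .rowRange(mask, r)
    if (is.null(rr)) 0L else rr[2] - rr[1]
  }, integer(1))
  if (max(widths) > cfg$raised_width_ratio * headWidth) "RAISED" else "LOWERED"
}

# min/max silhouette x over a 0-based row band [r0, r1]; errors with the
# joint name when the band is empty. Returns c(minx, maxx, rowOfMin, rowOfMax)
# where the rows are the median rows attaining each extreme.
.bandExtremes <- function(mask, r0, r1, joint) {
  r0 <- max(0L, min(nrow(mask) - 1L, r0)); r1 <- max(0L, min(nrow(mask) - 1L, r1))
  if (r1 < r0) { tmp <- r0; r0 <- r1; r1 <- tmp }
  sub <- mask[(r0:r1) + 1L, , drop = FALSE]
  nz <- which(sub > 0, arr.ind = TRUE)
  if (nrow(nz) == 0)
    stop("empty silhouette scan range for joint '", joint, "'", call. = FALSE)
  minx <- min(nz[, 2]) - 1L; maxx <- max(nz[, 2]) - 1L
  rmin <- stats::median(nz[nz[, 2] == minx + 1L, 1]) + r0 - 1L
  rmax <- stats::median(nz[nz[, 2] == maxx + 1L, 1]) + r0 - 1L
  c(minx, maxx, floor(rmin), floor(rmax))
}

#' Lowered-arm 24-point extraction
#'
#' The lowered-arm scan pipeline: head at (width/2, top); neck at
#' top + h/8 with x re-centred between the shoulder estimates; shoulders
#' at the neck-row silhouette extremes inset by 5 px; collarbones 15 px
#' inward of the shoulders; hips as the silhouette extremes over rows
#' top + [3h/5, 2h/3]; pelvis/spine/spine-upper/spine-lower as the stated
#' midpoints; elbows and wrists as band extremes between neck/spine and
#' spine/pelvis rows; ankles at the bottom-row extremes and heels h/40
#' above them. The four schema joints the lowered-arm table omits are
#' synthesized: knees as the row-3h/4 extremes inset by 7 px (the
#' raised-arm rule) and hands as the wrists offset down by h/40.
#'
#' @param mask binary silhouette (0/255), non-empty.
#' @return 24 x 2 matrix of (x, y) in \code{\link{jointNames24}} order.
#' @export
extractLowered <- function(mask) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot extract keypoints from an empty mask", call. = FALSE)
  W <- ncol(mask)
  bb <- .maskBbox(mask)
  top <- bb$top; h <- bb$h; bottom <- top + h
  headX <- W %/% 2L; headY <- top
  neckY <- headY + h %/% 8L
  nr <- .rowRange(mask, neckY)
  if (is.null(nr)) stop("empty silhouette scan range for joint 'neck'", call. = FALSE)
  shoulderLX <- nr[1] + 5L; shoulderRX <- nr[2] - 5L
  neckX <- (shoulderLX + shoulderRX) %/% 2L
  collarLX <- shoulderLX + 15L; collarRX <- shoulderRX - 15L
  hipStart <- top + (3L * h) %/% 5L; hipEnd <- top + (2L * h) %/% 3L
  hips <- .bandExtremes(mask, hipStart, hipEnd, "hip")
  pelvisX <- (hips[1] + hips[2]) %/% 2L
  pelvisY <- (hipStart + hipEnd) %/% 2L
  spineX <- (neckX + pelvisX) %/% 2L; spineY <- (neckY + pelvisY) %/% 2L
  spineUpX <- (neckX + spineX) %/% 2L; spineUpY <- (neckY + spineY) %/% 2L
  spineLoX <- (pelvisX + spineX) %/% 2L; spineLoY <- (pelvisY + spineY) %/% 2L
  elbows <- .bandExtremes(mask, neckY, spineY, "elbow")
  wrists <- .bandExtremes(mask, spineY, pelvisY, "wrist")
  ankles <- .bandExtremes(mask, bottom, bottom, "ankle")
  heelY <- bottom - h %/% 40L
  kneeRow <- top + (3L * h) %/% 4L
  knees <- .bandExtremes(mask, kneeRow, kneeRow, "knee")
  wristY <- c(wrists[3], wrists[4])
  kp <- rbind(
    pelvis = c(pelvisX, pelvisY),
    hip_l = c(hips[1], pelvisY), hip_r = c(hips[2], pelvisY),
    spine1 = c(spineLoX, spineLoY),
    knee_l = c(knees[1] + 7L, kneeRow), knee_r = c(knees[2] - 7L, kneeRow),
    spine2 = c(spineX, spineY),
    ankle_l = c(ankles[1], bottom), ankle_r = c(ankles[2], bottom),
    spine3 = c(spineUpX, spineUpY),
    foot_l = c(ankles[1], heelY), foot_r = c(ankles[2], heelY),
    neck = c(neckX, neckY),
    collar_l = c(collarLX, neckY), collar_r = c(collarRX, neckY),
    head = c(headX, headY),
    shoulder_l = c(shoulderLX, neckY), shoulder_r = c(shoulderRX, neckY),
    elbow_l = c(elbows[1], elbows[3]), elbow_r = c(elbows[2], elbows[4]),
    wrist_l = c(wrists[1], wrists[3]), wrist_r = c(wrists[2], wrists[4]),
    hand_l = c(wrists[1], wristY[1] + h %/% 40L),
    hand_r = c(wrists[2], wristY[2] + h %/% 40L))
  colnames(kp) <- c("x", "y")
  .clampKp(kp, mask)
}

# fixed-offset rules can leave the frame on degraded silhouettes; emitted
# keypoints are clamped to the image
.clampKp <- function(kp, mask) {
  kp[, 1] <- pmin(pmax(kp[, 1], 0L), ncol(mask) - 1L)
  kp[, 2] <- pmin(pmax(kp[, 2], 0L), nrow(mask) - 1L)
  kp
}

#' Raised-arm 24-point extraction
#'
#' The raised-arm scan pipeline: hips/pelvis as in the lowered-arm case;
#' head as the first non-zero row of the central body column (x = pelvis
#' x) above the hip band; neck at head + h/12; shoulders at the neck-row
#' extremes inset by 5 px and collarbones 15 px inward; hands at the
#' extreme non-zero silhouette columns (with the topmost row of each
#' column); wrists 10 px below the hands; elbows as band extremes between
#' the neck and spine rows; knees at row 3h/4 inset by 7 px; ankles at the
#' bottom-row extremes and heels h/30 above; spine-lower (absent from the
#' raised-arm table) as the spine/pelvis midpoint.
#'
#' @param mask binary silhouette (0/255), non-empty.
#' @return 24 x 2 matrix of (x, y) in \code{\link{jointNames24}} order.
#' @export
extractRaised <- function(mask) {
  .assertMask(mask)
  if (!any(mask > 0)) stop("cannot extract keypoints from an empty mask", call. = FALSE)
  bb <- .maskBbox(mask)
  top <- bb$top; h <- bb$h; bottom <- top + h
  hipStart <- top + (3L * h) %/% 5L; hipEnd <- top + (2L * h) %/% 3L
  hips <- .bandExtremes(mask, hipStart, hipEnd, "hip")
  pelvisX <- (hips[1] + hips[2]) %/% 2L
  pelvisY <- (hipStart + hipEnd) %/% 2L
  # head: first non-zero row of the central body column above the hip band
  col <- mask[, pelvisX + 1L]
  nzc <- which(col > 0) - 1L
  nzc <- nzc[nzc <= hipStart]
  if (length(nzc) == 0) stop("empty silhouette scan range for joint 'head'", call. = FALSE)
  headY <- min(nzc); headX <- pelvisX
  neckY <- headY + h %/% 12L; neckX <- headX
  nr <- .rowRange(mask, neckY)
  if (is.null(nr)) stop("empty silhouette scan range for joint 'shoulder'", call. = FALSE)
  shoulderLX <- nr[1] + 5L; shoulderRX <- nr[2] - 5L
  collarLX <- shoulderLX + 15L; collarRX <- shoulderRX - 15L
  # hands: extreme non-zero columns of the whole silhouette
  colsAny <- which(apply(mask > 0, 2, any)) - 1L
  handLX <- min(colsAny); handRX <- max(colsAny)
  handLY <- min(which(mask[, handLX + 1L] > 0)) - 1L
  handRY <- min(which(mask[, handRX + 1L] > 0)) - 1L
  wristLY <- handLY + 10L; wristRY <- handRY + 10L
  spineX <- (neckX + pelvisX) %/% 2L; spineY <- (neckY + pelvisY) %/% 2L
  spineUpX <- (neckX + spineX) %/% 2L; spineUpY <- (neckY + spineY) %/% 2L
  spineLoX <- (pelvisX + spineX) %/% 2L; spineLoY <- (pelvisY + spineY) %/% 2L
  elbows <- .bandExtremes(mask, neckY, spineY, "elbow")
  kneeRow <- top + (3L * h) %/% 4L
  knees <- .bandExtremes(mask, kneeRow, kneeRow, "knee")
  ankles <- .bandExtremes(mask, bottom, bottom, "ankle")
  heelY <- bottom - h %/% 30L
  kp <- rbind(
    pelvis = c(pelvisX, pelvisY),
    hip_l = c(hips[1], pelvisY), hip_r = c(hips[2], pelvisY),
    spine1 = c(spineLoX, spineLoY),
    knee_l = c(knees[1] + 7L, kneeRow), knee_r = c(knees[2] - 7L, kneeRow),
    spine2 = c(spineX, spineY),
    ankle_l = c(ankles[1], bottom), ankle_r = c(ankles[2], bottom),
    spine3 = c(spineUpX, spineUpY),
    foot_l = c(ankles[1], heelY), foot_r = c(ankles[2], heelY),
    neck = c(neckX, neckY),
    collar_l = c(collarLX, neckY), collar_r = c(collarRX, neckY),
    head = c(headX, headY),
    shoulder_l = c(shoulderLX, neckY), shoulder_r = c(shoulderRX, neckY),
    elbow_l = c(elbows[1], elbows[3]), elbow_r = c(elbows[2], elbows[4]),
    wrist_l = c(handLX, wristLY), wrist_r = c(handRX, wristRY),
    hand_l = c(handLX, handLY), hand_r = c(handRX, handRY))
  colnames(kp) <- c("x", "y")
  .clampKp(kp, mask)
}

#' Lift 2D keypoints to 3D with a depth frame
#'
#' z of each keypoint is the median of the valid depth values in the 3 x 3
#' window centred on it; when the window holds no valid pixel, the depth
#' of the nearest (Euclidean) valid pixel is used.
#'
#' @param kp2d 24 x 2 keypoints (x, y).
#' @param depth floor-removed depth matrix (mm, 0 invalid).
#' @param mode arm-pose mode string stored in the result.
#' @param bbox silhouette bounding box stored in the result.
#' @return A \linkS4class{Keypoints24}.
#' @export
liftTo3d <- function(kp2d, depth, mode = "LOWERED", bbox = list(top = 0, left = 0,
                                                               h = nrow(depth) - 1,
                                                               w = ncol(depth) - 1)) {
  valid <- which(depth > 0, arr.ind = TRUE)
  if (nrow(valid) == 0) stop("depth frame holds no valid pixels", call. = FALSE)
  H <- nrow(depth); W <- ncol(depth)
  z <- vapply(seq_len(nrow(kp2d)), function(i) {
    x <- min(max(round(kp2d[i, 1]), 0), W - 1)
    y <- min(max(round(kp2d[i, 2]), 0), H - 1)
    ys <- max(0, y - 1):min(H - 1, y + 1)
    xs <- max(0, x - 1):min(W - 1, x + 1)
    win <- depth[ys + 1, xs + 1]
    v <- win[win > 0]
    if (length(v) > 0) return(stats::median(v))
    d2 <- (valid[, 1] - 1 - y)^2 + (valid[, 2] - 1 - x)^2
    depth[valid[which.min(d2), , drop = FALSE]]
  }, numeric(1))
  pts <- cbind(x = kp2d[, 1], y = kp2d[, 2], z = z)
  rownames(pts) <- jointNames24()
  new("Keypoints24", points = pts, mode = mode, silhouetteBbox = bbox)
}

#' Full dynamic 24-point extraction from a silhouette and depth frame
#'
#' Selects the arm-pose mode, runs the matching scan pipeline and lifts
#' the points to 3D.
#'
#' @param mask binary silhouette (0/255).
#' @param depth floor-removed depth matrix (mm).
#' @param cfg a \code{\link{modeConfig}}.
#' @return A \linkS4class{Keypoints24}.
#' @export
extractKeypoints24 <- function(mask, depth, cfg = modeConfig()) {
  mode <- selectMode(mask, cfg)
  kp2d <- if (mode == "RAISED") extractRaised(mask) else extractLowered(mask)
  liftTo3d(kp2d, depth, mode = mode, bbox = maskBbox(mask))
}
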