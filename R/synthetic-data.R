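# Synthetic RGB-D motion generator: a single articulated person standing on
# a planar floor, rendered as silhouette + depth + part labels with
# ground-truth joints. The rest skeleton follows standard anthropometric
# segment proportions (Drillis-Contini) for a 1750 mm stature, scaled per
# subject; the camera is orthographic at a configurable mm-per-pixel scale.

# Rest skeleton in mm, y pointing UP from the floor, x to the image right,
# z toward the camera. Rows in jointNames24() order.
.restSkeleton <- function(scale = 1750) {
  J <- matrix(c(
      0, 975, 0,     # pelvis
    -95, 928, 0,     # hip_l
     95, 928, 0,     # hip_r
      0, 1060, 0,    # spine1
   -105, 500, 0,     # knee_l
    105, 500, 0,     # knee_r
      0, 1230, 0,    # spine2
   -110,  70, 0,     # ankle_l
    110,  70, 0,     # ankle_r
      0, 1370, 0,    # spine3
   -110,  25, 0,     # foot_l
    110,  25, 0,     # foot_r
      0, 1520, 0,    # neck
    -80, 1480, 0,    # collar_l
     80, 1480, 0,    # collar_r
      0, 1630, 0,    # head
   -210, 1430, 0,    # shoulder_l
    210, 1430, 0,    # shoulder_r
   -225, 1100, 0,    # elbow_l
    225, 1100, 0,    # elbow_r
   -235, 850, 0,     # wrist_l
    235, 850, 0,     # wrist_r
   -240, 760, 0,     # hand_l
    240, 760, 0      # hand_r
  ), ncol = 3, byrow = TRUE)
  rownames(J) <- jointNames24()
  J * (scale / 1750)
}

# Capsule table: each row renders the segment between two joints (indices in
# jointNames24() order) with a radius (mm) and a body-part id
# (1 head, 2 torso, 3/4 L/R arm, 5/6 L/R leg, 7/8 L/R foot) plus a part
# depth offset (mm toward the camera). Painted in listed order.
.capsuleTable <- function() {
  nm <- jointNames24()
  j <- function(x) match(x, nm)
  cap <- function(a, b, r, part, zoff)
    data.frame(a = j(a), b = j(b), r = r, part = part, zoff = zoff)
  rbind(
    cap("pelvis", "neck", 150, 2, 0),      # torso trunk fill
    cap("pelvis", "spine1", 150, 2, 0),
    cap("spine1", "spine2", 150, 2, 0),
    cap("spine2", "spine3", 145, 2, 0),
    cap("spine3", "neck", 90, 2, 0),
    cap("pelvis", "hip_l", 95, 2, 0),
    cap("pelvis", "hip_r", 95, 2, 0),
    cap("spine3", "collar_l", 70, 2, 0),
    cap("spine3", "collar_r", 70, 2, 0),
    cap("collar_l", "shoulder_l", 60, 2, 0),
    cap("collar_r", "shoulder_r", 60, 2, 0),
    cap("hip_l", "knee_l", 75, 5, 10),
    cap("hip_r", "knee_r", 75, 6, 10),
    cap("knee_l", "ankle_l", 55, 5, 10),
    cap("knee_r", "ankle_r", 55, 6, 10),
    cap("ankle_l", "foot_l", 28, 7, 50),
    cap("ankle_r", "foot_r", 28, 8, 50),
    cap("neck", "head", 58, 1, 40),
    cap("head", "head", 120, 1, 40),       # cranial sphere
    cap("shoulder_l", "elbow_l", 48, 3, 60),
    cap("shoulder_r", "elbow_r", 48, 4, 60),
    cap("elbow_l", "wrist_l", 40, 3, 60),
    cap("elbow_r", "wrist_r", 40, 4, 60),
    cap("wrist_l", "hand_l", 38, 3, 60),
    cap("wrist_r", "hand_r", 38, 4, 60)
  )
}

.exerciseClasses <- function() {
  c("idle", "arm_raise", "lateral_bar_shift", "trunk_bend", "squat")
}

# Run expr with a temporarily fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Scene configuration for the synthetic renderer
#'
#' Defaults emulate a Kinect-v2-like depth sensor: a 424 x 512 px frame at
#' 6 mm/px (a standing adult spans roughly 290 px; raised-arm poses of the
#' tallest synthetic subject stay inside the frame), a gently sloping floor
#' plane z = 0*x + 2*y + 2400 (mm), and 5 mm of Gaussian depth noise on
#' body pixels.
#'
#' @param imageSize integer (H, W) in pixels.
#' @param floorPlane numeric (a, b, c) of z = a*x + b*y + c (mm).
#' @param cameraScale mm per pixel.
#' @param depthNoiseSd body depth noise standard deviation (mm).
#' @param seed integer seed.
#' @return A \linkS4class{SceneConfig}.
#' @export
#' @examples
#' sceneConfig()
sceneConfig <- function(imageSize = c(424L, 512L), floorPlane = c(0, 2, 2400),
                        cameraScale = 6, depthNoiseSd = 5, seed = 1L) {
  new("SceneConfig", imageSize = as.integer(imageSize),
      floorPlane = as.numeric(floorPlane), cameraScale = as.numeric(cameraScale),
      depthNoiseSd = as.numeric(depthNoiseSd), seed = as.integer(seed))
}

#' Sample an exercise pose at a given phase
#'
#' Deterministically generates the articulated pose of one of the five
#' bundled exercise classes at phase \code{t} (0 = start, 1 = end of a
#' repetition), with small anatomically bounded jitter drawn from the seed.
#'
#' Classes: \code{idle} (rest pose), \code{arm_raise} (bilateral arm
#' abduction to ~143 degrees), \code{lateral_bar_shift} (arms held raised,
#' lateral pelvis translation), \code{trunk_bend} (lateral trunk lean),
#' \code{squat} (hip/knee flexion with compensating pelvis drop).
#'
#' @param classId one of \code{\link{exerciseClasses}}.
#' @param t phase in [0, 1].
#' @param seed integer seed for the jitter (NULL = no jitter).
#' @param amplitude multiplier on the class movement amplitude.
#' @param jitterSd axis-angle jitter standard deviation (radians), clamped
#'   at three standard deviations.
#' @param scale body stature in mm.
#' @return A \linkS4class{BodyPose}.
#' @export
#' @examples
#' samplePose("arm_raise", t = 0.5, seed = 1)
samplePose <- function(classId, t, seed = NULL, amplitude = 1,
                       jitterSd = 0.015, scale = 1750) {
  classes <- .exerciseClasses()
  if (!classId %in% classes)
    stop("unknown class '", classId, "'; valid classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  if (t < 0 || t > 1) stop("phase t must lie in [0, 1]", call. = FALSE)
  nm <- jointNames24()
  th <- matrix(0, 24, 3, dimnames = list(nm, c("x", "y", "z")))
  root <- c(0, 0, 0)
  a <- amplitude
  if (classId == "arm_raise") {
    alpha <- 2.5 * a * sin(pi * t)
    th["shoulder_l", "z"] <- -alpha
    th["shoulder_r", "z"] <- alpha
    th["collar_l", "z"] <- -0.08 * alpha
    th["collar_r", "z"] <- 0.08 * alpha
  } else if (classId == "lateral_bar_shift") {
    th["shoulder_l", "z"] <- -2.2
    th["shoulder_r", "z"] <- 2.2
    root[1] <- 150 * a * sin(2 * pi * t)
  } else if (classId == "trunk_bend") {
    lean <- 0.3 * a * sin(2 * pi * t)
    th["spine1", "z"] <- lean
    th["spine2", "z"] <- lean * 0.7
  } else if (classId == "squat") {
    flex <- a * sin(pi * t)
    th["hip_l", "x"] <- -1.0 * flex
    th["hip_r", "x"] <- -1.0 * flex
    th["knee_l", "x"] <- 1.9 * flex
    th["knee_r", "x"] <- 1.9 * flex
    th["ankle_l", "x"] <- -0.9 * flex
    th["ankle_r", "x"] <- -0.9 * flex
  }
  if (!is.null(seed) && jitterSd > 0) {
    jit <- .withSeed(seed, rnorm(72, 0, jitterSd))
    jit <- pmin(pmax(jit, -3 * jitterSd), 3 * jitterSd)
    th <- th + matrix(jit, 24, 3)
  }
  # keep the feet on the floor: drop the root by the posed ankle rise
  rest <- .restSkeleton(scale)
  posed <- .fk(rest, as.vector(t(th)))$joints
  ankles <- match(c("ankle_l", "ankle_r"), nm)
  root[2] <- root[2] - (min(posed[ankles, 2]) - min(rest[ankles, 2]))
  new("BodyPose", jointAngles = th, rootPosition = root, scale = scale)
}

#' Bundled exercise classes
#' @return Character vector of the five synthetic exercise class labels.
#' @export
exerciseClasses <- function() .exerciseClasses()

# Project world mm (y up) to 0-based pixel coordinates.
.projectPoints <- function(P, rootPosition, scene) {
  H <- scene@imageSize[1]; W <- scene@imageSize[2]; s <- scene@cameraScale
  groundRow <- floor(0.95 * H)
  cbind(x = (P[, 1] + rootPosition[1]) / s + (W - 1) / 2,
        y = groundRow - (P[, 2] + rootPosition[2]) / s,
        z = P[, 3] + rootPosition[3])
}

#' Render a synthetic RGB-D frame
#'
#' Rasterizes the posed body as a union of per-bone capsules over a planar
#' floor. Non-body pixels carry the exact floor-plane depth
#' z = a*x + b*y + c; body pixels carry the floor depth at the pelvis minus
#' a fixed 800 mm standoff, minus the local limb offset, plus Gaussian
#' noise of sd \code{depthNoiseSd}, so body and floor are separable by a
#' single threshold.
#'
#' @param pose a \linkS4class{BodyPose}.
#' @param scene a \linkS4class{SceneConfig}.
#' @param seed integer seed for the depth noise (defaults to the scene seed).
#' @return A \linkS4class{RenderedFrame}.
#' @export
#' @examples
#' fr <- renderFrame(samplePose("idle", 0), sceneConfig(depthNoiseSd = 0))
#' fr
renderFrame <- function(pose, scene, seed = scene@seed) {
  H <- scene@imageSize[1]; W <- scene@imageSize[2]; s <- scene@cameraScale
  rest <- .restSkeleton(pose@scale)
  fk <- .fk(rest, as.vector(t(pose@jointAngles)))
  jp <- .projectPoints(fk$joints, pose@rootPosition, scene)
  caps <- .capsuleTable()
  radScale <- pose@scale / 1750
  # frame-fit check including each capsule's own radius
  rpx <- caps$r * radScale / s
  ex <- cbind(pmin(jp[caps$a, 1], jp[caps$b, 1]) - rpx,
              pmax(jp[caps$a, 1], jp[caps$b, 1]) + rpx,
              pmin(jp[caps$a, 2], jp[caps$b, 2]) - rpx,
              pmax(jp[caps$a, 2], jp[caps$b, 2]) + rpx)
  if (min(ex[, 1]) < 0 || min(ex[, 3]) < 0 ||
      max(ex[, 2]) > W - 1 || max(ex[, 4]) > H - 1)
    stop("pose projects outside the image; increase cameraScale, ",
         "enlarge imageSize or move rootPosition", call. = FALSE)

  sil <- matrix(FALSE, H, W)
  parts <- matrix(0L, H, W)
  zbuf <- matrix(-Inf, H, W)
  for (k in seq_len(nrow(caps))) {
    p1 <- jp[caps$a[k], ]; p2 <- jp[caps$b[k], ]
    r <- caps$r[k] * radScale / s
    x0 <- max(0, floor(min(p1[1], p2[1]) - r)); x1 <- min(W - 1, ceiling(max(p1[1], p2[1]) + r))
    y0 <- max(0, floor(min(p1[2], p2[2]) - r)); y1 <- min(H - 1, ceiling(max(p1[2], p2[2]) + r))
    xs <- x0:x1; ys <- y0:y1
    gx <- matrix(rep(xs, each = length(ys)), length(ys))
    gy <- matrix(rep(ys, times = length(xs)), length(ys))
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    L2 <- dx * dx + dy * dy
    tt <- if (L2 < 1e-12) matrix(0, length(ys), length(xs)) else
      pmin(1, pmax(0, ((gx - p1[1]) * dx + (gy - p1[2]) * dy) / L2))
    d2 <- (gx - (p1[1] + tt * dx))^2 + (gy - (p1[2] + tt * dy))^2
    hit <- d2 <= r * r
    if (!any(hit)) next
    zc <- p1[3] + tt * (p2[3] - p1[3]) + caps$zoff[k] * radScale
    rows <- ys + 1; cols <- xs + 1
    subSil <- sil[rows, cols, drop = FALSE]
    subParts <- parts[rows, cols, drop = FALSE]
    subZ <- zbuf[rows, cols, drop = FALSE]
    subSil[hit] <- TRUE
    subParts[hit] <- caps$part[k]
    subZ[hit] <- pmax(subZ[hit], zc[hit])
    sil[rows, cols] <- subSil
    parts[rows, cols] <- subParts
    zbuf[rows, cols] <- subZ
  }

  a <- scene@floorPlane[1]; b <- scene@floorPlane[2]; cc <- scene@floorPlane[3]
  xg <- matrix(rep(0:(W - 1), each = H), H)
  yg <- matrix(rep(0:(H - 1), times = W), H)
  depth <- a * xg + b * yg + cc
  pelvis <- jp[1, ]
  floorAtPelvis <- a * pelvis[1] + b * pelvis[2] + cc
  nb <- sum(sil)
  noise <- if (scene@depthNoiseSd > 0)
    .withSeed(seed, rnorm(nb, 0, scene@depthNoiseSd)) else numeric(nb)
  depth[sil] <- floorAtPelvis - 800 - zbuf[sil] + noise
  depth[depth < 0] <- 0

  # ground-truth joint depth = the rendered surface depth at the joint pixel
  # (noise-free); falls back to the joint's own z where a joint is not
  # covered by any capsule pixel
  jz <- vapply(seq_len(24), function(i) {
    r <- round(jp[i, 2]) + 1; c <- round(jp[i, 1]) + 1
    z <- if (r >= 1 && r <= H && c >= 1 && c <= W) zbuf[r, c] else -Inf
    if (is.finite(z)) floorAtPelvis - 800 - z else floorAtPelvis - 800 - jp[i, 3]
  }, numeric(1))
  joints2d <- jp[, 1:2, drop = FALSE]
  joints3d <- cbind(jp[, 1] * s, jp[, 2] * s, jz)
  rownames(joints2d) <- rownames(joints3d) <- jointNames24()
  new("RenderedFrame", silhouette = sil * 255, depth = depth,
      partLabels = parts, joints2d = joints2d, joints3d = joints3d,
      scene = scene)
}

#' Generate a class-balanced synthetic motion dataset
#'
#' Builds \code{nSequences} motion sequences of \code{T} frames each,
#' cycling over \code{classes} (balanced up to remainder) and over
#' \code{nSubjects} synthetic subjects whose statures span 1660-1840 mm.
#' Fully reproducible from \code{seed}; an index manifest accompanies the
#' sequences and is also written as CSV when \code{dir} is given.
#'
#' @param nSequences number of sequences (>= number of classes).
#' @param T frames per sequence (>= 1).
#' @param classes class label set (default the five bundled exercises).
#' @param scene a \linkS4class{SceneConfig}.
#' @param seed integer master seed.
#' @param nSubjects number of synthetic subjects cycled over sequences.
#' @param dir optional output directory; when given, frames are written
#'   (silhouette/part PNG, 16-bit depth TIFF in mm, joints JSON) along with
#'   \code{manifest.csv}.
#' @return list(sequences = list of \linkS4class{MotionSequence},
#'   manifest = data.frame(sequence_id, class_id, subject_id, path)).
#' @export
#' @examples
#' d <- generateDataset(5, 2, scene = sceneConfig(c(120L, 96L), cameraScale = 18,
#'                                                depthNoiseSd = 0), seed = 1)
#' d$manifest
generateDataset <- function(nSequences, T, classes = exerciseClasses(),
                            scene = sceneConfig(), seed = 1L, nSubjects = 10L,
                            dir = NULL) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  K <- length(classes)
  if (nSequences < K) stop("nSequences must be >= number of classes", call. = FALSE)
  base <- as.integer(seed) %% 100000L
  seqs <- vector("list", nSequences)
  manifest <- data.frame(sequence_id = character(nSequences),
                         class_id = character(nSequences),
                         subject_id = integer(nSequences),
                         path = character(nSequences),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nSequences)) {
    cls <- classes[((i - 1L) %% K) + 1L]
    subject <- (((i - 1L) %/% K) %% nSubjects) + 1L
    stature <- 1640 + subject * 20
    seqSeed <- (base * 7919 + i * 104729) %% 2147483647
    pars <- .withSeed(seqSeed, list(amp = runif(1, 0.85, 1.15),
                                    phase = runif(1, 0, 0.08)))
    frames <- vector("list", T)
    for (f in seq_len(T)) {
      t <- if (T == 1) 0.5 else (f - 1) / (T - 1)
      t <- min(1, max(0, t * (1 - pars$phase) + pars$phase / 2))
      pose <- samplePose(cls, t, seed = seqSeed + 131 * f, amplitude = pars$amp,
                         scale = stature)
      frames[[f]] <- renderFrame(pose, scene, seed = seqSeed + 977 * f)
    }
    sid <- sprintf("seq%04d", i)
    seqs[[i]] <- new("MotionSequence", frames = frames, classId = cls,
                     subjectId = subject, sequenceId = sid)
    manifest[i, ] <- list(sid, cls, subject,
                          if (is.null(dir)) NA_character_ else file.path(dir, sid))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sq in seqs) writeSequence(sq, file.path(dir, sq@sequenceId))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(sequences = seqs, manifest = manifest)
}

#' Write one motion sequence to disk
#'
#' Silhouettes and part labels as 8-bit PNG, depth as 16-bit TIFF (mm),
#' ground-truth joints as one JSON file per frame.
#'
#' @param sq a \linkS4class{MotionSequence}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeSequence <- function(sq, dir) {
  for (sub in c("masks", "depth", "parts", "joints"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(sq@frames)) {
    fr <- sq@frames[[f]]
    png::writePNG(fr@silhouette / 255, file.path(dir, "masks", sprintf("%04d.png", f)))
    tiff::writeTIFF(pmin(round(fr@depth), 65535) / 65535,
                    file.path(dir, "depth", sprintf("%04d.tif", f)),
                    bits.per.sample = 16L, compression = "none")
    png::writePNG(fr@partLabels / 255, file.path(dir, "parts", sprintf("%04d.png", f)))
    jsonlite::write_json(
      list(frame = f, joints = unname(cbind(fr@joints2d, fr@joints3d[, 3]))),
      file.path(dir, "joints", sprintf("%04d.json", f)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
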