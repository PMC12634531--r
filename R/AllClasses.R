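#' @importClassesFrom methods ANY
NULL

#' BodyPose: articulated pose of the synthetic body
#'
#' Holds 24 axis-angle joint rotations (radians), a root translation in
#' scene millimetres, and the body stature used to scale the rest skeleton.
#'
#' @slot jointAngles numeric 24 x 3 matrix of axis-angle triplets (radians).
#' @slot rootPosition numeric length-3 translation (mm, scene coordinates).
#' @slot scale body stature in mm (> 0).
#' @export
setClass("BodyPose",
  representation(jointAngles = "matrix", rootPosition = "numeric", scale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@jointAngles) == c(24L, 3L)))
      msg <- c(msg, "jointAngles must be a 24 x 3 matrix")
    if (length(object@rootPosition) != 3L)
      msg <- c(msg, "rootPosition must have length 3")
    if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
      msg <- c(msg, "scale must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' SceneConfig: rendering and camera configuration
#'
#' @slot imageSize integer (H, W) in pixels.
#' @slot floorPlane numeric (a, b, c) of the floor depth plane
#'   z = a*x + b*y + c, with x, y 0-based pixel coordinates and z in mm.
#' @slot cameraScale mm per pixel of the orthographic projection.
#' @slot depthNoiseSd standard deviation of the body depth noise in mm.
#' @slot seed integer seed associated with the scene.
#' @export
setClass("SceneConfig",
  representation(imageSize = "integer", floorPlane = "numeric",
                 cameraScale = "numeric", depthNoiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@imageSize) != 2L || any(object@imageSize <= 0L))
      msg <- c(msg, "imageSize must be two positive integers (H, W)")
    if (length(object@floorPlane) != 3L)
      msg <- c(msg, "floorPlane must be (a, b, c)")
    if (object@cameraScale <= 0) msg <- c(msg, "cameraScale must be > 0")
    if (object@depthNoiseSd < 0) msg <- c(msg, "depthNoiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' RenderedFrame: one synthetic RGB-D observation
#'
#' @slot silhouette binary mask matrix (H x W, values 0/255).
#' @slot depth depth matrix in mm (0 = invalid).
#' @slot partLabels per-pixel part id matrix (0 = background, 1..8 parts).
#' @slot joints2d 24 x 2 ground-truth pixel coordinates (0-based x, y).
#' @slot joints3d 24 x 3 ground-truth positions (x px, y px, z mm).
#' @slot scene the SceneConfig used for rendering.
#' @export
setClass("RenderedFrame",
  representation(silhouette = "matrix", depth = "matrix", partLabels = "matrix",
                 joints2d = "matrix", joints3d = "matrix", scene = "SceneConfig"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@silhouette)
    if (!identical(dim(object@depth), d) || !identical(dim(object@partLabels), d))
      msg <- c(msg, "silhouette, depth and partLabels must share dimensions")
    if (!all(object@silhouette %in% c(0, 255)))
      msg <- c(msg, "silhouette must be binary {0, 255}")
    if (any(object@depth < 0)) msg <- c(msg, "depth must be >= 0")
    if (!all(dim(object@joints2d) == c(24L, 2L)))
      msg <- c(msg, "joints2d must be 24 x 2")
    if (!all(dim(object@joints3d) == c(24L, 3L)))
      msg <- c(msg, "joints3d must be 24 x 3")
    if (is.null(msg)) TRUE else msg
  })

#' MotionSequence: an ordered list of rendered frames with a class label
#'
#' @slot frames list of RenderedFrame objects sharing one image size.
#' @slot classId exercise class label.
#' @slot subjectId synthetic subject identifier.
#' @slot sequenceId sequence identifier within a dataset.
#' @export
setClass("MotionSequence",
  representation(frames = "list", classId = "character",
                 subjectId = "integer", sequenceId = "character"),
  validity = function(object) {
    if (length(object@frames) < 1L) return("a MotionSequence needs >= 1 frame")
    dims <- vapply(object@frames, function(f) dim(f@silhouette), integer(2))
    if (nrow(unique(t(dims))) != 1L) return("all frames must share image_size")
    TRUE
  })

#' FloorModel: fitted floor plane of a depth frame
#'
#' @slot a,b,c plane coefficients of z = a*x + b*y + c (x, y 0-based pixels, z mm).
#' @slot epsilon inlier/removal threshold in mm (> 0).
#' @slot inlierCount number of candidate pixels within epsilon of the plane.
#' @export
setClass("FloorModel",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 epsilon = "numeric", inlierCount = "integer"),
  validity = function(object) {
    if (object@epsilon <= 0) "epsilon must be > 0" else TRUE
  })

#' Keypoints24: the canonical 24-joint keypoint set of one frame
#'
#' @slot points 24 x 3 matrix (x px, y px, z mm) in \code{\link{jointNames24}} order.
#' @slot mode arm-pose mode, "LOWERED" or "RAISED".
#' @slot silhouetteBbox list(top, left, h, w) of the source silhouette.
#' @export
setClass("Keypoints24",
  representation(points = "matrix", mode = "character", silhouetteBbox = "list"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@points) == c(24L, 3L)))
      msg <- c(msg, "points must be 24 x 3")
    if (!identical(rownames(object@points), jointNames24()))
      msg <- c(msg, "points rows must be named and ordered by jointNames24()")
    if (!object@mode %in% c("LOWERED", "RAISED"))
      msg <- c(msg, "mode must be LOWERED or RAISED")
    if (is.null(msg)) TRUE else msg
  })

#' ToyBodyModel: procedurally generated linear-blend-skinning body
#'
#' A compact parametric body with the same parameter dimensions as standard
#' skinned multi-person linear models (72 pose parameters over 24 joints,
#' 10 shape parameters), built from per-bone capsule rings.
#'
#' @slot templateVertices V x 3 rest vertices (mm).
#' @slot faces F x 3 vertex indices (1-based).
#' @slot skinWeights V x 24 skinning weights, rows summing to 1.
#' @slot kinematicTree length-24 parent indices (0 = root).
#' @slot shapeBasis 3V x 10 vertex displacement modes (unit columns).
#' @slot jointBasis 72 x 10 rest-joint displacement modes.
#' @slot restJoints 24 x 3 rest joint positions (mm).
#' @export
setClass("ToyBodyModel",
  representation(templateVertices = "matrix", faces = "matrix",
                 skinWeights = "matrix", kinematicTree = "integer",
                 shapeBasis = "matrix", jointBasis = "matrix", restJoints = "matrix"),
  validity = function(object) {
    msg <- NULL
    V <- nrow(object@templateVertices)
    if (ncol(object@templateVertices) != 3L) msg <- c(msg, "templateVertices must be V x 3")
    if (!all(dim(object@skinWeights) == c(V, 24L)))
      msg <- c(msg, "skinWeights must be V x 24")
    else if (max(abs(rowSums(object@skinWeights) - 1)) > 1e-9)
      msg <- c(msg, "skinWeights rows must sum to 1 (tolerance 1e-9)")
    if (length(object@kinematicTree) != 24L || object@kinematicTree[1] != 0L ||
        any(object@kinematicTree[-1] >= seq_len(23L) + 1L))
      msg <- c(msg, "kinematicTree must be 24 topologically ordered parent indices rooted at joint 1")
    if (!all(dim(object@shapeBasis) == c(3L * V, 10L)))
      msg <- c(msg, "shapeBasis must be 3V x 10")
    else if (any(abs(sqrt(colSums(object@shapeBasis^2)) - 1) > 1e-6))
      msg <- c(msg, "shapeBasis columns must be unit-normalized")
    if (!all(dim(object@restJoints) == c(24L, 3L)))
      msg <- c(msg, "restJoints must be 24 x 3")
    if (!all(dim(object@jointBasis) == c(72L, 10L)))
      msg <- c(msg, "jointBasis must be 72 x 10")
    if (is.null(msg)) TRUE else msg
  })

#' FitResult: output of the body-model sequence fit
#'
#' @slot theta T x 72 fitted pose parameters (axis-angle, radians).
#' @slot beta length-10 shared shape parameters.
#' @slot translation T x 3 per-frame global translations (mm).
#' @slot lossTrace data.frame of per-iteration total and per-term losses.
#' @slot joints T x 24 x 3 array of fitted joint positions (mm).
#' @slot vertices V x 3 fitted vertices of the last frame (mm).
#' @export
setClass("FitResult",
  representation(theta = "matrix", beta = "numeric", translation = "matrix",
                 lossTrace = "data.frame", joints = "array", vertices = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@theta) != 72L) msg <- c(msg, "theta must be T x 72")
    if (length(object@beta) != 10L) msg <- c(msg, "beta must have length 10")
    if (!all(is.finite(as.matrix(object@lossTrace[-1]))))
      msg <- c(msg, "lossTrace must be finite")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "BodyPose", function(object) {
  cat("BodyPose: stature", object@scale, "mm, root (",
      paste(round(object@rootPosition, 1), collapse = ", "),
      ") mm, mean |angle|", round(mean(abs(object@jointAngles)), 3), "rad\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px, %.2f mm/px, floor z = %g*x + %g*y + %g, noise sd %g mm\n",
              object@imageSize[1], object@imageSize[2], object@cameraScale,
              object@floorPlane[1], object@floorPlane[2], object@floorPlane[3],
              object@depthNoiseSd))
})

setMethod("show", "RenderedFrame", function(object) {
  cat(sprintf("RenderedFrame: %d x %d px, %d silhouette px, depth range [%g, %g] mm\n",
              nrow(object@silhouette), ncol(object@silhouette),
              sum(object@silhouette > 0), min(object@depth[object@depth > 0]),
              max(object@depth)))
})

setMethod("show", "MotionSequence", function(object) {
  cat(sprintf("MotionSequence '%s': class '%s', subject %d, %d frames\n",
              object@sequenceId, object@classId, object@subjectId,
              length(object@frames)))
})

setMethod("show", "FloorModel", function(object) {
  cat(sprintf("FloorModel: z = %.4f*x + %.4f*y + %.2f (epsilon %g mm, %d inliers)\n",
              object@a, object@b, object@c, object@epsilon, object@inlierCount))
})

setMethod("show", "Keypoints24", function(object) {
  cat(sprintf("Keypoints24 (%s mode): 24 joints, x in [%g, %g], y in [%g, %g]\n",
              object@mode, min(object@points[, 1]), max(object@points[, 1]),
              min(object@points[, 2]), max(object@points[, 2])))
})

setMethod("show", "ToyBodyModel", function(object) {
  cat(sprintf("ToyBodyModel: %d vertices, %d faces, 24 joints, 10 shape modes\n",
              nrow(object@templateVertices), nrow(object@faces)))
})

setMethod("show", "FitResult", function(object) {
  n <- nrow(object@lossTrace)
  cat(sprintf("FitResult: %d frame(s), final total loss %.4g (initial %.4g)\n",
              nrow(object@theta), object@lossTrace$total[n], object@lossTrace$total[1]))
})

# ---- accessors ----

#' Accessors for rendered frames and fits
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an object of the documented class.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("silhouette", function(x) standardGeneric("silhouette"))
#' @rdname accessors
#' @export
setMethod("silhouette", "RenderedFrame", function(x) x@silhouette)

#' @rdname accessors
#' @export
setGeneric("depthMap", function(x) standardGeneric("depthMap"))
#' @rdname accessors
#' @export
setMethod("depthMap", "RenderedFrame", function(x) x@depth)

#' @rdname accessors
#' @export
setGeneric("partLabels", function(x) standardGeneric("partLabels"))
#' @rdname accessors
#' @export
setMethod("partLabels", "RenderedFrame", function(x) x@partLabels)

#' @rdname accessors
#' @export
setGeneric("gtJoints2d", function(x) standardGeneric("gtJoints2d"))
#' @rdname accessors
#' @export
setMethod("gtJoints2d", "RenderedFrame", function(x) x@joints2d)

#' @rdname accessors
#' @export
setGeneric("gtJoints3d", function(x) standardGeneric("gtJoints3d"))
#' @rdname accessors
#' @export
setMethod("gtJoints3d", "RenderedFrame", function(x) x@joints3d)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "MotionSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("classId", function(x) standardGeneric("classId"))
#' @rdname accessors
#' @export
setMethod("classId", "MotionSequence", function(x) x@classId)

#' @rdname accessors
#' @export
setGeneric("keypointMatrix", function(x) standardGeneric("keypointMatrix"))
#' @rdname accessors
#' @export
setMethod("keypointMatrix", "Keypoints24", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("poseMode", function(x) standardGeneric("poseMode"))
#' @rdname accessors
#' @export
setMethod("poseMode", "Keypoints24", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("fittedTheta", function(x) standardGeneric("fittedTheta"))
#' @rdname accessors
#' @export
setMethod("fittedTheta", "FitResult", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("fittedBeta", function(x) standardGeneric("fittedBeta"))
#' @rdname accessors
#' @export
setMethod("fittedBeta", "FitResult", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("fittedJoints", function(x) standardGeneric("fittedJoints"))
#' @rdname accessors
#' @export
setMethod("fittedJoints", "FitResult", function(x) x@joints)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "FitResult", function(x) x@lossTrace)
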