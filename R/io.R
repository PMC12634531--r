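# Plain-text exporters for downstream tools: Wavefront OBJ meshes,
# per-frame keypoint JSON, and fit parameter/loss-trace JSON.

#' Write a mesh as Wavefront OBJ
#'
#' @param vertices V x 3 vertex positions (mm).
#' @param faces F x 3 1-based vertex indices.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeMeshObj <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}

#' Write one frame's 24 keypoints as JSON
#'
#' Layout: \code{{"mode": "L"|"R", "joints": {name: [x, y, z], ...}}}.
#'
#' @param kp a \linkS4class{Keypoints24}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeKeypoints24Json <- function(kp, path) {
  pts <- keypointMatrix(kp)
  joints <- lapply(seq_len(nrow(pts)), function(i) unname(pts[i, ]))
  names(joints) <- rownames(pts)
  jsonlite::write_json(list(mode = if (poseMode(kp) == "RAISED") "R" else "L",
                            joints = joints),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a detector's keypoints as JSON
#'
#' Layout: \code{{"detector": id, "points": [[x, y, response], ...]}}.
#'
#' @param set a KeypointSet from \code{\link{detectKeypoints}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeKeypointSetJson <- function(set, path) {
  pts <- set$points
  jsonlite::write_json(list(detector = set$detectorId,
                            points = unname(as.matrix(pts[, c("x", "y", "response")]))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write fitted body-model parameters and loss trace as JSON
#'
#' @param fit a \linkS4class{FitResult}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeFitResultJson <- function(fit, path) {
  jsonlite::write_json(list(theta = fittedTheta(fit), beta = fittedBeta(fit),
                            translation = fit@translation,
                            loss_trace = lossTrace(fit)),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
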