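# End-to-end orchestration: configuration, per-sequence feature
# extraction over the RGB stream (silhouette -> keypoint bank -> part
# contours) and the depth stream (floor removal -> enhancement -> depth
# segmentation -> 24-point extraction -> body-model fit), fusion, and
# training/evaluation of the sequence classifier.

#' Pipeline configuration
#'
#' Nested configuration of every stage with validated keys. Unknown keys
#' are rejected. The configuration can be loaded from YAML with
#' \code{\link{readPipelineConfig}}.
#'
#' @param synth list: imageSize, cameraScale, depthNoiseSd, floorPlane,
#'   nSequences, T, nSubjects, classes.
#' @param segmentation list: backend ("synthetic"; external networks are
#'   supplied programmatically as \code{\link{scoreBackend}} objects),
#'   input_size, mean, std (see \code{\link{preprocessRgb}}).
#' @param keypoints2d list: detector settings (see
#'   \code{\link{detectorConfig}}) plus \code{enabled} detectors.
#' @param parts list: points_per_part.
#' @param depth list: see \code{\link{depthPreprocConfig}} plus
#'   \code{seg_input_size}.
#' @param meshfit list: lambdas, iters, lr, polish, polishIters, prior
#'   ("gmm" or "gauss"), gmm_components.
#' @param transformer list: d_model, heads, layers, ffn_dim, dropout,
#'   max_len.
#' @param train list: epochs, batchSize, lr, split ("subject" or
#'   "random"), holdoutFrac.
#' @param seed master seed.
#' @return Nested named list with class "PipelineConfig".
#' @export
pipelineConfig <- function(synth = list(), segmentation = list(),
                           keypoints2d = list(), parts = list(),
                           depth = list(), meshfit = list(), transformer = list(),
                           train = list(), seed = 0L) {
  def <- list(
    synth = list(imageSize = c(80L, 72L), cameraScale = 35, depthNoiseSd = 5,
                 floorPlane = c(0, 2, 2400), nSequences = 200L, T = 30L,
                 nSubjects = 10L, classes = exerciseClasses()),
    segmentation = list(backend = "synthetic", input_size = NULL,
                        mean = c(0, 0, 0), std = c(1, 1, 1)),
    keypoints2d = list(harris_k = 0.04, harris_window = 2, dp_epsilon = 2,
                       max_points = 32L, blur_sigma = 1, fast_threshold = 0.08,
                       response_frac = 0.01, enabled = .detectorIds()),
    parts = list(points_per_part = 16L),
    depth = list(ransac_iters = 100L, epsilon = 15, clahe_clip = 2,
                 clahe_tiles = 8L, bilateral_diameter = 5L,
                 bilateral_sigma_space = 75, bilateral_sigma_range = 75,
                 max_candidates = 3000L, candidate_frac = 0.4,
                 seg_input_size = 128L),
    meshfit = list(lambdas = c(1, 0.01, 0.001, 0.1, 0),
                   iters = c(global = 4L, pose = 8L, pose_shape = 3L),
                   lr = 0.08, polish = FALSE, polishIters = 50L,
                   prior = "gauss", gmm_components = 8L),
    transformer = list(d_model = 64L, heads = 4L, layers = 2L, ffn_dim = 128L,
                       dropout = 0, max_len = 64L),
    train = list(epochs = 12L, batchSize = 16L, lr = 1e-3,
                 split = "subject", holdoutFrac = 0.2),
    seed = 0L)
  user <- list(synth = synth, segmentation = segmentation,
               keypoints2d = keypoints2d, parts = parts,
               depth = depth, meshfit = meshfit, transformer = transformer,
               train = train, seed = seed)
  for (sec in names(def)) {
    if (sec == "seed") next
    unknown <- setdiff(names(user[[sec]]), names(def[[sec]]))
    if (length(unknown) > 0)
      stop("unknown config key(s) in ", sec, ": ", paste(unknown, collapse = ", "),
           call. = FALSE)
    def[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  def$seed <- as.integer(seed)
  class(def) <- "PipelineConfig"
  def
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of the \code{\link{pipelineConfig}}
#'   sections.
#' @return A validated "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("synth", "segmentation", "keypoints2d", "parts", "depth",
             "meshfit", "transformer", "train", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, y)
}

# stage sub-configs assembled once per run
.stageConfigs <- function(cfg) {
  if (!identical(cfg$segmentation$backend, "synthetic"))
    stop("only the bundled 'synthetic' segmentation backend is configurable ",
         "by name; pass external backends programmatically as scoreBackend ",
         "objects", call. = FALSE)
  list(det = detectorConfig(harris_k = cfg$keypoints2d$harris_k,
                            harris_window = cfg$keypoints2d$harris_window,
                            dp_epsilon = cfg$keypoints2d$dp_epsilon,
                            max_points = cfg$keypoints2d$max_points,
                            blur_sigma = cfg$keypoints2d$blur_sigma,
                            fast_threshold = cfg$keypoints2d$fast_threshold,
                            response_frac = cfg$keypoints2d$response_frac),
       enabled = cfg$keypoints2d$enabled,
       nParts = cfg$parts$points_per_part,
       depth = depthPreprocConfig(ransac_iters = cfg$depth$ransac_iters,
                                  epsilon = cfg$depth$epsilon,
                                  clahe_clip = cfg$depth$clahe_clip,
                                  clahe_tiles = cfg$depth$clahe_tiles,
                                  bilateral_diameter = cfg$depth$bilateral_diameter,
                                  bilateral_sigma_space = cfg$depth$bilateral_sigma_space,
                                  bilateral_sigma_range = cfg$depth$bilateral_sigma_range,
                                  max_candidates = cfg$depth$max_candidates,
                                  candidate_frac = cfg$depth$candidate_frac,
                                  seed = cfg$seed),
       segSize = cfg$depth$seg_input_size,
       segmentation = cfg$segmentation,
       mode = modeConfig())
}

#' Generate the synthetic dataset of a pipeline configuration
#' @param cfg a "PipelineConfig".
#' @return As \code{\link{generateDataset}}.
#' @export
runSynth <- function(cfg) {
  sc <- sceneConfig(imageSize = cfg$synth$imageSize,
                    floorPlane = cfg$synth$floorPlane,
                    cameraScale = cfg$synth$cameraScale,
                    depthNoiseSd = cfg$synth$depthNoiseSd, seed = cfg$seed)
  generateDataset(cfg$synth$nSequences, cfg$synth$T, cfg$synth$classes,
                  sc, seed = cfg$seed, nSubjects = cfg$synth$nSubjects)
}

# RGB-stream features of one frame: silhouette chain, keypoint bank
# encoding, part-contour encoding.
.rgbFeatures <- function(frame, sc) {
  sil <- silhouette(frame)
  seg <- sc$segmentation
  identityStats <- all(seg$mean == 0) && all(seg$std == 1) &&
    is.null(seg$input_size)
  ni <- if (identityStats) {
    # fast path: identity normalization at source size
    structure(list(values = array(rep(sil / 255, 3), c(dim(sil), 3)),
                   mean = c(0, 0, 0), std = c(1, 1, 1),
                   sourceSize = dim(sil)),
              class = "NormalizedImage")
  } else {
    preprocessRgb(array(rep(sil, 3), c(dim(sil), 3)), mean = seg$mean,
                  std = seg$std, targetSize = seg$input_size)
  }
  mask <- .silhouetteChain(ni, thresholdBackend(sil))
  mask <- .alignMaskNn(mask, dim(sil))
  bb <- maskBbox(mask)
  sets <- lapply(sc$enabled, function(id) detectKeypoints(mask, id, sc$det))
  kEnc <- encodeKeypoints(sets, bb, sc$det$max_points)
  pp <- parseParts(ni, partsBackend(partLabels(frame)))
  bEnc <- encodeParts(partContourSet(pp$labels, sc$nParts), bb)
  list(k = kEnc, b = bEnc, mask = mask, bbox = bb)
}

# Depth-stream 24-point extraction of one frame.
.depthKeypoints <- function(frame, sc) {
  dp <- depthMap(frame)
  fm <- fitFloorRansac(dp, cfg = sc$depth)
  dr <- removeFloor(dp, fm)
  en <- enhanceDepth(normalizeMinMax(dr), sc$depth)
  mask <- segmentDepth(en, thresholdBackend((dr > 0) * 255), sc$segSize)
  dBody <- dr
  dBody[mask == 0] <- 0
  extractKeypoints24(mask, dBody, sc$mode)
}

#' Extract fused features for one motion sequence
#'
#' Runs the RGB stream (silhouette, keypoint bank, part contours) and the
#' depth stream (floor removal, enhancement, depth segmentation, 24-point
#' extraction) per frame, fits the body model to the lifted joints of the
#' whole sequence, and fuses per-frame blocks k, b, m (m = pose, shape,
#' fitted joints).
#'
#' @param sq a \linkS4class{MotionSequence}.
#' @param cfg a "PipelineConfig".
#' @param model a \linkS4class{ToyBodyModel} (built once per run).
#' @param prior a "posePrior" for the fit.
#' @return M x (P+Q+S) feature matrix.
#' @export
extractSequenceFeatures <- function(sq, cfg, model = toyBodyModel(),
                                    prior = standardGaussianPrior()) {
  sc <- .stageConfigs(cfg)
  frames <- frames(sq)
  rgb <- lapply(frames, .rgbFeatures, sc = sc)
  kps <- lapply(frames, .depthKeypoints, sc = sc)
  camScale <- frames[[1]]@scene@cameraScale
  target <- mapJoints(kps, camScale)
  # the fit operates in the model's coordinate frame: image y grows down,
  # so flip y and undo the z inversion of the mapping stage
  target[, , 2] <- -target[, , 2]
  target[, , 3] <- -target[, , 3]
  fcfg <- fitConfig(lambdas = cfg$meshfit$lambdas, lr = cfg$meshfit$lr,
                    iters = cfg$meshfit$iters, prior = prior,
                    polish = cfg$meshfit$polish,
                    polishIters = cfg$meshfit$polishIters, seed = cfg$seed)
  fit <- fitSequence(target, model, fcfg)
  bodyH <- max(model@restJoints[, 2]) - min(model@restJoints[, 2])
  rows <- lapply(seq_along(frames), function(t) {
    m <- c(fittedTheta(fit)[t, ], fittedBeta(fit),
           as.vector(fittedJoints(fit)[t, , ]) / bodyH)
    fuseFeatures(rgb[[t]]$k, rgb[[t]]$b, m)
  })
  featureMatrix(rows)
}

#' Extract features for a whole dataset
#'
#' Per-sequence extraction with skip-on-error: a sequence whose frames
#' cannot be processed is recorded in the manifest with its reason and
#' excluded from the feature list. Optionally writes one CSV per sequence
#' plus a JSON manifest with the configuration hash.
#'
#' @param dataset list(sequences, manifest) from \code{\link{runSynth}} or
#'   \code{\link{generateDataset}}.
#' @param cfg a "PipelineConfig".
#' @param dir optional output directory; existing feature files are
#'   reused unless \code{force}.
#' @param force overwrite existing outputs.
#' @param verbose log per-sequence progress.
#' @return list(features, labels, subjects, manifest, skipped).
#' @export
runExtract <- function(dataset, cfg, dir = NULL, force = FALSE, verbose = FALSE) {
  model <- toyBodyModel()
  prior <- if (identical(cfg$meshfit$prior, "gmm"))
    .pipelinePrior(cfg) else standardGaussianPrior()
  cfgHash <- .configHash(cfg)
  feats <- list(); labels <- character(0); subjects <- integer(0)
  skipped <- data.frame(sequence_id = character(0), reason = character(0))
  rows <- NULL
  for (sq in dataset$sequences) {
    sid <- sq@sequenceId
    outFile <- if (!is.null(dir)) file.path(dir, paste0(sid, ".csv")) else NULL
    t0 <- proc.time()[3]
    F <- NULL
    if (!is.null(outFile) && file.exists(outFile) && !force) {
      F <- as.matrix(read.csv(outFile))
      dimnames(F) <- NULL
      attr(F, "blocks") <- c(k = 2L * cfg$keypoints2d$max_points *
                               length(cfg$keypoints2d$enabled),
                             b = 2L * cfg$parts$points_per_part * 8L,
                             m = 154L)
    } else {
      F <- tryCatch(extractSequenceFeatures(sq, cfg, model, prior),
                    error = function(e) {
                      skipped <<- rbind(skipped,
                                        data.frame(sequence_id = sid,
                                                   reason = conditionMessage(e)))
                      NULL
                    })
      if (!is.null(F) && !is.null(outFile)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write.csv(as.data.frame(F), outFile, row.names = FALSE)
      }
    }
    if (is.null(F)) next
    feats[[sid]] <- F
    labels <- c(labels, sq@classId)
    subjects <- c(subjects, sq@subjectId)
    rows <- rbind(rows, data.frame(sequence_id = sid, class_id = sq@classId,
                                   subject_id = sq@subjectId,
                                   frames = nrow(F), dims = ncol(F),
                                   seconds = round(proc.time()[3] - t0, 2)))
    if (verbose) message(sprintf("[extract] %s (%s): %d x %d in %.1fs", sid,
                                 sq@classId, nrow(F), ncol(F),
                                 proc.time()[3] - t0))
  }
  manifest <- list(config_hash = cfgHash, sequences = rows, skipped = skipped)
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(features = feats, labels = labels, subjects = subjects,
       manifest = manifest, skipped = skipped)
}

.configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(unclass(cfg), file = tf)
  unname(tools::md5sum(tf))
}

# pose library -> mixture prior, deterministic under the run seed
.pipelinePrior <- function(cfg) {
  classes <- cfg$synth$classes
  lib <- NULL
  for (cl in classes) for (t in seq(0, 1, length.out = 12))
    lib <- rbind(lib, as.vector(t(samplePose(cl, t, seed = cfg$seed + 17L)@jointAngles)))
  for (cl in classes) for (i in 1:12)
    lib <- rbind(lib, as.vector(t(samplePose(cl, (i - 1) / 11,
                                             seed = cfg$seed + i)@jointAngles)))
  fitPosePrior(lib, G = cfg$meshfit$gmm_components)
}

#' Train and evaluate the sequence classifier
#'
#' Splits the extracted features (subject-wise by default: the last
#' \code{holdoutFrac} of subject ids form the held-out set), trains the
#' Transformer and reports held-out metrics in the layout of a confusion
#' matrix with per-class precision/recall/F1.
#'
#' @param extracted output of \code{\link{runExtract}}.
#' @param cfg a "PipelineConfig".
#' @param dir optional directory for metrics JSON and the model checkpoint.
#' @return list(model, history, metrics, split).
#' @export
runTrainEval <- function(extracted, cfg, dir = NULL) {
  if (length(extracted$features) == 0) stop("no features found", call. = FALSE)
  tc <- do.call(transformerConfig,
                c(cfg$transformer, list(classes = length(unique(extracted$labels)),
                                        seed = cfg$seed)))
  n <- length(extracted$features)
  if (identical(cfg$train$split, "subject")) {
    subs <- sort(unique(extracted$subjects))
    nHold <- max(1L, round(length(subs) * cfg$train$holdoutFrac))
    holdSubs <- tail(subs, nHold)
    testIdx <- which(extracted$subjects %in% holdSubs)
  } else {
    nHold <- max(1L, round(n * cfg$train$holdoutFrac))
    testIdx <- .withSeed(cfg$seed, sample.int(n, nHold))
  }
  trainIdx <- setdiff(seq_len(n), testIdx)
  feats <- unname(extracted$features)
  tr <- trainTransformer(feats[trainIdx], extracted$labels[trainIdx], tc,
                         epochs = cfg$train$epochs, batchSize = cfg$train$batchSize,
                         lr = cfg$train$lr, seed = cfg$seed)
  metrics <- evaluateClassifier(tr$model, feats[testIdx],
                                extracted$labels[testIdx])
  out <- list(model = tr$model, history = tr$history, metrics = metrics,
              split = list(type = cfg$train$split, train = trainIdx,
                           test = testIdx))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(accuracy = metrics$accuracy,
           confusion = as.data.frame(metrics$confusion),
           per_class = metrics$perClass, history = tr$history),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    saveRDS(tr$model, file.path(dir, "model.rds"))
  }
  out
}

#' Keypoint overlay for visual QA
#'
#' Writes a PNG with the silhouette and the 24 extracted keypoints marked.
#'
#' @param mask binary silhouette.
#' @param kp a \linkS4class{Keypoints24}.
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
writeKeypointOverlay <- function(mask, kp, path) {
  img <- array(0, c(dim(mask), 3))
  img[, , 1] <- img[, , 2] <- img[, , 3] <- mask / 255 * 0.5
  pts <- keypointMatrix(kp)
  for (i in seq_len(nrow(pts))) {
    x <- round(pts[i, 1]); y <- round(pts[i, 2])
    ys <- pmax(1, pmin(nrow(mask), y + (-1:1) + 1))
    xs <- pmax(1, pmin(ncol(mask), x + (-1:1) + 1))
    img[ys, xs, 1] <- 1; img[ys, xs, 2] <- 0; img[ys, xs, 3] <- 0
  }
  png::writePNG(img, path)
  invisible(path)
}
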