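# Parametric linear-blend-skinning body model and the five-term fitting
# objective: weighted joint distance, Gaussian-mixture pose prior, shape
# regularization, temporal smoothness, and Laplacian mesh smoothness,
# minimized by staged Adam (plus an optional quasi-Newton polish) with
# analytic gradients through the kinematic chain.
#
# The bundled body is procedurally generated (per-bone capsule rings,
# ~550 vertices) with the parameter dimensions of standard skinned
# multi-person linear models: 24 joints, theta in R^72, beta in R^10.

# Bone radii (mm) for the capsule rings, keyed by child joint.
.boneRadii <- function() {
  c(pelvis = NA, hip_l = 95, hip_r = 95, spine1 = 150, knee_l = 75,
    knee_r = 75, spine2 = 150, ankle_l = 55, ankle_r = 55, spine3 = 140,
    foot_l = 28, foot_r = 28, neck = 55, collar_l = 70, collar_r = 70,
    head = 58, shoulder_l = 60, shoulder_r = 60, elbow_l = 48, elbow_r = 48,
    wrist_l = 40, wrist_r = 40, hand_l = 38, hand_r = 38)
}

#' Build the bundled parametric body model
#'
#' Generates capsule-ring vertices along each bone of the 24-joint
#' skeleton (three rings of eight vertices per bone), triangulates
#' consecutive rings, assigns nearest-bone skin weights with linear
#' falloff across joints, and constructs 10 unit-normalized shape modes
#' (stature, girth, leg/arm/torso length, shoulder/hip width, head size,
#' leg/arm girth) applied consistently to vertices and rest joints.
#'
#' @param stature rest body height in mm.
#' @return A \linkS4class{ToyBodyModel}.
#' @export
#' @examples
#' toyBodyModel()
toyBodyModel <- function(stature = 1750) {
  J <- .restSkeleton(stature)
  parents <- .jointParents()
  radii <- .boneRadii() * (stature / 1750)
  verts <- NULL; faces <- NULL; wrows <- NULL
  ringT <- c(0.25, 0.5, 0.75)
  nR <- 8L
  for (j in 2:24) {
    p <- parents[j]
    a <- J[p, ]; b <- J[j, ]
    axis <- b - a
    L <- sqrt(sum(axis^2))
    if (L < 1e-9) next
    axis <- axis / L
    # orthonormal frame of the bone
    up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- up - sum(up * axis) * axis; u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2],
           axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    base <- nrow(verts %||% matrix(0, 0, 3))
    ang <- 2 * pi * (0:(nR - 1)) / nR
    for (ti in seq_along(ringT)) {
      tt <- ringT[ti]
      ctr <- a + tt * (b - a)
      ring <- t(vapply(ang, function(th)
        ctr + radii[j] * (cos(th) * u + sin(th) * v), numeric(3)))
      verts <- rbind(verts, ring)
      # skin weights: bone binds to the parent joint, blending toward the
      # grandparent near the parent end and toward the child near the far end
      gp <- parents[p]
      wUp <- max(0, 0.5 - tt)        # toward grandparent (or parent itself at root)
      wDn <- max(0, tt - 0.5)        # toward child joint
      wSelf <- 1 - wUp - wDn
      w <- numeric(24)
      w[p] <- w[p] + wSelf
      w[if (gp == 0L) p else gp] <- w[if (gp == 0L) p else gp] + wUp
      w[j] <- w[j] + wDn
      wrows <- rbind(wrows, matrix(rep(w, nR), nR, 24, byrow = TRUE))
    }
    # triangulate consecutive rings
    for (ti in 1:(length(ringT) - 1)) {
      r0 <- base + (ti - 1) * nR; r1 <- base + ti * nR
      for (k in 1:nR) {
        k2 <- (k %% nR) + 1L
        faces <- rbind(faces,
                       c(r0 + k, r0 + k2, r1 + k),
                       c(r0 + k2, r1 + k2, r1 + k))
      }
    }
  }
  V <- nrow(verts)
  wrows <- wrows / rowSums(wrows)
  # residual float error: force exact row sums
  wrows[, 1] <- wrows[, 1] + (1 - rowSums(wrows))

  # ---- shape modes: displacement fields over rest position ----
  pelvisY <- J[1, 2]
  armJ <- match(c("shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
                  "wrist_l", "wrist_r", "hand_l", "hand_r"), rownames(J))
  legJ <- match(c("hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r",
                  "foot_l", "foot_r"), rownames(J))
  armRegion <- function(P) abs(P[, 1]) > 0.09 * stature & P[, 2] > 0.35 * stature
  legRegion <- function(P) P[, 2] < pelvisY * 0.97
  fields <- list(
    stature = function(P, joints) cbind(0, P[, 2], 0),
    girth = function(P, joints) if (joints) matrix(0, nrow(P), 3) else cbind(P[, 1] * 0.5, 0, P[, 3] * 0.5),
    leg_len = function(P, joints) cbind(0, ifelse(P[, 2] < pelvisY, P[, 2] - pelvisY, 0), 0),
    arm_len = function(P, joints) {
      sel <- armRegion(P)
      cbind(sign(P[, 1]) * sel * (abs(P[, 1]) - 0.09 * stature) * 0.5,
            sel * (P[, 2] - 0.82 * stature) * 0.5, 0)
    },
    torso_len = function(P, joints) cbind(0, ifelse(P[, 2] > pelvisY, P[, 2] - pelvisY, 0), 0),
    shoulder_w = function(P, joints) cbind(ifelse(P[, 2] > 0.7 * stature, P[, 1], 0), 0, 0),
    head_size = function(P, joints) {
      sel <- P[, 2] > 0.88 * stature
      ctr <- c(0, 0.93 * stature, 0)
      cbind(sel * (P[, 1] - ctr[1]), sel * (P[, 2] - ctr[2]), sel * (P[, 3] - ctr[3]))
    },
    hip_w = function(P, joints) cbind(ifelse(P[, 2] < 0.6 * stature & P[, 2] > 0.2 * stature, P[, 1], 0), 0, 0),
    leg_girth = function(P, joints) if (joints) matrix(0, nrow(P), 3) else {
      sel <- legRegion(P)
      cbind(sel * P[, 1] * 0.2, 0, sel * P[, 3])
    },
    arm_girth = function(P, joints) if (joints) matrix(0, nrow(P), 3) else {
      sel <- armRegion(P)
      cbind(0, sel * 0.2 * P[, 2], sel * P[, 3])
    })
  shapeBasis <- matrix(0, 3 * V, 10)
  jointBasis <- matrix(0, 72, 10)
  for (m in seq_along(fields)) {
    dv <- fields[[m]](verts, joints = FALSE)
    dj <- fields[[m]](J, joints = TRUE)
    nrm <- sqrt(sum(dv^2))
    if (nrm < 1e-9) nrm <- 1
    shapeBasis[, m] <- as.vector(dv) / nrm
    jointBasis[, m] <- as.vector(dj) / nrm
  }
  dimnames(verts) <- NULL
  new("ToyBodyModel", templateVertices = verts, faces = faces,
      skinWeights = wrows, kinematicTree = parents,
      shapeBasis = shapeBasis, jointBasis = jointBasis, restJoints = J)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shaped rest joints and template for a given beta.
.shaped <- function(model, beta) {
  V <- nrow(model@templateVertices)
  list(verts = model@templateVertices + matrix(model@shapeBasis %*% beta, V, 3),
       joints = model@restJoints + matrix(model@jointBasis %*% beta, 24, 3))
}

#' Linear-blend-skinning forward pass
#'
#' Deforms the template by the shape modes, poses the shape-dependent
#' skeleton by forward kinematics over the axis-angle parameters, and
#' skins the vertices: v' = sum_j w_vj * (G_j [x_v - J_j]) + translation.
#'
#' @param model a \linkS4class{ToyBodyModel}.
#' @param theta length-72 axis-angle pose (24 joints x 3).
#' @param beta length-10 shape coefficients.
#' @param translation length-3 global translation (mm).
#' @param withVertices FALSE skips the vertex skinning (joints only).
#' @return list(vertices = V x 3 (or NULL), joints = 24 x 3).
#' @export
lbsForward <- function(model, theta, beta = numeric(10),
                       translation = c(0, 0, 0), withVertices = TRUE) {
  stopifnot(length(theta) == 72, length(beta) == 10)
  sh <- .shaped(model, beta)
  fk <- .fk(sh$joints, theta)
  joints <- sweep(fk$joints, 2, translation, `+`)
  verts <- NULL
  if (withVertices) {
    V <- nrow(sh$verts)
    verts <- matrix(0, V, 3)
    W <- model@skinWeights
    for (j in 1:24) {
      wj <- W[, j]
      if (all(wj == 0)) next
      Rj <- fk$G[[j]][1:3, 1:3]
      tj <- fk$G[[j]][1:3, 4] - Rj %*% sh$joints[j, ]
      verts <- verts + wj * (sh$verts %*% t(Rj) + matrix(tj, V, 3, byrow = TRUE))
    }
    verts <- sweep(verts, 2, translation, `+`)
  }
  list(vertices = verts, joints = joints)
}

# ---- loss terms ----

#' Weighted squared joint distance
#' @param Jfit,Jtarget 24 x 3 joint positions.
#' @param weights per-joint positive weights.
#' @return sum_i w_i * ||Jfit_i - Jtarget_i||^2.
#' @export
jointLoss <- function(Jfit, Jtarget, weights = rep(1, 24)) {
  if (!all(dim(Jfit) == dim(Jtarget)))
    stop("joint arrays must share dimensions", call. = FALSE)
  sum(weights * rowSums((Jfit - Jtarget)^2))
}

#' Shape regularization ||beta||^2
#' @param beta length-10 shape coefficients.
#' @export
shapeReg <- function(beta) sum(beta^2)

#' Temporal smoothness of a joint sequence
#'
#' Sum of squared joint displacements between consecutive frames; 0 for a
#' single frame.
#'
#' @param Jseq T x 24 x 3 array.
#' @export
smoothReg <- function(Jseq) {
  T <- dim(Jseq)[1]
  if (T < 2) return(0)
  sum((Jseq[-1, , , drop = FALSE] - Jseq[-T, , , drop = FALSE])^2)
}

#' Laplacian mesh smoothness
#'
#' sum_i ||V_i - mean of one-ring neighbours||^2 with the neighbourhood
#' taken from the face list.
#'
#' @param vertices V x 3 vertex positions.
#' @param adjacency neighbour index list from \code{\link{meshAdjacency}}.
#' @export
meshReg <- function(vertices, adjacency) {
  sum((vertices - .neighbourMeans(vertices, adjacency))^2)
}

#' One-ring adjacency of a face list
#'
#' Neighbour lists plus the sparse one-ring averaging operator A (row i
#' holds 1/|N_i| on the neighbours of i), so the Laplacian penalty is
#' ||(I - A) V||^2 with gradient 2 (I - A)' (I - A) V.
#'
#' @param faces F x 3 vertex indices (1-based).
#' @param V vertex count.
#' @return list(neighbours = list of index vectors, averaging = sparse A).
#' @export
meshAdjacency <- function(faces, V) {
  nb <- vector("list", V)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  deg <- vapply(nb, length, integer(1))
  ii <- rep(seq_len(V), deg)
  jj <- unlist(nb)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / deg[ii], dims = c(V, V))
  # isolated vertices average to themselves (zero Laplacian contribution)
  iso <- which(deg == 0)
  if (length(iso) > 0)
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(V, V))
  list(neighbours = nb, averaging = A)
}

.neighbourMeans <- function(vertices, adjacency) {
  as.matrix(adjacency$averaging %*% vertices)
}

# gradient of meshReg w.r.t. vertices: with L = I - A (A the averaging
# operator), d/dV ||L V||^2 = 2 L^T L V.
.meshRegGrad <- function(vertices, adjacency) {
  LV <- vertices - .neighbourMeans(vertices, adjacency)
  2 * (LV - as.matrix(Matrix::crossprod(adjacency$averaging, LV)))
}

# ---- pose prior ----

#' Pose priors
#'
#' \code{fitPosePrior} fits a diagonal-covariance Gaussian mixture to a
#' library of plausible poses (rows = length-72 axis-angle vectors) with
#' \pkg{mclust}; \code{standardGaussianPrior} is the closed-form fallback,
#' an isotropic standard Gaussian over the 72 pose dimensions.
#' \code{posePrior} evaluates the negative log-likelihood -log p(theta).
#'
#' @param thetas n x 72 matrix of pose samples.
#' @param G number of mixture components.
#' @return A "posePrior" object.
#' @export
fitPosePrior <- function(thetas, G = 8) {
  stopifnot(ncol(thetas) == 72)
  G <- min(G, max(1, nrow(thetas) %/% 10))
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(thetas, G = G, modelNames = "VVI", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  vars <- array(0, c(72, fit$G))
  for (k in seq_len(fit$G)) vars[, k] <- diag(fit$parameters$variance$sigma[, , k])
  structure(list(type = "gmm", weights = fit$parameters$pro,
                 means = fit$parameters$mean, vars = pmax(vars, 1e-8)),
            class = "posePrior")
}

#' @rdname fitPosePrior
#' @export
standardGaussianPrior <- function() {
  structure(list(type = "gauss"), class = "posePrior")
}

#' @rdname fitPosePrior
#' @param theta length-72 pose vector.
#' @param prior a "posePrior" object.
#' @export
posePrior <- function(theta, prior) {
  if (!inherits(prior, "posePrior")) stop("prior has not been fitted", call. = FALSE)
  if (prior$type == "gauss")
    return(36 * log(2 * pi) + 0.5 * sum(theta^2))
  lk <- vapply(seq_along(prior$weights), function(k) {
    d <- theta - prior$means[, k]
    log(prior$weights[k]) - 0.5 * sum(log(2 * pi * prior$vars[, k])) -
      0.5 * sum(d^2 / prior$vars[, k])
  }, numeric(1))
  m <- max(lk)
  -(m + log(sum(exp(lk - m))))
}

.posePriorGrad <- function(theta, prior) {
  if (prior$type == "gauss") return(theta)
  lk <- vapply(seq_along(prior$weights), function(k) {
    d <- theta - prior$means[, k]
    log(prior$weights[k]) - 0.5 * sum(log(2 * pi * prior$vars[, k])) -
      0.5 * sum(d^2 / prior$vars[, k])
  }, numeric(1))
  r <- exp(lk - max(lk)); r <- r / sum(r)
  g <- numeric(72)
  for (k in seq_along(r)) g <- g + r[k] * (theta - prior$means[, k]) / prior$vars[, k]
  g
}

# ---- analytic gradient engine ----

# Per-frame backpropagation through the LBS forward pass.
# gJ: 24 x 3 upstream gradient on posed joints (before translation removal);
# gV: V x 3 upstream gradient on vertices, or NULL.
# Returns list(theta = 72, trans = 3, beta = 10).
.lbsBackward <- function(model, theta, beta, fk, sh, gJ, gV = NULL,
                         needBeta = TRUE) {
  parents <- model@kinematicTree
  anc <- .jointAncestors()
  W <- model@skinWeights
  V <- nrow(sh$verts)
  G33 <- lapply(fk$G, function(G) G[1:3, 1:3])
  Gt <- lapply(fk$G, function(G) G[1:3, 4])

  # per-joint aggregates C_i (3x3) and d_i (3) collecting vertex and joint
  # sensitivities of the global transforms
  Clist <- vector("list", 24)
  dmat <- t(gJ)                       # 3 x 24, joint part of d_i
  useV <- !is.null(gV)
  qs <- matrix(0, 3, 24)              # vertex-gradient mass per joint
  Dacc <- NULL                        # sum_i (w_i gV) R_i, for the beta grad
  if (useV) {
    Dacc <- matrix(0, V, 3)
    for (i in 1:24) {
      wi <- W[, i]
      if (all(wi == 0)) { Clist[[i]] <- NULL; next }
      gw <- gV * wi                   # V x 3
      P <- crossprod(gw, sh$verts)    # 3 x 3: sum_v w g_v x_v^T
      q <- colSums(gw)
      qs[, i] <- q
      Dacc <- Dacc + gw %*% G33[[i]]
      Clist[[i]] <- P - tcrossprod(q, sh$joints[i, ])  # P - q J_i^T
      dmat[, i] <- dmat[, i] + q
    }
  }

  # With Rel(a -> i) = G_a^{-1} G_i, the per-ancestor aggregate
  # S_a = sum_{i >= a} (C_i RelR^T + d_i Rel_t^T) factorizes as
  # S_a = (U_a - w_a t_a^T) R_a, where U_a = sum_{i >= a} (C_i R_i^T +
  # d_i t_i^T) and w_a = sum_{i >= a} d_i accumulate leaves-to-root.
  Usub <- vector("list", 24)
  wsub <- matrix(0, 3, 24)
  for (i in 24:1) {
    di <- dmat[, i]
    Ui <- base::tcrossprod(di, Gt[[i]])
    if (!is.null(Clist[[i]])) Ui <- Ui + Clist[[i]] %*% t(G33[[i]])
    if (!is.null(Usub[[i]])) Ui <- Ui + Usub[[i]]
    wi <- di + wsub[, i]
    Usub[[i]] <- Ui
    wsub[, i] <- wi
    p <- parents[i]
    if (p > 0L) {
      Usub[[p]] <- if (is.null(Usub[[p]])) Ui else Usub[[p]] + Ui
      wsub[, p] <- wsub[, p] + wi
    }
  }

  gTheta <- numeric(72)
  for (a in 1:24) {
    Sa <- (Usub[[a]] - base::tcrossprod(wsub[, a], Gt[[a]])) %*% G33[[a]]
    Rpar <- if (parents[a] == 0L) diag(3) else G33[[parents[a]]]
    dR <- .rodriguesGrad(theta[(3 * a - 2):(3 * a)], fk$R[[a]])
    for (k in 1:3) {
      B <- Rpar %*% dR[[k]]
      gTheta[3 * (a - 1) + k] <- sum(B * Sa)
    }
  }

  gTrans <- colSums(gJ) + if (useV) colSums(gV) else 0

  # beta gradient: template displacement + shape-dependent skeleton
  gBeta <- numeric(10)
  if (!needBeta)
    return(list(theta = gTheta, trans = gTrans, beta = gBeta))
  JB <- model@jointBasis
  for (m in 1:10) {
    JBm <- matrix(JB[, m], 24, 3)
    # offsets do_a = JB_a - JB_parent(a)
    dGt <- matrix(0, 3, 24)           # dG_i.t / dbeta_m
    for (i in 1:24) {
      p <- parents[i]
      do_i <- if (p == 0L) JBm[i, ] else JBm[i, ] - JBm[p, ]
      Rpar <- if (p == 0L) diag(3) else G33[[p]]
      base <- if (p == 0L) 0 else dGt[, p]
      dGt[, i] <- base + Rpar %*% do_i
    }
    g <- sum(dmat * dGt)
    if (useV) {
      # template term: sum_v sum_i w g_v^T R_i S_v,m
      g <- g + sum(Dacc * matrix(model@shapeBasis[, m], V, 3))
      # A_i.t beta-dependence: -G_i.R dJ_i/dbeta
      for (i in 1:24) {
        if (all(qs[, i] == 0)) next
        g <- g - sum(qs[, i] * (G33[[i]] %*% JBm[i, ]))
      }
    }
    gBeta[m] <- g
  }
  list(theta = gTheta, trans = gTrans, beta = gBeta)
}

#' Map extracted keypoints to fitting targets
#'
#' Converts pixel coordinates to millimetres via the camera scale and
#' negates z (depth inversion) so the body faces the model's forward axis;
#' frames are stacked as a (T, 24, 3) array.
#'
#' @param kps a \linkS4class{Keypoints24} or a list of them (one per frame).
#' @param cameraScale mm per pixel.
#' @return T x 24 x 3 numeric array.
#' @export
mapJoints <- function(kps, cameraScale = 1) {
  if (is(kps, "Keypoints24")) kps <- list(kps)
  T <- length(kps)
  out <- array(0, c(T, 24, 3), dimnames = list(NULL, jointNames24(), c("x", "y", "z")))
  for (t in seq_len(T)) {
    p <- keypointMatrix(kps[[t]])
    out[t, , ] <- cbind(p[, 1] * cameraScale, p[, 2] * cameraScale, -p[, 3])
  }
  out
}

#' Fit configuration for the body-model objective
#'
#' @param lambdas the five term weights (joint, pose prior, shape,
#'   smoothness, mesh Laplacian).
#' @param jointWeights 24 positive per-joint weights of the joint term.
#' @param lr Adam learning rate (mm-scale parameters use lr * lrTransScale).
#' @param iters iterations of the three stages (global orientation +
#'   translation; full pose; pose + shape).
#' @param prior a "posePrior" (default the closed-form standard Gaussian).
#' @param polish run a final quasi-Newton (L-BFGS-B) refinement with the
#'   same analytic gradients.
#' @param polishIters iteration cap of the polish stage.
#' @param lrTransScale learning-rate multiplier for translations (mm).
#' @param seed integer seed (initialization is deterministic; kept for
#'   interface stability).
#' @return Named list.
#' @export
fitConfig <- function(lambdas = c(1, 0.01, 0.001, 0.1, 0.01),
                      jointWeights = rep(1, 24), lr = 0.05,
                      iters = c(global = 60L, pose = 120L, pose_shape = 80L),
                      prior = standardGaussianPrior(), polish = TRUE,
                      polishIters = 150L, lrTransScale = 400, seed = 0L) {
  stopifnot(length(lambdas) == 5, all(lambdas >= 0), all(jointWeights > 0))
  list(lambdas = lambdas, jointWeights = jointWeights, lr = lr,
       iters = iters, prior = prior, polish = polish,
       polishIters = as.integer(polishIters), lrTransScale = lrTransScale,
       seed = as.integer(seed))
}

# objective + gradient over the whole sequence for the active parameter set
.seqObjective <- function(par, layout, Jtarget, model, cfg, adjacency, needGrad = TRUE,
                          needBeta = TRUE) {
  T <- layout$T
  lam <- cfg$lambdas
  thetas <- matrix(0, T, 72); trans <- matrix(0, T, 3)
  for (t in seq_len(T)) {
    thetas[t, ] <- par[layout$thetaIdx[[t]]]
    trans[t, ] <- par[layout$transIdx[[t]]]
  }
  beta <- par[layout$betaIdx]
  useMesh <- lam[5] > 0
  sh <- .shaped(model, beta)
  Jfit <- array(0, c(T, 24, 3))
  fks <- vector("list", T)
  verts <- vector("list", T)
  lJoint <- lPose <- lMesh <- 0
  V <- nrow(model@templateVertices)
  W <- model@skinWeights
  for (t in seq_len(T)) {
    fk <- .fk(sh$joints, thetas[t, ])
    fks[[t]] <- fk
    Jfit[t, , ] <- sweep(fk$joints, 2, trans[t, ], `+`)
    lJoint <- lJoint + jointLoss(Jfit[t, , ], Jtarget[t, , ], cfg$jointWeights)
    if (lam[2] > 0) lPose <- lPose + posePrior(thetas[t, ], cfg$prior)
    if (useMesh) {
      vt <- matrix(0, V, 3)
      for (j in 1:24) {
        wj <- W[, j]
        if (all(wj == 0)) next
        Rj <- fk$G[[j]][1:3, 1:3]
        tj <- fk$G[[j]][1:3, 4] - Rj %*% sh$joints[j, ]
        vt <- vt + wj * (sh$verts %*% t(Rj) + matrix(tj, V, 3, byrow = TRUE))
      }
      verts[[t]] <- vt
      lMesh <- lMesh + meshReg(vt, adjacency)
    }
  }
  lShape <- shapeReg(beta)
  lSmooth <- smoothReg(Jfit)
  total <- lam[1] * lJoint + lam[2] * lPose + lam[3] * lShape +
    lam[4] * lSmooth + lam[5] * lMesh
  terms <- c(joint = lJoint, pose = lPose, shape = lShape,
             smooth = lSmooth, mesh = lMesh)
  if (!needGrad)
    return(list(value = total, terms = terms, Jfit = Jfit,
                lastVerts = verts[[T]] %||% NULL))
  grad <- numeric(length(par))
  gBetaTotal <- 2 * lam[3] * beta
  for (t in seq_len(T)) {
    gJ <- 2 * lam[1] * (cfg$jointWeights * (Jfit[t, , ] - Jtarget[t, , ]))
    if (T >= 2) {
      if (t > 1) gJ <- gJ + 2 * lam[4] * (Jfit[t, , ] - Jfit[t - 1, , ])
      if (t < T) gJ <- gJ + 2 * lam[4] * (Jfit[t, , ] - Jfit[t + 1, , ])
    }
    gV <- if (useMesh) lam[5] * .meshRegGrad(verts[[t]], adjacency) else NULL
    bk <- .lbsBackward(model, thetas[t, ], beta, fks[[t]], sh, gJ, gV, needBeta)
    gTheta <- bk$theta
    if (lam[2] > 0) gTheta <- gTheta + lam[2] * .posePriorGrad(thetas[t, ], cfg$prior)
    grad[layout$thetaIdx[[t]]] <- gTheta
    grad[layout$transIdx[[t]]] <- bk$trans
    gBetaTotal <- gBetaTotal + bk$beta
  }
  grad[layout$betaIdx] <- gBetaTotal
  list(value = total, terms = terms, grad = grad, Jfit = Jfit,
       lastVerts = verts[[T]] %||% NULL)
}

#' Fit the body model to a sequence of target joints
#'
#' Staged optimization of the five-term objective: global orientation and
#' translation first, then the full pose, then pose and shape jointly,
#' each stage run with Adam on the analytic gradients; an optional
#' quasi-Newton polish refines the final stage. Pose and translation are
#' per frame; shape is shared across the sequence. Initialization is
#' theta = 0, beta = 0, translation = target pelvis.
#'
#' @param Jtarget T x 24 x 3 target joints (mm), e.g. from
#'   \code{\link{mapJoints}}.
#' @param model a \linkS4class{ToyBodyModel}.
#' @param cfg a \code{\link{fitConfig}}.
#' @return A \linkS4class{FitResult}.
#' @export
fitSequence <- function(Jtarget, model, cfg = fitConfig()) {
  if (length(dim(Jtarget)) == 2) Jtarget <- array(Jtarget, c(1, dim(Jtarget)))
  T <- dim(Jtarget)[1]
  stopifnot(dim(Jtarget)[2] == 24, dim(Jtarget)[3] == 3)
  nPar <- T * 75 + 10
  layout <- list(T = T,
                 thetaIdx = lapply(seq_len(T), function(t) (t - 1) * 75 + 1:72),
                 transIdx = lapply(seq_len(T), function(t) (t - 1) * 75 + 73:75),
                 betaIdx = T * 75 + 1:10)
  par <- numeric(nPar)
  for (t in seq_len(T))
    par[layout$transIdx[[t]]] <- Jtarget[t, 1, ] - model@restJoints[1, ]
  adjacency <- if (cfg$lambdas[5] > 0)
    meshAdjacency(model@faces, nrow(model@templateVertices)) else NULL

  # per-parameter scale: translations live on the mm scale
  scale <- rep(1, nPar)
  for (t in seq_len(T)) scale[layout$transIdx[[t]]] <- cfg$lrTransScale

  stages <- list(
    list(n = cfg$iters[1], active = unlist(lapply(seq_len(T), function(t)
      c(layout$thetaIdx[[t]][1:3], layout$transIdx[[t]])))),
    list(n = cfg$iters[2], active = unlist(lapply(seq_len(T), function(t)
      c(layout$thetaIdx[[t]], layout$transIdx[[t]])))),
    list(n = cfg$iters[3], active = c(unlist(lapply(seq_len(T), function(t)
      c(layout$thetaIdx[[t]], layout$transIdx[[t]]))), layout$betaIdx)))

  trace <- NULL
  m <- numeric(nPar); v <- numeric(nPar)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  iterGlobal <- 0L
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    if (st$n <= 0) next
    act <- st$active
    stageNeedsBeta <- si == 3L
    m[] <- 0; v[] <- 0
    for (it in seq_len(st$n)) {
      ob <- .seqObjective(par, layout, Jtarget, model, cfg, adjacency, needGrad = TRUE,
                          needBeta = stageNeedsBeta)
      if (!is.finite(ob$value)) {
        bad <- names(ob$terms)[!is.finite(ob$terms)]
        stop("non-finite loss in term(s): ", paste(bad, collapse = ", "), call. = FALSE)
      }
      iterGlobal <- iterGlobal + 1L
      trace <- rbind(trace, data.frame(iter = iterGlobal, total = ob$value,
                                       joint = ob$terms["joint"], pose = ob$terms["pose"],
                                       shape = ob$terms["shape"], smooth = ob$terms["smooth"],
                                       mesh = ob$terms["mesh"]))
      g <- ob$grad[act]
      m[act] <- b1 * m[act] + (1 - b1) * g
      v[act] <- b2 * v[act] + (1 - b2) * g * g
      mh <- m[act] / (1 - b1^it); vh <- v[act] / (1 - b2^it)
      par[act] <- par[act] - cfg$lr * scale[act] * mh / (sqrt(vh) + epsA)
    }
  }
  if (isTRUE(cfg$polish)) {
    act <- stages[[3]]$active
    fn <- function(p) { q <- par; q[act] <- p
      .seqObjective(q, layout, Jtarget, model, cfg, adjacency, needGrad = FALSE)$value }
    gr <- function(p) { q <- par; q[act] <- p
      .seqObjective(q, layout, Jtarget, model, cfg, adjacency, needGrad = TRUE)$grad[act] }
    # run the polish budget in chunks of 400 iterations; restarting
    # L-BFGS-B resets its curvature memory, which keeps progress alive in
    # the flat, ill-conditioned valleys of the axis-angle parametrization
    left <- cfg$polishIters
    while (left > 0) {
      op <- stats::optim(par[act], fn, gr, method = "L-BFGS-B",
                         control = list(maxit = min(400L, left), factr = 1,
                                        pgtol = 0))
      par[act] <- op$par
      left <- left - 400L
      if (op$convergence == 0) break
    }
  }
  ob <- .seqObjective(par, layout, Jtarget, model, cfg, adjacency, needGrad = FALSE)
  iterGlobal <- iterGlobal + 1L
  trace <- rbind(trace, data.frame(iter = iterGlobal, total = ob$value,
                                   joint = ob$terms["joint"], pose = ob$terms["pose"],
                                   shape = ob$terms["shape"], smooth = ob$terms["smooth"],
                                   mesh = ob$terms["mesh"]))
  rownames(trace) <- NULL
  thetas <- t(vapply(seq_len(T), function(t) par[layout$thetaIdx[[t]]], numeric(72)))
  trans <- t(vapply(seq_len(T), function(t) par[layout$transIdx[[t]]], numeric(3)))
  lastVerts <- ob$lastVerts
  if (is.null(lastVerts)) {
    fwd <- lbsForward(model, thetas[T, ], par[layout$betaIdx], trans[T, ])
    lastVerts <- fwd$vertices
  }
  new("FitResult", theta = matrix(thetas, T, 72), beta = par[layout$betaIdx],
      translation = matrix(trans, T, 3), lossTrace = trace,
      joints = ob$Jfit, vertices = lastVerts)
}
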