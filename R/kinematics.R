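# Internal kinematics shared by the synthetic generator and the body-model
# fit: the canonical 24-joint schema, axis-angle rotations (Rodrigues) with
# analytic derivatives, and forward kinematics along the kinematic tree.

#' Canonical 24-joint schema
#'
#' Ordered joint names of the canonical 24-joint skeleton used throughout
#' the package (pelvis-rooted, left/right refer to image-frame left/right
#' for a person facing the camera). The order matches the joint set of
#' standard 72-parameter skinned body models.
#'
#' @return Character vector of 24 joint names.
#' @export
#' @examples
#' jointNames24()
jointNames24 <- function() {
  c("pelvis", "hip_l", "hip_r", "spine1", "knee_l", "knee_r", "spine2",
    "ankle_l", "ankle_r", "spine3", "foot_l", "foot_r", "neck",
    "collar_l", "collar_r", "head", "shoulder_l", "shoulder_r",
    "elbow_l", "elbow_r", "wrist_l", "wrist_r", "hand_l", "hand_r")
}

# Parent index of each joint (0 = root).
.jointParents <- function() {
  c(0L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 10L, 10L,
    13L, 14L, 15L, 17L, 18L, 19L, 20L, 21L, 22L)
}

# Rodrigues: axis-angle 3-vector to 3x3 rotation matrix.
.rodrigues <- function(v) {
  th <- sqrt(sum(v * v))
  if (th < 1e-12) {
    K <- .crossMat(v)
    return(diag(3) + K)  # first-order expansion near zero
  }
  k <- v / th
  K <- .crossMat(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.crossMat <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Analytic derivative of the Rodrigues rotation w.r.t. each axis-angle
# component: returns a list of three 3x3 matrices dR/dv_k (Gallego & Yezzi
# closed form, with the small-angle limit dR/dv_k -> [e_k]_x). R may be
# passed in when already computed by the forward pass.
.rodriguesGrad <- function(v, R = NULL) {
  th2 <- v[1] * v[1] + v[2] * v[2] + v[3] * v[3]
  if (th2 < 1e-16) {
    return(list(matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),
                matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3, 3),
                matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3)))
  }
  if (is.null(R)) R <- .rodrigues(v)
  ImR <- diag(3) - R
  lapply(1:3, function(k) {
    # w = v_k * v + v x (I - R) e_k
    u <- ImR[, k]
    w <- v[k] * v + c(v[2] * u[3] - v[3] * u[2],
                      v[3] * u[1] - v[1] * u[3],
                      v[1] * u[2] - v[2] * u[1])
    (.crossMat(w) %*% R) / th2
  })
}

# Forward kinematics. restJoints: 24x3 rest positions; theta: length-72
# axis-angle stack. Returns list(joints = 24x3 posed joint positions,
# G = list of 24 4x4 global transforms, R = list of local rotations).
# Global transform of joint i maps rest-frame coordinates to posed
# coordinates: G_i = G_parent %*% [R_i | (J_i - J_parent)].
.fk <- function(restJoints, theta) {
  parents <- .jointParents()
  G <- vector("list", 24L)
  Rl <- vector("list", 24L)
  joints <- matrix(0, 24, 3)
  for (i in 1:24) {
    Ri <- .rodrigues(theta[(3 * i - 2):(3 * i)])
    Rl[[i]] <- Ri
    off <- if (parents[i] == 0L) restJoints[i, ] else restJoints[i, ] - restJoints[parents[i], ]
    Li <- rbind(cbind(Ri, off), c(0, 0, 0, 1))
    G[[i]] <- if (parents[i] == 0L) Li else G[[parents[i]]] %*% Li
    joints[i, ] <- G[[i]][1:3, 4]
  }
  list(joints = joints, G = G, R = Rl)
}

# Ancestor chain (self first, then up to the root) per joint, cached.
.jointAncestors <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    parents <- .jointParents()
    out <- lapply(1:24, function(i) {
      ch <- i
      while (parents[ch[length(ch)]] != 0L) ch <- c(ch, parents[ch[length(ch)]])
      ch
    })
    cache <<- out
    out
  }
})
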