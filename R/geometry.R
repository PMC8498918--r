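# 3D geometry primitives shared by calibration, triangulation and kinematics.

#' Convert an axis-angle rotation vector to a rotation matrix
#'
#' Rodrigues' formula. The direction of `r` is the rotation axis and its
#' norm the rotation angle in radians.
#'
#' @param r Numeric length-3 rotation vector.
#' @return A 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) {
    K <- skew(r)
    return(diag(3) + K) # first-order expansion near identity
  }
  k <- r / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Convert a rotation matrix to an axis-angle rotation vector
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric length-3 rotation vector with norm in `[0, pi]`.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- clamp((sum(diag(R)) - 1) / 2, -1, 1)
  th <- acos(ct)
  if (th < 1e-10) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (abs(pi - th) < 1e-6) {
    # near pi the antisymmetric part vanishes; recover axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using the largest component
    i <- which.max(ax)
    s <- sign(B[i, ])
    s[s == 0] <- 1
    ax <- ax * s * sign(ax[i])
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

# compose two rigid transforms (R1,t1) after (R2,t2): x -> R1 (R2 x + t2) + t1
compose_pose <- function(R1, t1, R2, t2) {
  list(R = R1 %*% R2, t = as.numeric(R1 %*% t2 + t1))
}

invert_pose <- function(R, t) {
  list(R = t(R), t = as.numeric(-t(R) %*% t))
}

#' Planar homography by the normalized direct linear transform
#'
#' Maps 2D source points (e.g. board coordinates on its plane) to 2D
#' destination points (e.g. pixels), `dst ~ H src`.
#'
#' @param src,dst Nx2 matrices of corresponding points, N >= 4.
#' @return A 3x3 homography matrix with `H[3,3] = 1`.
#' @export
homography_dlt <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  stopifnot(n >= 4, nrow(dst) == n)
  norm_pts <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums((p - matrix(mu, n, 2, byrow = TRUE))^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    Tm <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
    list(T = Tm, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  z0 <- numeric(n); z1 <- rep(1, n)
  A <- rbind(
    cbind(-x, -y, -z1, z0, z0, z0, u * x, u * y, u),
    cbind(z0, z0, z0, -x, -y, -z1, v * x, v * y, v)
  )
  # smallest right singular vector (via the normal matrix, so it exists
  # even for the minimal 4-point system whose A is 8 x 9)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H / H[3, 3]
}

# Planar pose (R, t) of a z=0 plane from homography and intrinsics K.
# Returns NULL when the decomposition is degenerate.
pose_from_homography <- function(H, K) {
  Hn <- solve(K, H)
  l1 <- sqrt(sum(Hn[, 1]^2)); l2 <- sqrt(sum(Hn[, 2]^2))
  l <- (l1 + l2) / 2
  if (!is.finite(l) || l < 1e-12) return(NULL)
  Hn <- Hn / l
  t <- Hn[, 3]
  if (t[3] < 0) { Hn <- -Hn; t <- Hn[, 3] } # plane in front of the camera
  r1 <- Hn[, 1]; r2 <- Hn[, 2]
  R0 <- cbind(r1, r2, pracma_cross(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  list(R = R, t = as.numeric(t))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Align two point sets by a similarity transform
#'
#' Least-squares Procrustes alignment `Y ~ s * R X + t` (Kabsch/Umeyama).
#' Used to compare reconstructed rigs or trajectories with ground truth,
#' since a multi-camera reconstruction is only identifiable up to a global
#' rotation, translation and scale.
#'
#' @param X,Y Nx3 matrices of corresponding points.
#' @param scale Estimate a scale factor (default `TRUE`).
#' @return A list with `R`, `t`, `s`, the aligned points `Xa` and the
#'   root-mean-square residual `rmsd`.
#' @export
align_similarity <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  Xo <- X[ok, , drop = FALSE]; Yo <- Y[ok, , drop = FALSE]
  stopifnot(nrow(Xo) >= 3)
  mx <- colMeans(Xo); my <- colMeans(Yo)
  Xc <- sweep(Xo, 2, mx); Yc <- sweep(Yo, 2, my)
  S <- t(Yc) %*% Xc / nrow(Xc)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (scale) sum(diag(D) * sv$d) / mean(rowSums(Xc^2)) else 1
  t_ <- my - s * as.numeric(R %*% mx)
  Xa <- sweep(s * (X %*% t(R)), 2, t_, `+`)
  rmsd <- sqrt(mean(rowSums((Xa[ok, , drop = FALSE] - Yo)^2)))
  list(R = R, t = t_, s = s, Xa = Xa, rmsd = rmsd)
}

# Weiszfeld geometric median of rows; falls back to the componentwise
# median if the iteration stalls.
geometric_median <- function(X, tol = 1e-10, max_iter = 100) {
  X <- as.matrix(X)
  if (nrow(X) == 1) return(as.numeric(X))
  m <- apply(X, 2, median)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    if (any(d < 1e-12)) return(m)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}
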