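# Joint-angle extraction from 3D trajectories and gait feature
# construction.

#' Flexion angle at a joint from three 3D points
#'
#' Angle in degrees between the unit vectors `p_i - p_j` and
#' `p_k - p_j`, where `p_j` is the joint vertex; the dot product is
#' clamped to [-1, 1] before the arccosine. Vectorized over rows.
#'
#' @param p_i,p_j,p_k Nx3 matrices (or length-3 vectors).
#' @return Numeric vector of angles in `[0, 180]` degrees; missing where
#'   a segment has zero length or a coordinate is missing.
#' @export
flexion_angle <- function(p_i, p_j, p_k) {
  to_mat <- function(p) matrix(as.numeric(p), ncol = 3)
  a <- to_mat(p_i) - to_mat(p_j)
  b <- to_mat(p_k) - to_mat(p_j)
  na_ <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  bad <- !is.finite(na_) | !is.finite(nb) | na_ < 1e-12 | nb < 1e-12
  ct <- rowSums(a * b) / (na_ * nb)
  ang <- acos(clamp(ct, -1, 1)) * 180 / pi
  ang[bad] <- NA_real_
  ang
}

# body frame from three reference keypoints per frame:
# x = anterior direction, z = dorsal direction orthogonalized to x,
# y = z cross x (Gram-Schmidt, per frame)
body_frame_from_keypoints <- function(origin, anterior, dorsal) {
  x <- anterior - origin
  x <- x / sqrt(sum(x^2))
  z <- dorsal - origin
  z <- z - sum(z * x) * x
  nz <- sqrt(sum(z^2))
  if (!is.finite(nz) || nz < 1e-12) return(NULL)
  z <- z / nz
  y <- pracma_cross(z, x)
  cbind(x, y, z)
}

# Decompose a relative rotation between consecutive segment frames.
# By construction of the frames (z along the distal segment, x the
# proximal direction orthogonalized against z) the relative rotation is
# exactly Rz(rotation) Ry(theta); flexion is reported as 180 - theta so
# it matches the three-point vertex angle. Near-straight or fully folded
# configurations (theta near 0 or 180) leave the rotation undefined
# (gimbal lock) and it is reported missing.
decompose_segment_rotation <- function(R, gimbal_tol = 1e-7) {
  R <- unname(R)
  theta <- acos(clamp(R[3, 3], -1, 1)) * 180 / pi
  st <- sin(theta * pi / 180)
  rot <- if (abs(st) < gimbal_tol) NA_real_ else {
    atan2(R[2, 3], R[1, 3]) * 180 / pi
  }
  c(rotation = rot, flexion = 180 - theta)
}

#' Joint angles along a kinematic chain
#'
#' Two-stage inverse kinematics. Stage 1 assigns each joint that has a
#' distal segment an orthonormal frame: z along the distal segment
#' (pointing away from the body), x the proximal segment direction
#' orthogonalized against z, y = z cross x. The first joint has no
#' proximal segment, so its x is pinned from the body frame (the body's
#' -z axis plays the proximal role); the body frame itself supplies the
#' reference axes. Stage 2 decomposes each relative rotation between
#' consecutive frames as intrinsic Euler angles in {z, y, x} order,
#' read as (rotation, flexion, abduction). With segment-aligned frames
#' the relative rotation is exactly `Rz(rotation) Ry(theta)`, so the
#' abduction channel is emitted only for the first joint (the
#' field's convention that only the most proximal joint may abduct; it
#' is identically zero under the body-axis pinning used here), and the
#' unobservable twist of the terminal segment about its own axis is
#' never parameterized (equivalently, the most distal joint cannot
#' rotate). Flexion is reported as `180 - theta` degrees so that, at
#' every interior vertex, it equals the three-point [flexion_angle()].
#'
#' @param traj Trajectory tibble (frame, joint, x, y, z).
#' @param chain Ordered character vector of >= 3 joint names, body to
#'   tip.
#' @param body_frame Either `"world"` (identity axes) or a character
#'   vector of three reference keypoint names
#'   `(origin, anterior, dorsal)` present in `traj`, from which
#'   per-frame body axes are built by Gram-Schmidt (x toward anterior,
#'   z toward dorsal).
#' @return Tibble (frame, joint, kind, value_deg) with kinds
#'   `rotation`, `flexion`, `abduction`. The relative rotation between
#'   frame i and frame i+1 is attributed to the vertex joint
#'   `chain[i+1]`; the body-to-first-frame rotation is attributed to
#'   `chain[1]`.
#' @export
chain_angles <- function(traj, chain, body_frame = "world") {
  if (length(chain) < 3) abort("chain must have at least 3 joints")
  frames <- sort(unique(traj$frame))
  grab <- function(j) {
    d <- traj[traj$joint == j, ]
    m <- matrix(NA_real_, length(frames), 3)
    m[match(d$frame, frames), ] <- as.matrix(d[, c("x", "y", "z")])
    m
  }
  pos <- lapply(chain, grab)
  use_ref <- !identical(body_frame, "world")
  if (use_ref) {
    stopifnot(length(body_frame) == 3)
    ref <- lapply(body_frame, grab)
  }
  n <- length(chain)
  res <- list()
  emit <- function(fi, joint, kind, value) {
    res[[length(res) + 1L]] <<- list(frame = frames[fi], joint = joint,
                                     kind = kind, value_deg = value)
  }
  for (fi in seq_along(frames)) {
    P <- do.call(rbind, lapply(pos, function(m) m[fi, ]))
    M0 <- if (use_ref) {
      o <- ref[[1]][fi, ]; a <- ref[[2]][fi, ]; d <- ref[[3]][fi, ]
      if (anyNA(c(o, a, d))) NULL else body_frame_from_keypoints(o, a, d)
    } else diag(3)
    # stage 1: segment frames for joints 1..n-1. When the proximal
    # direction is parallel to the segment (a perfectly straight pair),
    # the frame's x axis is arbitrary: pick any perpendicular and flag
    # the frame so rotations measured in it are reported missing.
    Ms <- vector("list", n - 1L)
    degen <- logical(n - 1L)
    for (i in seq_len(n - 1L)) {
      zv <- P[i + 1, ] - P[i, ]
      nz <- sqrt(sum(zv^2))
      if (anyNA(zv) || nz < 1e-12) next
      zv <- zv / nz
      xv <- if (i == 1) {
        if (is.null(M0)) next
        -M0[, 3] # body -z plays the proximal role for the first joint
      } else {
        P[i - 1, ] - P[i, ]
      }
      if (anyNA(xv)) next
      xv <- xv - sum(xv * zv) * zv
      nx <- sqrt(sum(xv^2))
      if (nx < 1e-9) {
        degen[i] <- TRUE
        ref <- if (abs(zv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        xv <- ref - sum(ref * zv) * zv
        nx <- sqrt(sum(xv^2))
      }
      xv <- xv / nx
      Ms[[i]] <- cbind(xv, pracma_cross(zv, xv), zv)
    }
    # stage 2: body -> frame 1 (joint 1), then frame i -> frame i+1
    # (vertex joint i+1)
    if (!is.null(M0) && !is.null(Ms[[1]])) {
      ang <- decompose_segment_rotation(t(M0) %*% Ms[[1]])
      emit(fi, chain[1], "rotation", unname(ang["rotation"]))
      emit(fi, chain[1], "flexion", unname(ang["flexion"]))
      emit(fi, chain[1], "abduction",
           if (is.na(ang["rotation"])) NA_real_ else 0)
    }
    for (i in seq_len(n - 2L)) {
      if (is.null(Ms[[i]]) || is.null(Ms[[i + 1]])) next
      ang <- decompose_segment_rotation(t(Ms[[i]]) %*% Ms[[i + 1]])
      rot <- if (degen[i]) NA_real_ else unname(ang["rotation"])
      emit(fi, chain[i + 1], "rotation", rot)
      emit(fi, chain[i + 1], "flexion", unname(ang["flexion"]))
    }
  }
  dplyr::bind_rows(res)
}

#' Forward kinematics of a chain from joint angles
#'
#' Rebuilds 3D joint positions from segment lengths and the
#' (rotation, flexion) angles produced by [chain_angles()]: each frame
#' is the previous frame rotated by `Rz(rotation) Ry(180 - flexion)`,
#' and each joint sits one segment length along its frame's z axis.
#' The exact inverse of [chain_angles()] for non-degenerate poses. The
#' last segment's rotation, which [chain_angles()] does not report, is
#' taken as 0 (it does not move any point).
#'
#' @param rotation,flexion Numeric vectors of length `n_seg` (degrees);
#'   entries follow the [chain_angles()] attribution (element 1 is the
#'   first joint relative to the body, element i the vertex joint i).
#' @param lengths Segment lengths, length `n_seg`.
#' @param base Position of the first joint.
#' @param body_frame 3x3 body axes matrix.
#' @return `(n_seg + 1) x 3` matrix of joint positions.
#' @export
forward_kinematics_chain <- function(rotation, flexion, lengths,
                                     base = c(0, 0, 0),
                                     body_frame = diag(3)) {
  d2r <- pi / 180
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  n_seg <- length(lengths)
  stopifnot(length(rotation) == n_seg, length(flexion) == n_seg)
  rotation[is.na(rotation)] <- 0
  P <- matrix(NA_real_, n_seg + 1, 3)
  P[1, ] <- base
  M <- body_frame
  for (i in seq_len(n_seg)) {
    M <- M %*% Rz(rotation[i] * d2r) %*% Ry((180 - flexion[i]) * d2r)
    P[i + 1, ] <- P[i, ] + lengths[i] * M[, 3]
  }
  P
}

#' Angular velocities of an angle series
#'
#' Forward difference scaled by the frame rate. Rotation and abduction
#' angles are circularly unwrapped first so a 359 -> 1 degree step reads
#' as +2 deg/frame.
#'
#' @param angles Tibble (frame, joint, kind, value_deg) from
#'   [chain_angles()].
#' @param frame_rate Frames per second.
#' @return Same shape with `value_deg` replaced by `deg_per_s`.
#' @export
angle_derivatives <- function(angles, frame_rate) {
  angles |>
    dplyr::group_by(.data$joint, .data$kind) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(value_unwrapped = if (.data$kind[1] %in%
                                        c("rotation", "abduction")) {
      unwrap_angle(.data$value_deg, period = 360)
    } else .data$value_deg) |>
    dplyr::mutate(deg_per_s = (dplyr::lead(.data$value_unwrapped) -
                                 .data$value_unwrapped) * frame_rate) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("frame", "joint", "kind", "deg_per_s")))
}

#' Windowed gait feature matrix
#'
#' Slices each angle series (and its derivative) into chunks of
#' `window` samples advancing by `stride`, concatenating all angles and
#' derivatives per chunk into one row: with A angle series the rows have
#' `window * A * 2` columns and there are `floor((T - window)/stride) + 1`
#' rows. Columns are standardized (mean 0, sd 1) over rows; zero-variance
#' columns are centered only, with a warning.
#'
#' @param angles Wide numeric matrix or data frame, frames x angles.
#' @param window Chunk length in samples (e.g. 32 or 24).
#' @param stride Advance between chunks (default 8).
#' @param frame_rate Frame rate used for the derivative term.
#' @param standardize Standardize columns (default TRUE).
#' @return Feature matrix.
#' @export
build_feature_vectors <- function(angles, window, stride = 8L,
                                  frame_rate = 1, standardize = TRUE) {
  A <- as.matrix(angles)
  TT <- nrow(A)
  if (window > TT) {
    return(matrix(numeric(0), 0, window * ncol(A) * 2))
  }
  D <- rbind(diff(A), NA) * frame_rate
  full <- cbind(A, D)
  n_rows <- floor((TT - window) / stride) + 1L
  out <- matrix(NA_real_, n_rows, window * ncol(full))
  for (r in seq_len(n_rows)) {
    s <- (r - 1L) * stride + 1L
    out[r, ] <- as.numeric(full[s:(s + window - 1L), ])
  }
  if (standardize && n_rows > 1) {
    mu <- colMeans(out, na.rm = TRUE)
    sg <- apply(out, 2, sd, na.rm = TRUE)
    zero_var <- !is.finite(sg) | sg < 1e-12
    if (any(zero_var)) {
      warn(sprintf("%d zero-variance feature column(s) centered only",
                   sum(zero_var)))
      sg[zero_var] <- 1
    }
    out <- sweep(sweep(out, 2, mu), 2, sg, `/`)
  }
  out
}

#' Step phase from a band-passed joint angle
#'
#' First-order Butterworth band-pass (applied forward and backward, so
#' zero phase), then the instantaneous phase of the analytic signal.
#'
#' @param x Numeric angle series (degrees or any unit).
#' @param frame_rate Sampling rate in Hz; must exceed twice the upper
#'   band edge.
#' @param band Pass band in Hz (default 3-60).
#' @return Phase series in `[-pi, pi)`; all-missing for a constant
#'   input.
#' @export
estimate_phase <- function(x, frame_rate, band = c(3, 60)) {
  if (frame_rate <= 2 * band[2]) {
    abort("frame_rate must exceed twice the upper band edge")
  }
  if (!is.finite(sd(x)) || sd(x) < 1e-12) {
    return(rep(NA_real_, length(x)))
  }
  bf <- signal::butter(1, band / (frame_rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  ph <- Arg(analytic_signal(xf))
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  ph
}
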