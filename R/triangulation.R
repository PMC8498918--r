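# 3D reconstruction from multi-camera 2D keypoints.

#' Define a skeleton
#'
#' @param joints Ordered character vector of joint names.
#' @param limbs Tibble with columns `joint_a`, `joint_b` and optionally
#'   `weight` (limb-length variance weight; flexible limbs such as a
#'   tarsus or shoulder are conventionally down-weighted to 0.5).
#' @param chains List of ordered joint-name vectors, each a kinematic
#'   chain from body to tip.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(joints, limbs = NULL, chains = list()) {
  joints <- as.character(joints)
  if (is.null(limbs)) {
    limbs <- tibble(joint_a = character(), joint_b = character(),
                    weight = numeric())
  }
  limbs <- as_tibble(limbs)
  if (!"weight" %in% names(limbs)) limbs$weight <- 1
  bad <- setdiff(c(limbs$joint_a, limbs$joint_b, unlist(chains)), joints)
  if (length(bad)) abort(paste("unknown joints:", paste(bad, collapse = ", ")))
  for (ch in chains) {
    if (anyDuplicated(ch)) abort("chains must be simple paths")
  }
  structure(list(joints = joints, limbs = limbs, chains = chains),
            class = "skeleton")
}

# assemble DLT rows and solve one point; obs: list of (cam, xy)
solve_dlt <- function(normed, mats) {
  A <- do.call(rbind, purrr::map2(normed, mats, function(nx, M) {
    rbind(nx[1] * M[3, ] - M[1, ],
          nx[2] * M[3, ] - M[2, ])
  }))
  v <- svd(A, nu = 0)$v[, 4]
  if (abs(v[4]) < 1e-14) return(rep(NA_real_, 3))
  v[1:3] / v[4]
}

#' Triangulate 2D keypoints into 3D
#'
#' Linear (SVD/DLT) triangulation or RANSAC-style exhaustive pair search.
#' For `method = "ransac"`, all camera pairs are triangulated and the
#' point minimizing the two-view squared reprojection error is returned,
#' which suppresses single-camera outliers.
#'
#' @param detections Tibble (camera, frame, joint, x, y); rows with
#'   missing coordinates are ignored.
#' @param rig A `camera_rig`.
#' @param method `"linear"` or `"ransac"`.
#' @param min_cameras Minimum views per point (>= 2).
#' @return Tibble (frame, joint, x, y, z, error, n_cams); `error` is the
#'   mean reprojection error in pixels over contributing cameras.
#' @export
triangulate_points <- function(detections, rig,
                               method = c("linear", "ransac"),
                               min_cameras = 2L) {
  method <- match.arg(method)
  min_cameras <- max(2L, min_cameras)
  det <- detections[is.finite(detections$x) & is.finite(detections$y), ]
  det$cam_idx <- match(det$camera, names(rig))
  if (anyNA(det$cam_idx)) abort("detections reference cameras not in the rig")

  # precompute per-camera [R|t] and normalized coordinates
  mats <- lapply(rig, function(cm) {
    cbind(rotvec_to_matrix(cm$rotation), cm$translation)
  })
  det$nx <- NA_real_; det$ny <- NA_real_
  for (c_i in seq_along(rig)) {
    idx <- which(det$cam_idx == c_i)
    if (!length(idx)) next
    nrm <- pixels_to_normalized(cbind(det$x[idx], det$y[idx]), rig[[c_i]])
    det$nx[idx] <- nrm[, 1]; det$ny[idx] <- nrm[, 2]
  }
  det <- det[is.finite(det$nx), ]

  groups <- split(seq_len(nrow(det)), paste(det$frame, det$joint, sep = "\r"))
  out <- purrr::map_dfr(groups, function(idx) {
    frame <- det$frame[idx[1]]; joint <- det$joint[idx[1]]
    cams <- det$cam_idx[idx]
    keep <- !duplicated(cams)
    idx <- idx[keep]; cams <- cams[keep]
    if (length(idx) < min_cameras) {
      return(tibble(frame = frame, joint = joint, x = NA_real_, y = NA_real_,
                    z = NA_real_, error = NA_real_, n_cams = length(idx)))
    }
    normed <- lapply(idx, function(i) c(det$nx[i], det$ny[i]))
    obs_px <- cbind(det$x[idx], det$y[idx])
    if (method == "linear") {
      p <- solve_dlt(normed, mats[cams])
    } else {
      pairs <- utils::combn(seq_along(idx), 2)
      best <- NULL; best_cost <- Inf
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        pk <- solve_dlt(normed[c(a, b)], mats[cams[c(a, b)]])
        if (anyNA(pk)) next
        pa <- project_points(matrix(pk, 1), rig[[cams[a]]])
        pb <- project_points(matrix(pk, 1), rig[[cams[b]]])
        cost <- sum((pa - obs_px[a, ])^2) + sum((pb - obs_px[b, ])^2)
        if (is.finite(cost) && cost < best_cost) { best_cost <- cost; best <- pk }
      }
      p <- if (is.null(best)) rep(NA_real_, 3) else best
    }
    if (anyNA(p)) {
      return(tibble(frame = frame, joint = joint, x = NA_real_, y = NA_real_,
                    z = NA_real_, error = NA_real_, n_cams = length(idx)))
    }
    errs <- vapply(seq_along(idx), function(i) {
      pr <- project_points(matrix(p, 1), rig[[cams[i]]])
      sqrt(sum((pr - obs_px[i, ])^2))
    }, numeric(1))
    tibble(frame = frame, joint = joint, x = p[1], y = p[2], z = p[3],
           error = mean(errs, na.rm = TRUE), n_cams = length(idx))
  })
  dplyr::arrange(out, .data$frame, match(.data$joint, unique(detections$joint)))
}

# per-point nonlinear reprojection refinement (Gauss-Newton); used as the
# no-regularizer reference for triangulate_regularized
triangulate_nonlinear <- function(detections, rig, min_cameras = 2L,
                                  max_iter = 20L) {
  lin <- triangulate_points(detections, rig, method = "linear",
                            min_cameras = min_cameras)
  det <- detections[is.finite(detections$x) & is.finite(detections$y), ]
  for (r in seq_len(nrow(lin))) {
    if (!is.finite(lin$x[r])) next
    d <- det[det$frame == lin$frame[r] & det$joint == lin$joint[r], ]
    p <- c(lin$x[r], lin$y[r], lin$z[r])
    fn <- function(q) {
      unlist(lapply(seq_len(nrow(d)), function(i) {
        pr <- project_points_clamped(matrix(q, 1), rig[[d$camera[i]]])
        c(pr[1] - d$x[i], pr[2] - d$y[i])
      }))
    }
    for (it in seq_len(max_iter)) {
      r0 <- fn(p)
      J <- vapply(1:3, function(k) {
        h <- 1e-6 * max(1, abs(p[k])); p2 <- p; p2[k] <- p2[k] + h
        (fn(p2) - r0) / h
      }, numeric(length(r0)))
      delta <- tryCatch(solve(crossprod(J) + 1e-9 * diag(3), -crossprod(J, r0)),
                        error = function(e) NULL)
      if (is.null(delta)) break
      p <- p + as.numeric(delta)
      if (max(abs(delta)) < 1e-10) break
    }
    lin$x[r] <- p[1]; lin$y[r] <- p[2]; lin$z[r] <- p[3]
  }
  lin
}

#' Median-filter a 3D trajectory
#'
#' Rolling per-coordinate median across frames, per joint. Missing
#' entries are ignored inside each window; frames missing in the input
#' stay missing.
#'
#' @param traj Tibble (frame, joint, x, y, z, ...).
#' @param window Odd window length in frames.
#' @return Filtered trajectory tibble.
#' @export
median_filter_3d <- function(traj, window = 7L) {
  stopifnot(window %% 2 == 1)
  traj |>
    dplyr::group_by(.data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("x", "y", "z")), function(v) {
      was_na <- is.na(v)
      out <- rolling_median(v, window)
      out[was_na] <- NA_real_
      out
    })) |>
    dplyr::ungroup()
}

#' Temporally regularize a (possibly gappy) signal
#'
#' Solves the quadratic problem
#' `sum_observed (x_t - y_t)^2 + alpha * sum ((Delta^k x)_t)^2`
#' for each column of `y`, where `alpha = beta * gamma` and the scale
#' `gamma` is the reciprocal mean one-frame displacement of the
#' linearly-interpolated input, making `beta` unit-free. This is the
#' temporal term of the regularized triangulation applied directly in
#' trajectory space; it reconstructs smooth trajectories from noisy,
#' partially missing ones.
#'
#' @param y Numeric vector or matrix (frames x dims) with NAs at missing
#'   samples.
#' @param beta Smoothing strength (unit-free).
#' @param order Finite-difference order `k` to penalize (1, 2 or 3).
#' @return Matrix (or vector) of the reconstructed signal.
#' @export
smooth_temporal <- function(y, beta = 2, order = 2L) {
  vec <- is.null(dim(y))
  Y <- as.matrix(y)
  TT <- nrow(Y)
  # gamma from the linear-interp initialization, pooled over columns
  Yi <- apply(Y, 2, function(v) {
    if (all(is.na(v))) return(rep(0, TT))
    interp_gaps(v, max_gap = Inf, method = "linear")
  })
  Yi <- apply(Yi, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE); v
  })
  if (TT < 2) return(y)
  disp <- if (ncol(Y) == 3) {
    sqrt(rowSums(diff(Yi)^2))
  } else {
    abs(diff(as.matrix(Yi)))
  }
  gamma <- length(disp) / max(sum(disp), 1e-12)
  alpha <- beta * gamma
  D <- Matrix::bandSparse(TT - order, TT,
                          k = 0:order,
                          diagonals = lapply(0:order, function(j) {
                            rep(choose(order, j) * (-1)^(order - j), TT - order)
                          }))
  out <- Y
  for (cc in seq_len(ncol(Y))) {
    obs <- which(is.finite(Y[, cc]))
    if (length(obs) < order + 1) next
    W <- Matrix::sparseMatrix(i = seq_along(obs), j = obs,
                              x = 1, dims = c(length(obs), TT))
    A <- Matrix::crossprod(W) + alpha * Matrix::crossprod(D)
    b <- Matrix::crossprod(W, Y[obs, cc])
    out[, cc] <- as.numeric(Matrix::solve(A, b))
  }
  if (vec) as.numeric(out) else out
}

#' Spatiotemporally regularized triangulation
#'
#' Joint optimization of all 3D points and per-limb lengths, minimizing
#' robustified reprojection residuals plus a temporal penalty on order-k
#' frame differences and a limb-length penalty
#' `((|p_j1 - p_j2| - d_l) / d_l)^2`. The temporal weight is
#' `alpha_time = beta_time * gamma`, with `gamma` the reciprocal mean
#' frame-to-frame displacement of the linear-triangulation
#' initialization, so `beta_time` is transferable across datasets.
#' Defaults `beta_time = 2`, `alpha_limb = 2`.
#'
#' @param detections Tibble (camera, frame, joint, x, y) of filtered 2D
#'   keypoints.
#' @param rig A `camera_rig`.
#' @param skel A [skeleton()]; its `limbs` drive the length penalty.
#' @param beta_time Temporal regularization strength (unit-free).
#' @param alpha_limb Limb-length regularization strength.
#' @param derivative_order Finite-difference order of the temporal
#'   penalty (default 2).
#' @param robust_norm Loss for reprojection residuals (`"huber"`,
#'   `"soft_l1"`, `"linear"`).
#' @param robust_scale Robust-norm scale in pixels.
#' @param reproj_drop Post-hoc mask: points with reprojection error above
#'   this many pixels are set missing (default 20).
#' @param chunk_size,chunk_overlap Long recordings are optimized in
#'   overlapping chunks blended linearly, keeping memory linear in the
#'   number of frames.
#' @param max_iter LM steps per chunk.
#' @param frame_rate Frames per second, attached to the result.
#' @return List with `traj` (frame, joint, x, y, z, error, n_cams) and
#'   `limb_lengths` (joint_a, joint_b, length).
#' @export
triangulate_regularized <- function(detections, rig, skel,
                                    beta_time = 2, alpha_limb = 2,
                                    derivative_order = 2L,
                                    robust_norm = "huber", robust_scale = 10,
                                    reproj_drop = 20,
                                    chunk_size = 500L, chunk_overlap = 50L,
                                    max_iter = 40L, frame_rate = NULL) {
  frames <- sort(unique(detections$frame))
  if (length(frames) > chunk_size) {
    return(triangulate_regularized_chunked(
      detections, rig, skel, beta_time, alpha_limb, derivative_order,
      robust_norm, robust_scale, reproj_drop, chunk_size, chunk_overlap,
      max_iter, frame_rate))
  }
  joints <- skel$joints
  TT <- length(frames)
  J <- length(joints)

  # --- initialization: per-frame linear triangulation, gaps interpolated
  lin <- triangulate_points(detections, rig, method = "linear")
  P0 <- array(NA_real_, c(TT, J, 3))
  idx_f <- match(lin$frame, frames); idx_j <- match(lin$joint, joints)
  ok <- !is.na(idx_f) & !is.na(idx_j)
  for (k in 1:3) {
    P0[cbind(idx_f[ok], idx_j[ok], k)] <- as.matrix(lin[, c("x", "y", "z")])[ok, k]
  }
  observed_joint <- logical(J)
  for (j in seq_len(J)) {
    observed_joint[j] <- any(is.finite(P0[, j, 1]))
    for (k in 1:3) {
      v <- P0[, j, k]
      if (all(is.na(v))) next
      v <- interp_gaps(v, max_gap = Inf, method = "linear")
      # extend flat at the edges so the initializer is complete
      v <- zoo::na.locf(zoo::na.locf(v, na.rm = FALSE), fromLast = TRUE)
      P0[, j, k] <- v
    }
  }
  act <- which(observed_joint)
  if (!length(act)) abort("no joint has any triangulated point")

  # --- gamma scale from the initialization
  disp <- c()
  for (j in act) disp <- c(disp, sqrt(rowSums(diff(P0[, j, , drop = TRUE],
                                                   lag = 1)^2)))
  gamma <- length(disp) / max(sum(disp, na.rm = TRUE), 1e-12)
  alpha_time <- beta_time * gamma

  # --- limb set restricted to observed joints
  limbs <- skel$limbs[skel$limbs$joint_a %in% joints[act] &
                        skel$limbs$joint_b %in% joints[act], ]
  L <- nrow(limbs)
  d0 <- vapply(seq_len(L), function(l) {
    a <- match(limbs$joint_a[l], joints); b <- match(limbs$joint_b[l], joints)
    median(sqrt(rowSums((P0[, a, ] - P0[, b, ])^2)), na.rm = TRUE)
  }, numeric(1))

  # --- observation bookkeeping
  det <- detections[is.finite(detections$x) & is.finite(detections$y), ]
  det <- det[det$joint %in% joints[act] & det$frame %in% frames, ]
  det$cam_idx <- match(det$camera, names(rig))
  det$f_idx <- match(det$frame, frames)
  det$j_idx <- match(det$joint, joints)
  n_obs <- nrow(det)

  # parameter layout: points for active joints (frame-major per joint),
  # then limb lengths
  jmap <- match(seq_len(J), act) # joint -> active index or NA
  n_pt <- length(act) * TT
  par_of <- function(f_idx, j_idx, k) {
    ((jmap[j_idx] - 1) * TT + (f_idx - 1)) * 3 + k
  }
  theta0 <- numeric(3 * n_pt + L)
  for (j in act) for (k in 1:3) {
    theta0[par_of(seq_len(TT), j, k)] <- P0[, j, k]
  }
  if (L) theta0[3 * n_pt + seq_len(L)] <- d0

  # residual layout: 2*n_obs reprojection; temporal; limb
  n_td <- TT - derivative_order
  temporal_rows <- if (n_td > 0) length(act) * n_td * 3 else 0
  limb_rows <- L * TT
  m <- 2 * n_obs + temporal_rows + limb_rows
  sqrt_at <- sqrt(alpha_time)
  limb_w <- if (L) sqrt(alpha_limb * limbs$weight) else numeric(0)
  dcoef <- choose(derivative_order, 0:derivative_order) *
    (-1)^(derivative_order - (0:derivative_order))
  la <- if (L) match(limbs$joint_a, joints) else integer(0)
  lb <- if (L) match(limbs$joint_b, joints) else integer(0)

  resid_fn <- function(theta) {
    res <- numeric(m)
    # reprojection
    for (c_i in unique(det$cam_idx)) {
      sel <- which(det$cam_idx == c_i)
      Pm <- cbind(theta[par_of(det$f_idx[sel], det$j_idx[sel], 1)],
                  theta[par_of(det$f_idx[sel], det$j_idx[sel], 2)],
                  theta[par_of(det$f_idx[sel], det$j_idx[sel], 3)])
      pr <- project_points_clamped(Pm, rig[[c_i]])
      res[2 * sel - 1] <- pr[, 1] - det$x[sel]
      res[2 * sel] <- pr[, 2] - det$y[sel]
    }
    res[seq_len(2 * n_obs)] <- robustify_residuals(res[seq_len(2 * n_obs)],
                                                   robust_norm, robust_scale)
    off <- 2 * n_obs
    if (n_td > 0) {
      for (ja in seq_along(act)) {
        j <- act[ja]
        for (k in 1:3) {
          v <- theta[par_of(seq_len(TT), j, k)]
          dv <- v
          for (dd in seq_len(derivative_order)) dv <- diff(dv)
          rows <- off + ((ja - 1) * 3 + (k - 1)) * n_td + seq_len(n_td)
          res[rows] <- sqrt_at * dv
        }
      }
      off <- off + temporal_rows
    }
    if (L) {
      dl <- theta[3 * n_pt + seq_len(L)]
      for (l in seq_len(L)) {
        pa <- cbind(theta[par_of(seq_len(TT), la[l], 1)],
                    theta[par_of(seq_len(TT), la[l], 2)],
                    theta[par_of(seq_len(TT), la[l], 3)])
        pb <- cbind(theta[par_of(seq_len(TT), lb[l], 1)],
                    theta[par_of(seq_len(TT), lb[l], 2)],
                    theta[par_of(seq_len(TT), lb[l], 3)])
        len <- sqrt(rowSums((pa - pb)^2))
        res[off + (l - 1) * TT + seq_len(TT)] <-
          limb_w[l] * (len - dl[l]) / max(dl[l], 1e-9)
      }
    }
    res
  }

  # --- sparsity structure
  param_rows <- vector("list", length(theta0))
  obs_rows_by_pt <- split(seq_len(n_obs),
                          (jmap[det$j_idx] - 1) * TT + det$f_idx)
  limb_rows_of <- function(l, f) 2 * n_obs + temporal_rows + (l - 1) * TT + f
  limbs_of_joint <- if (L) {
    lapply(seq_len(J), function(j) which(la == j | lb == j))
  } else rep(list(integer(0)), J)
  for (ja in seq_along(act)) {
    j <- act[ja]
    for (f in seq_len(TT)) {
      pt_lin <- (ja - 1) * TT + f
      o <- obs_rows_by_pt[[as.character(pt_lin)]]
      rws <- if (length(o)) as.integer(rbind(2 * o - 1, 2 * o)) else integer(0)
      if (n_td > 0) {
        t_lo <- max(1L, f - derivative_order); t_hi <- min(n_td, f)
        if (t_lo <= t_hi) {
          base <- 2 * n_obs + ((ja - 1) * 3 + (0:2)) * n_td
          rws <- c(rws, as.integer(outer(t_lo:t_hi, base, `+`)))
        }
      }
      for (l in limbs_of_joint[[j]]) rws <- c(rws, limb_rows_of(l, f))
      for (k in 1:3) param_rows[[par_of(f, j, k)]] <- rws
    }
  }
  if (L) for (l in seq_len(L)) {
    param_rows[[3 * n_pt + l]] <- limb_rows_of(l, seq_len(TT))
  }

  # --- coloring: frames modulo (order+1) x greedy joint coloring over the
  # limb graph, separately per coordinate; limb lengths are one group
  jcol <- rep(1L, J)
  if (L) {
    for (j in seq_len(J)) {
      nb <- c(lb[la == j], la[lb == j])
      used <- jcol[nb[nb < j]]
      jcol[j] <- min(setdiff(seq_len(J), used))
    }
  }
  ncol_j <- max(jcol[act])
  stride <- derivative_order + 1L
  groups <- list()
  for (k in 1:3) for (fm in seq_len(stride)) for (jc in seq_len(ncol_j)) {
    ids <- c()
    for (ja in seq_along(act)) {
      j <- act[ja]
      if (jcol[j] != jc) next
      fs <- seq.int(fm, TT, by = stride)
      ids <- c(ids, par_of(fs, j, k))
    }
    if (length(ids)) groups[[length(groups) + 1L]] <- ids
  }
  if (L) groups[[length(groups) + 1L]] <- 3 * n_pt + seq_len(L)

  fit <- slm_least_squares(theta0, resid_fn, param_rows, groups,
                           max_iter = max_iter)

  # --- unpack, attach errors, post-hoc masking
  theta <- fit$theta
  out <- tidyr::expand_grid(frame = frames, joint = joints)
  out$x <- NA_real_; out$y <- NA_real_; out$z <- NA_real_
  for (j in act) {
    rows <- which(out$joint == joints[j])
    out$x[rows] <- theta[par_of(seq_len(TT), j, 1)]
    out$y[rows] <- theta[par_of(seq_len(TT), j, 2)]
    out$z[rows] <- theta[par_of(seq_len(TT), j, 3)]
  }
  err <- reproj_error_by_point(out, det, rig)
  out <- dplyr::left_join(out, err, by = c("frame", "joint"))
  out$n_cams[is.na(out$n_cams)] <- 0L
  # never report interpolated positions where nothing was ever observed
  seen <- dplyr::distinct(det, .data$frame, .data$joint)
  seen$observed <- TRUE
  out <- dplyr::left_join(out, seen, by = c("frame", "joint"))
  drop <- (!is.na(out$error) & out$error > reproj_drop)
  out$x[drop] <- NA_real_; out$y[drop] <- NA_real_; out$z[drop] <- NA_real_
  out$observed <- NULL
  attr(out, "frame_rate") <- frame_rate

  lengths_out <- if (L) {
    tibble(joint_a = limbs$joint_a, joint_b = limbs$joint_b,
           length = theta[3 * n_pt + seq_len(L)])
  } else {
    tibble(joint_a = character(), joint_b = character(), length = numeric())
  }
  list(traj = out, limb_lengths = lengths_out,
       gamma = gamma, alpha_time = alpha_time,
       converged = fit$converged)
}

reproj_error_by_point <- function(traj, det, rig) {
  d <- dplyr::inner_join(det, traj, by = c("frame", "joint"),
                         suffix = c("", "_3d"))
  if (!nrow(d)) {
    return(tibble(frame = integer(), joint = character(),
                  error = numeric(), n_cams = integer()))
  }
  d$err <- NA_real_
  for (cm in unique(d$camera)) {
    idx <- which(d$camera == cm)
    pr <- project_points(cbind(d$x_3d[idx], d$y_3d[idx], d$z[idx]),
                         rig[[cm]])
    d$err[idx] <- sqrt((pr[, 1] - d$x[idx])^2 + (pr[, 2] - d$y[idx])^2)
  }
  d |>
    dplyr::group_by(.data$frame, .data$joint) |>
    dplyr::summarise(error = mean(.data$err, na.rm = TRUE),
                     n_cams = dplyr::n(), .groups = "drop")
}

triangulate_regularized_chunked <- function(detections, rig, skel, beta_time,
                                            alpha_limb, derivative_order,
                                            robust_norm, robust_scale,
                                            reproj_drop, chunk_size,
                                            chunk_overlap, max_iter,
                                            frame_rate) {
  frames <- sort(unique(detections$frame))
  TT <- length(frames)
  starts <- seq(1L, TT, by = chunk_size - chunk_overlap)
  starts <- starts[starts <= TT - 1]
  pieces <- list(); weights <- list()
  lengths_acc <- NULL
  for (s in starts) {
    e <- min(s + chunk_size - 1L, TT)
    sub <- detections[detections$frame %in% frames[s:e], ]
    fit <- triangulate_regularized(sub, rig, skel, beta_time, alpha_limb,
                                   derivative_order, robust_norm,
                                   robust_scale, reproj_drop,
                                   chunk_size = .Machine$integer.max,
                                   max_iter = max_iter,
                                   frame_rate = frame_rate)
    n_f <- e - s + 1L
    w <- rep(1, n_f)
    ramp <- min(chunk_overlap, n_f)
    if (s > 1) w[seq_len(ramp)] <- seq(0, 1, length.out = ramp + 2)[2:(ramp + 1)]
    if (e < TT) w[n_f - seq_len(ramp) + 1] <-
        seq(0, 1, length.out = ramp + 2)[2:(ramp + 1)]
    fit$traj$.w <- w[match(fit$traj$frame, frames[s:e])]
    pieces[[length(pieces) + 1L]] <- fit$traj
    lengths_acc <- dplyr::bind_rows(lengths_acc, fit$limb_lengths)
    if (e == TT) break
  }
  allp <- dplyr::bind_rows(pieces)
  traj <- allp |>
    dplyr::group_by(.data$frame, .data$joint) |>
    dplyr::summarise(
      x = stats::weighted.mean(.data$x, .data$.w, na.rm = TRUE),
      y = stats::weighted.mean(.data$y, .data$.w, na.rm = TRUE),
      z = stats::weighted.mean(.data$z, .data$.w, na.rm = TRUE),
      error = stats::weighted.mean(.data$error, .data$.w, na.rm = TRUE),
      n_cams = max(.data$n_cams), .groups = "drop"
    )
  traj$x[is.nan(traj$x)] <- NA_real_
  traj$y[is.nan(traj$y)] <- NA_real_
  traj$z[is.nan(traj$z)] <- NA_real_
  attr(traj, "frame_rate") <- frame_rate
  lengths_out <- lengths_acc |>
    dplyr::group_by(.data$joint_a, .data$joint_b) |>
    dplyr::summarise(length = mean(.data$length), .groups = "drop")
  list(traj = traj, limb_lengths = lengths_out, converged = TRUE)
}

#' Finite-difference velocity of a 3D trajectory
#'
#' One-frame forward difference scaled by the frame rate; missing
#' positions yield missing velocities.
#'
#' @param traj Tibble (frame, joint, x, y, z).
#' @param frame_rate Frames per second (taken from the trajectory's
#'   `frame_rate` attribute when omitted).
#' @return Tibble (frame, joint, vx, vy, vz, speed).
#' @export
estimate_derivative <- function(traj, frame_rate = NULL) {
  frame_rate <- frame_rate %||% attr(traj, "frame_rate")
  if (is.null(frame_rate)) abort("frame_rate must be set")
  traj |>
    dplyr::group_by(.data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      vx = (dplyr::lead(.data$x) - .data$x) * frame_rate,
      vy = (dplyr::lead(.data$y) - .data$y) * frame_rate,
      vz = (dplyr::lead(.data$z) - .data$z) * frame_rate,
      speed = sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("frame", "joint", "vx", "vy", "vz", "speed")))
}

#' Absolute angle errors against a reference angle table
#'
#' @param pred,ref Angle tibbles (frame, joint, kind, value_deg) as
#'   produced by [chain_angles()], matched on (frame, joint, kind).
#' @return List with `errors` (per-angle absolute differences, circular
#'   for rotation/abduction) and a `summary` (mean + 95% CI).
#' @export
angle_errors <- function(pred, ref) {
  j <- dplyr::inner_join(pred, ref, by = c("frame", "joint", "kind"),
                         suffix = c("", "_ref"))
  if (!nrow(j)) abort("no overlapping (frame, joint, kind) angles")
  d <- j$value_deg - j$value_deg_ref
  circ <- j$kind %in% c("rotation", "abduction")
  d[circ] <- (d[circ] + 180) %% 360 - 180
  j$error <- abs(d)
  ev <- j$error[is.finite(j$error)]
  ci <- mean(ev) + c(-1, 1) * qt(0.975, length(ev) - 1) * sd(ev) / sqrt(length(ev))
  list(errors = dplyr::select(j, dplyr::all_of(c("frame", "joint", "kind",
                                                 "error"))),
       summary = tibble(mean_error = mean(ev), n = length(ev),
                        ci_low = ci[1], ci_high = ci[2]))
}

#' Pointwise position errors and paired method comparison
#'
#' Euclidean per-point errors of one or two reconstructions against a
#' reference, with the paired mean difference and its 95% confidence
#' interval (the standard way to compare two filters on the same points).
#'
#' @param pred Tibble (frame, joint, x, y, z).
#' @param ref Reference tibble with the same keys.
#' @param pred2 Optional second method for the paired comparison.
#' @return List with `errors` (per-point tibble) and `summary`; when
#'   `pred2` is given the summary contains the paired difference
#'   `pred - pred2` with `ci_low`/`ci_high`.
#' @export
position_errors <- function(pred, ref, pred2 = NULL) {
  e1 <- dplyr::inner_join(pred, ref, by = c("frame", "joint"),
                          suffix = c("", "_ref"))
  if (!nrow(e1)) abort("no overlapping (frame, joint) pairs")
  e1$error <- sqrt((e1$x - e1$x_ref)^2 + (e1$y - e1$y_ref)^2 +
                     (e1$z - e1$z_ref)^2)
  errors <- dplyr::select(e1, dplyr::all_of(c("frame", "joint", "error")))
  if (is.null(pred2)) {
    ev <- errors$error[is.finite(errors$error)]
    ci <- mean(ev) + c(-1, 1) * qt(0.975, length(ev) - 1) * sd(ev) / sqrt(length(ev))
    return(list(errors = errors,
                summary = tibble(mean_error = mean(ev), n = length(ev),
                                 ci_low = ci[1], ci_high = ci[2])))
  }
  cmp <- position_errors(pred2, ref)$errors
  d <- dplyr::inner_join(errors, cmp, by = c("frame", "joint"),
                         suffix = c("_1", "_2"))
  dd <- d$error_1 - d$error_2
  dd <- dd[is.finite(dd)]
  ci <- mean(dd) + c(-1, 1) * qt(0.975, length(dd) - 1) * sd(dd) / sqrt(length(dd))
  list(errors = errors,
       summary = tibble(mean_error = mean(errors$error, na.rm = TRUE),
                        mean_diff = mean(dd), n = length(dd),
                        ci_low = ci[1], ci_high = ci[2]))
}
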