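# Camera calibration from calibration-board corner detections:
# covisibility graph -> intrinsics/extrinsics initialization -> (iterative)
# sparse bundle adjustment.

#' Define a planar calibration board
#'
#' A checkerboard-with-markers target: `squares_x` x `squares_y` squares
#' of side `square_size`, with fiducial markers of side `marker_size`
#' inside the white squares. Corner keypoints live on the interior lattice
#' of the checkerboard (the `(squares_x-1) x (squares_y-1)` grid), on the
#' z = 0 plane, indexed row-major from 0.
#'
#' @param squares_x,squares_y Number of squares along each side.
#' @param square_size Square side length (world units, e.g. mm).
#' @param marker_size Marker side length; must be positive and smaller
#'   than `square_size`.
#' @param tracked_corner_ids Integer ids of the corners used as keypoints
#'   (default: all interior corners).
#' @return An object of class `board_geometry` with the canonical 3D
#'   corner coordinates in `$corners` (tibble: corner_id, x, y, z).
#' @export
board_geometry <- function(squares_x = 6L, squares_y = 6L,
                           square_size = 0.5, marker_size = 0.375,
                           tracked_corner_ids = NULL) {
  if (!(marker_size > 0 && marker_size < square_size)) {
    abort("marker_size must satisfy 0 < marker_size < square_size")
  }
  nx <- squares_x - 1L; ny <- squares_y - 1L
  grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  corners <- tibble(
    corner_id = seq_len(nrow(grid)) - 1L,
    x = (grid$ix - (nx - 1) / 2) * square_size,
    y = (grid$iy - (ny - 1) / 2) * square_size,
    z = 0
  )
  if (is.null(tracked_corner_ids)) tracked_corner_ids <- corners$corner_id
  if (!all(tracked_corner_ids %in% corners$corner_id)) {
    abort("tracked_corner_ids outside the board's corner lattice")
  }
  structure(list(
    squares_x = squares_x, squares_y = squares_y,
    square_size = square_size, marker_size = marker_size,
    tracked_corner_ids = as.integer(tracked_corner_ids),
    corners = corners[corners$corner_id %in% tracked_corner_ids, ]
  ), class = "board_geometry")
}

#' Build the camera covisibility graph
#'
#' Counts, for every camera pair, the frames in which the board is
#' detected by both, and greedily selects spanning edges in decreasing
#' order of shared-frame count (an edge is kept only if its endpoints are
#' not yet connected). Calibration is possible iff the graph is connected.
#'
#' @param detections Tibble with columns `camera`, `frame`, `corner_id`,
#'   `x`, `y`.
#' @param min_corners A frame counts as a detection for a camera only if
#'   at least this many corners are seen (pose needs >= 4).
#' @return A `camera_graph`: list with `cameras`, `pairs` (all pairs with
#'   counts and a `selected` flag) and `edges` (the spanning tree).
#' @export
build_camera_graph <- function(detections, min_corners = 4L) {
  frames_by_cam <- detections |>
    dplyr::count(.data$camera, .data$frame) |>
    dplyr::filter(.data$n >= min_corners)
  cams <- sort(unique(detections$camera))
  if (length(cams) < 2) abort("need at least 2 cameras")
  combs <- utils::combn(cams, 2)
  pair_counts <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    fa <- frames_by_cam$frame[frames_by_cam$camera == a]
    fb <- frames_by_cam$frame[frames_by_cam$camera == b]
    tibble(cam_a = a, cam_b = b, n_shared = length(intersect(fa, fb)))
  }) |>
    dplyr::arrange(dplyr::desc(.data$n_shared))

  # union-find
  parent <- setNames(cams, cams)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  selected <- logical(nrow(pair_counts))
  for (i in seq_len(nrow(pair_counts))) {
    if (pair_counts$n_shared[i] < 1) next
    ra <- find(pair_counts$cam_a[i]); rb <- find(pair_counts$cam_b[i])
    if (ra != rb) { parent[[ra]] <- rb; selected[i] <- TRUE }
  }
  pair_counts$selected <- selected
  roots <- vapply(cams, find, "")
  if (length(unique(roots)) > 1) {
    comps <- split(cams, roots)
    abort(paste0(
      "camera graph is disconnected; calibration impossible. Components: ",
      paste(vapply(comps, function(cc) paste0("{", paste(cc, collapse = ","), "}"),
                   ""), collapse = " vs ")
    ))
  }
  structure(list(cameras = cams, pairs = pair_counts,
                 edges = pair_counts[pair_counts$selected, ]),
            class = "camera_graph")
}

# homography board-plane -> pixels for one camera/frame; NULL if < 4 corners
board_frame_homography <- function(det_cf, board) {
  d <- dplyr::inner_join(det_cf, board$corners, by = "corner_id",
                         suffix = c("_px", "_mm"))
  if (nrow(d) < 4) return(NULL)
  homography_dlt(cbind(d$x_mm, d$y_mm), cbind(d$x_px, d$y_px))
}

#' Initialize per-camera focal lengths from board homographies
#'
#' Closed-form single-focal reduction of the planar-target intrinsics
#' solution: with the principal point fixed at the image center, each
#' board homography contributes estimates of `f^2` through the
#' orthogonality and equal-norm constraints on its first two columns.
#' The per-camera focal is the median over all valid frame estimates.
#' Distortion is initialized to zero.
#'
#' @param detections Board detection tibble (camera, frame, corner_id, x, y).
#' @param board A [board_geometry()].
#' @param image_sizes Named list of `(width, height)` per camera.
#' @param min_frames Minimum usable frames; below this (or if all views
#'   are fronto-parallel, which is degenerate for focal estimation) the
#'   focal falls back to `fallback_fov_factor * max(image_size)` with a
#'   warning.
#' @param fallback_fov_factor Field-of-view prior for the fallback focal.
#' @return Named numeric vector of focal lengths (pixels).
#' @export
initialize_intrinsics <- function(detections, board, image_sizes,
                                  min_frames = 3L, fallback_fov_factor = 1.2) {
  cams <- sort(unique(detections$camera))
  focals <- setNames(numeric(length(cams)), cams)
  for (cm in cams) {
    sz <- image_sizes[[cm]]
    cx <- sz[1] / 2; cy <- sz[2] / 2
    det_c <- detections[detections$camera == cm, ]
    f2 <- c()
    n_used <- 0L
    for (fr in unique(det_c$frame)) {
      H <- board_frame_homography(det_c[det_c$frame == fr, ], board)
      if (is.null(H)) next
      n_used <- n_used + 1L
      # shift principal point to origin
      H <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1)) %*% H
      h1 <- H[, 1]; h2 <- H[, 2]
      if (abs(h1[3] * h2[3]) > 1e-12) {
        v <- -(h1[1] * h2[1] + h1[2] * h2[2]) / (h1[3] * h2[3])
        if (is.finite(v) && v > 0) f2 <- c(f2, v)
      }
      den <- h1[3]^2 - h2[3]^2
      if (abs(den) > 1e-12) {
        v <- -(h1[1]^2 + h1[2]^2 - h2[1]^2 - h2[2]^2) / den
        if (is.finite(v) && v > 0) f2 <- c(f2, v)
      }
    }
    if (n_used < min_frames || length(f2) < min_frames) {
      warn(sprintf(
        "camera '%s': focal not identifiable from board views (%d usable frames, %d constraints); falling back to FOV prior",
        cm, n_used, length(f2)))
      focals[cm] <- fallback_fov_factor * max(sz)
    } else {
      focals[cm] <- sqrt(median(f2))
    }
  }
  focals
}

# board pose per (camera, frame) given intrinsics
board_poses_for_camera <- function(det_c, board, focal, cx, cy) {
  K <- rbind(c(focal, 0, cx), c(0, focal, cy), c(0, 0, 1))
  frames <- sort(unique(det_c$frame))
  poses <- list()
  for (fr in frames) {
    H <- board_frame_homography(det_c[det_c$frame == fr, ], board)
    if (is.null(H)) next
    p <- pose_from_homography(H, K)
    if (!is.null(p)) poses[[as.character(fr)]] <- p
  }
  poses
}

#' Initialize camera extrinsics from the covisibility graph
#'
#' The first camera (graph root) is placed at the identity; each
#' neighbor along a spanning-tree edge is initialized from the relative
#' pose of the board seen simultaneously by the two cameras, averaged
#' over shared frames (rotation-vector/translation geometric median), and
#' the recursion covers the whole tree.
#'
#' @param graph A [build_camera_graph()] result.
#' @param detections Board detections.
#' @param board A [board_geometry()].
#' @param focals Named focal vector from [initialize_intrinsics()].
#' @param image_sizes Named list of image sizes.
#' @return A `camera_rig` with k1 = 0 for all cameras.
#' @export
initialize_extrinsics <- function(graph, detections, board, focals,
                                  image_sizes) {
  cams <- graph$cameras
  poses_by_cam <- lapply(setNames(cams, cams), function(cm) {
    sz <- image_sizes[[cm]]
    board_poses_for_camera(detections[detections$camera == cm, ], board,
                           focals[[cm]], sz[1] / 2, sz[2] / 2)
  })
  ext <- list()
  root <- cams[1]
  ext[[root]] <- list(R = diag(3), t = c(0, 0, 0))
  adj <- graph$edges
  todo <- root
  visited <- root
  while (length(todo)) {
    a <- todo[1]; todo <- todo[-1]
    nb <- c(adj$cam_b[adj$cam_a == a], adj$cam_a[adj$cam_b == a])
    for (b in setdiff(nb, visited)) {
      shared <- intersect(names(poses_by_cam[[a]]), names(poses_by_cam[[b]]))
      if (!length(shared)) {
        abort(sprintf("no shared frame with estimable board pose on edge %s-%s",
                      a, b))
      }
      rel <- purrr::map(shared, function(fr) {
        pa <- poses_by_cam[[a]][[fr]]; pb <- poses_by_cam[[b]][[fr]]
        R_ab <- pb$R %*% t(pa$R)
        t_ab <- pb$t - as.numeric(R_ab %*% pa$t)
        c(as.numeric(R_ab), t_ab)
      })
      M <- do.call(rbind, rel)
      # average rotations by the chordal geometric median (robust and
      # free of the axis-angle sign ambiguity near 180 degrees), then
      # project back to SO(3)
      Rmed <- matrix(geometric_median(M[, 1:9, drop = FALSE]), 3, 3)
      sv <- svd(Rmed)
      R_ab <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
      tv <- geometric_median(M[, 10:12, drop = FALSE])
      ext[[b]] <- list(R = R_ab %*% ext[[a]]$R,
                       t = as.numeric(R_ab %*% ext[[a]]$t) + tv)
      visited <- c(visited, b)
      todo <- c(todo, b)
    }
  }
  camera_rig(lapply(cams, function(cm) {
    camera(name = cm,
           rotation = matrix_to_rotvec(ext[[cm]]$R),
           translation = ext[[cm]]$t,
           focal = focals[[cm]],
           k1 = 0,
           image_size = image_sizes[[cm]])
  }))
}

#' Per-observation reprojection errors
#'
#' @param rig A `camera_rig`.
#' @param detections Board detections (camera, frame, corner_id, x, y).
#' @param points3d Tibble (frame, corner_id, x, y, z) of 3D points.
#' @return `detections` with an `error` column (pixel residual norm);
#'   observations without a 3D point are dropped.
#' @export
reprojection_errors <- function(rig, detections, points3d) {
  d <- dplyr::inner_join(detections, points3d, by = c("frame", "corner_id"),
                         suffix = c("", "_3d"))
  d$error <- NA_real_
  for (cm in names(rig)) {
    idx <- which(d$camera == cm)
    if (!length(idx)) next
    proj <- project_points(cbind(d$x_3d[idx], d$y_3d[idx], d$z[idx]),
                           rig[[cm]])
    d$error[idx] <- sqrt((proj[, 1] - d$x[idx])^2 + (proj[, 2] - d$y[idx])^2)
  }
  dplyr::select(d, dplyr::all_of(c("camera", "frame", "corner_id", "x", "y")),
                dplyr::any_of("score"), "error")
}

# linear triangulation of board corners per (frame, corner_id)
triangulate_board <- function(rig, detections) {
  det <- dplyr::rename(detections, joint = "corner_id")
  out <- triangulate_points(det, rig, method = "linear")
  dplyr::rename(out, corner_id = "joint")
}

# pack/unpack parameter vectors for bundle adjustment
pack_ba <- function(rig, pts) {
  c(unlist(lapply(rig, function(cm) {
    c(cm$rotation, cm$translation, cm$focal, cm$k1)
  })), as.numeric(t(pts)))
}
unpack_ba_rig <- function(theta, rig) {
  for (i in seq_along(rig)) {
    off <- (i - 1) * 8
    rig[[i]]$rotation <- theta[off + 1:3]
    rig[[i]]$translation <- theta[off + 4:6]
    rig[[i]]$focal <- max(theta[off + 7], 1e-6)
    rig[[i]]$k1 <- theta[off + 8]
  }
  rig
}

#' Bundle adjustment
#'
#' Jointly refines all camera parameters (8 per camera) and the 3D board
#' points by sparse nonlinear least squares on the reprojection
#' residuals, optionally robustified with a Huber or soft-L1 norm.
#'
#' @param rig Initialized `camera_rig`.
#' @param detections Board detections (camera, frame, corner_id, x, y).
#' @param loss One of `"linear"`, `"huber"`, `"soft_l1"`.
#' @param loss_scale Robust-norm scale in pixels.
#' @param points3d Optional initial 3D points (frame, corner_id, x, y, z);
#'   computed by linear triangulation when missing.
#' @param max_iter Maximum LM steps.
#' @param fix_cameras Optimize points only (used internally).
#' @return List with the refined `rig`, `points3d`, and a `summary`
#'   tibble (initial/final mean reprojection error in pixels), plus a
#'   `converged` flag.
#' @export
bundle_adjust <- function(rig, detections, loss = c("linear", "huber", "soft_l1"),
                          loss_scale = 10, points3d = NULL, max_iter = 30L,
                          fix_cameras = FALSE) {
  loss <- match.arg(loss)
  n_cam <- length(rig)
  if (is.null(points3d)) points3d <- triangulate_board(rig, detections)
  pts <- points3d[is.finite(points3d$x), c("frame", "corner_id", "x", "y", "z")]
  key <- paste(pts$frame, pts$corner_id)
  det <- detections
  det$pt_idx <- match(paste(det$frame, det$corner_id), key)
  det <- det[!is.na(det$pt_idx), ]
  # a point is only identifiable with >= 2 views
  tb <- table(det$pt_idx)
  keep_pts <- as.integer(names(tb)[tb >= 2])
  pts <- pts[keep_pts, ]
  det$pt_idx <- match(det$pt_idx, keep_pts)
  det <- det[!is.na(det$pt_idx), ]
  det$cam_idx <- match(det$camera, names(rig))
  n_obs <- nrow(det)
  n_pts <- nrow(pts)
  min_obs <- 10 * (8 * n_cam)
  if (n_obs < max(min_obs / 10, 15)) {
    abort(sprintf("too few observations (%d) for bundle adjustment", n_obs))
  }

  P0 <- as.matrix(pts[, c("x", "y", "z")])
  theta0 <- pack_ba(rig, P0)
  obs <- cbind(det$x, det$y)
  cam_idx <- det$cam_idx
  pt_idx <- det$pt_idx

  resid_fn <- function(theta) {
    rg <- unpack_ba_rig(theta, rig)
    P <- matrix(theta[(8 * n_cam + 1):length(theta)], ncol = 3, byrow = TRUE)
    res <- numeric(2 * n_obs)
    for (c_i in seq_len(n_cam)) {
      sel <- which(cam_idx == c_i)
      if (!length(sel)) next
      pr <- project_points_clamped(P[pt_idx[sel], , drop = FALSE], rg[[c_i]])
      res[2 * sel - 1] <- pr[, 1] - obs[sel, 1]
      res[2 * sel] <- pr[, 2] - obs[sel, 2]
    }
    robustify_residuals(res, loss, loss_scale)
  }

  # sparsity: camera p -> rows of its observations; point coord -> rows of
  # the observations of that point
  rows_of_obs <- function(sel) as.integer(rbind(2 * sel - 1, 2 * sel))
  param_rows <- vector("list", length(theta0))
  for (c_i in seq_len(n_cam)) {
    rws <- rows_of_obs(which(cam_idx == c_i))
    for (k in 1:8) param_rows[[(c_i - 1) * 8 + k]] <- rws
  }
  obs_by_pt <- split(seq_len(n_obs), pt_idx)
  for (p_i in seq_len(n_pts)) {
    rws <- rows_of_obs(obs_by_pt[[as.character(p_i)]])
    for (k in 1:3) param_rows[[8 * n_cam + (p_i - 1) * 3 + k]] <- rws
  }
  groups <- c(
    lapply(1:8, function(k) (seq_len(n_cam) - 1) * 8 + k),
    lapply(1:3, function(k) 8 * n_cam + (seq_len(n_pts) - 1) * 3 + k)
  )
  if (fix_cameras) {
    groups <- groups[9:11]
    for (c_i in seq_len(8 * n_cam)) param_rows[[c_i]] <- integer(0)
  }

  err0 <- mean(reprojection_errors(rig, det, pts3d_tibble(pts, P0))$error,
               na.rm = TRUE)
  fit <- slm_least_squares(theta0, resid_fn, param_rows, groups,
                           max_iter = max_iter)
  rig_out <- unpack_ba_rig(fit$theta, rig)
  P1 <- matrix(fit$theta[(8 * n_cam + 1):length(fit$theta)], ncol = 3,
               byrow = TRUE)
  pts_out <- pts3d_tibble(pts, P1)
  err1 <- mean(reprojection_errors(rig_out, det, pts_out)$error, na.rm = TRUE)
  list(
    rig = rig_out,
    points3d = pts_out,
    summary = tibble(loss = loss, n_observations = n_obs, n_points = n_pts,
                     initial_mean_error = err0, final_mean_error = err1,
                     converged = fit$converged),
    converged = fit$converged
  )
}

pts3d_tibble <- function(pts, P) {
  tibble(frame = pts$frame, corner_id = pts$corner_id,
         x = P[, 1], y = P[, 2], z = P[, 3])
}

# projection that stays differentiable for points drifting behind the
# camera during optimization (depth clamped instead of masked)
project_points_clamped <- function(points, cam, min_depth = 1e-6) {
  R <- rotvec_to_matrix(cam$rotation)
  Xc <- points %*% t(R) + matrix(cam$translation, nrow(points), 3, byrow = TRUE)
  z <- pmax(Xc[, 3], min_depth)
  d <- distort_points(cbind(Xc[, 1] / z, Xc[, 2] / z), cam$k1)
  cbind(cam$focal * d[, 1] + cam$principal_point[1],
        cam$focal * d[, 2] + cam$principal_point[2])
}

#' Iterative bundle adjustment with a decaying error threshold
#'
#' Robust calibration by alternating observation selection and bundle
#' adjustment: at iteration `i` (0-based) only observations whose current
#' reprojection error is below `mu_i = mu_start * (mu_end/mu_start)^(i/(n_iter-1))`
#' pixels (a geometric decay from `mu_start` to `mu_end`) are adjusted.
#' A random subsample of at most `max_frames` detected frames bounds the
#' per-iteration cost; a final pass reports errors on all observations.
#'
#' @param rig Initialized `camera_rig`.
#' @param detections Board detections.
#' @param n_iter Number of threshold iterations (default 12).
#' @param mu_start,mu_end Start/end thresholds in pixels (defaults 15, 1).
#' @param loss Loss inside each iteration (outliers are handled by the
#'   threshold, so the default is `"linear"`).
#' @param max_frames Frame-subsample cap per iteration.
#' @param seed Seed for the frame subsample.
#' @param max_iter_inner LM steps per iteration.
#' @param board Optional [board_geometry()]; when given, the global
#'   scale of the reconstruction (a gauge freedom of bundle adjustment)
#'   is re-anchored so that triangulated inter-corner distances match
#'   the board's known geometry.
#' @return List with `rig`, `points3d` (all frames, linear triangulation
#'   with the final rig), `errors` (all observations), and `summary`.
#' @export
iterative_bundle_adjust <- function(rig, detections, n_iter = 12L,
                                    mu_start = 15, mu_end = 1,
                                    loss = "linear", max_frames = 100L,
                                    seed = 1L, max_iter_inner = 10L,
                                    board = NULL) {
  thresholds <- mu_start * (mu_end / mu_start)^((seq_len(n_iter) - 1) / (n_iter - 1))
  frames <- sort(unique(detections$frame))
  withr_seed <- sub_seed(seed, "iterative-ba")
  set.seed(withr_seed)
  sub_frames <- if (length(frames) > max_frames) {
    sort(sample(frames, max_frames))
  } else frames
  det_sub <- detections[detections$frame %in% sub_frames, ]
  min_keep <- 10 * (8 * length(rig))
  history <- tibble(iteration = integer(), threshold = numeric(),
                    n_selected = integer(), mean_error = numeric())

  pts <- triangulate_board(rig, det_sub)
  for (i in seq_along(thresholds)) {
    errs <- reprojection_errors(rig, det_sub, pts)
    sel <- errs[!is.na(errs$error) & errs$error < thresholds[i], ]
    if (nrow(sel) < max(min_keep / 4, 30)) {
      history <- dplyr::add_row(history, iteration = i,
                                threshold = thresholds[i],
                                n_selected = nrow(sel),
                                mean_error = NA_real_)
      next # keep previous iterate, move to the next threshold
    }
    fit <- tryCatch(
      bundle_adjust(rig, sel[, c("camera", "frame", "corner_id", "x", "y")],
                    loss = loss, max_iter = max_iter_inner),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rig <- fit$rig
    pts <- triangulate_board(rig, det_sub)
    history <- dplyr::add_row(history, iteration = i,
                              threshold = thresholds[i],
                              n_selected = nrow(sel),
                              mean_error = fit$summary$final_mean_error)
  }
  if (!is.null(board)) {
    rig <- anchor_rig_scale(rig, det_sub, board)
  }
  pts_all <- triangulate_board(rig, detections)
  errors <- reprojection_errors(rig, detections, pts_all)
  list(rig = rig, points3d = pts_all, errors = errors,
       summary = tibble(
         n_iter = n_iter, mu_start = mu_start, mu_end = mu_end,
         mean_error = mean(errors$error, na.rm = TRUE),
         median_error = median(errors$error, na.rm = TRUE)
       ),
       history = history)
}

# Gauge fixing: bundle adjustment cannot observe the global scale, so
# the reconstruction may drift away from the metric scale set by the
# board at initialization. Rescale the rig (camera translations) so the
# median ratio of known to triangulated inter-corner distances is 1.
anchor_rig_scale <- function(rig, detections, board) {
  pts <- triangulate_board(rig, detections)
  pts <- pts[is.finite(pts$x), ]
  canon <- board$corners
  ratios <- c()
  for (fr in unique(pts$frame)) {
    p <- pts[pts$frame == fr, ]
    if (nrow(p) < 2) next
    m <- dplyr::inner_join(p, canon, by = "corner_id",
                           suffix = c("_est", "_ref"))
    if (nrow(m) < 2) next
    i <- seq_len(nrow(m) - 1)
    d_est <- sqrt((m$x_est[i] - m$x_est[i + 1])^2 +
                    (m$y_est[i] - m$y_est[i + 1])^2 +
                    (m$z_est[i] - m$z_est[i + 1])^2)
    d_ref <- sqrt((m$x_ref[i] - m$x_ref[i + 1])^2 +
                    (m$y_ref[i] - m$y_ref[i + 1])^2)
    ok <- d_ref > 1e-9
    ratios <- c(ratios, d_ref[ok] / d_est[ok])
  }
  if (!length(ratios)) return(rig)
  s <- median(ratios, na.rm = TRUE)
  for (i in seq_along(rig)) rig[[i]]$translation <- rig[[i]]$translation * s
  rig
}

#' Calibrate a multi-camera rig from board detections
#'
#' End-to-end calibration: covisibility graph, focal initialization from
#' board homographies (k1 = 0), extrinsics initialization along the
#' spanning tree, then iterative bundle adjustment.
#'
#' @param detections Board detections (camera, frame, corner_id, x, y).
#' @param board A [board_geometry()].
#' @param image_sizes Named list of `(width, height)` per camera.
#' @param n_iter,mu_start,mu_end,loss,max_frames,seed Passed to
#'   [iterative_bundle_adjust()].
#' @return An object of class `camera_calibration` with elements `rig`,
#'   `errors`, `summary`, `graph`, `history`.
#' @export
calibrate_cameras <- function(detections, board, image_sizes,
                              n_iter = 12L, mu_start = 15, mu_end = 1,
                              loss = "linear", max_frames = 100L, seed = 1L) {
  graph <- build_camera_graph(detections)
  focals <- initialize_intrinsics(detections, board, image_sizes)
  rig0 <- initialize_extrinsics(graph, detections, board, focals, image_sizes)
  fit <- iterative_bundle_adjust(rig0, detections, n_iter = n_iter,
                                 mu_start = mu_start, mu_end = mu_end,
                                 loss = loss, max_frames = max_frames,
                                 seed = seed, board = board)
  structure(list(rig = fit$rig, errors = fit$errors, summary = fit$summary,
                 points3d = fit$points3d, graph = graph,
                 history = fit$history),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> %d cameras, mean reprojection error %.3f px\n",
              length(x$rig), x$summary$mean_error))
  invisible(x)
}

#' @export
tidy.camera_calibration <- function(x, ...) {
  cam_err <- x$errors |>
    dplyr::group_by(.data$camera) |>
    dplyr::summarise(mean_error = mean(.data$error, na.rm = TRUE),
                     n_obs = dplyr::n())
  dplyr::left_join(tidy(x$rig), cam_err, by = "camera")
}

#' @export
glance.camera_calibration <- function(x, ...) {
  x$summary
}
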