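# Synthetic data generators: camera rigs, calibration-board sequences,
# smooth trajectories, corruption models, and rigid articulated walkers.
# Every generator is deterministic under its seed and stores ground truth
# alongside the corrupted outputs, so all estimators in the package can
# be validated without recorded footage.

#' Simulate a ring of cameras aimed at the origin
#'
#' `n_cameras` identical perspective cameras evenly spaced on a circle
#' of given radius at height `elevation`, all looking at the world
#' origin, mirroring the classic arrangement of cameras distributed
#' around a subject.
#'
#' @param n_cameras Number of cameras.
#' @param radius Ring radius (world units).
#' @param elevation Camera height above the origin's plane.
#' @param image_size `(width, height)` pixels.
#' @param focal Focal length in pixels.
#' @param k1 Radial distortion coefficient.
#' @param seed Unused randomness slot kept for interface symmetry; the
#'   rig is deterministic.
#' @return A `camera_rig`.
#' @export
simulate_rig <- function(n_cameras = 6L, radius = 10, elevation = 3,
                         image_size = c(832L, 632L), focal = 600,
                         k1 = -0.02, seed = 1L) {
  stopifnot(n_cameras >= 1)
  cams <- lapply(seq_len(n_cameras), function(i) {
    phi <- 2 * pi * (i - 1) / n_cameras
    C <- c(radius * cos(phi), radius * sin(phi), elevation)
    zc <- -C / sqrt(sum(C^2)) # optical axis toward the origin
    up <- c(0, 0, 1)
    xc <- pracma_cross(zc, up)
    nx <- sqrt(sum(xc^2))
    if (nx < 1e-9) { xc <- c(1, 0, 0); nx <- 1 }
    xc <- xc / nx
    yc <- pracma_cross(zc, xc)
    R <- rbind(xc, yc, zc) # world -> camera rows
    camera(name = sprintf("cam%02d", i),
           rotation = matrix_to_rotvec(R),
           translation = as.numeric(-R %*% C),
           focal = focal, k1 = k1, image_size = image_size)
  })
  camera_rig(cams)
}

#' Simulate a calibration-board sequence with corrupted detections
#'
#' The board follows a smooth random pose trajectory (a low-pass
#' filtered random walk in rotation-vector/translation space) through
#' the shared view volume; its corners are projected into every camera,
#' perturbed with isotropic Gaussian pixel noise, a fraction of
#' detections displaced by a large outlier offset, and corners
#' projecting outside the image dropped.
#'
#' @param rig A `camera_rig`.
#' @param board A [board_geometry()].
#' @param n_frames Number of frames.
#' @param noise_px Gaussian detection noise (pixels).
#' @param outlier_frac Fraction of detections turned into outliers.
#' @param outlier_px Outlier displacement magnitude (pixels).
#' @param rot_amp Board orientation excursion (radians).
#' @param trans_amp Board position excursion (world units); defaults to
#'   a fraction of the rig radius.
#' @param seed Integer seed.
#' @return List with `detections` (camera, frame, corner_id, x, y),
#'   `points3d` ground truth (frame, corner_id, x, y, z) and `poses`.
#' @export
simulate_board_sequence <- function(rig, board, n_frames = 300L,
                                    noise_px = 0, outlier_frac = 0,
                                    outlier_px = 30, rot_amp = 0.9,
                                    trans_amp = NULL, seed = 1L) {
  set.seed(sub_seed(seed, "board-sequence"))
  centers <- vapply(rig, camera_center, numeric(3))
  if (is.null(trans_amp)) {
    trans_amp <- 0.15 * mean(sqrt(colSums(centers^2)))
  }
  smooth_walk <- function(n, amp) {
    v <- rnorm(n + 60)
    bf <- signal::butter(2, 0.04)
    v <- signal::filtfilt(bf, v)[31:(n + 30)]
    v <- v - mean(v) # keep the walk centered in the shared view volume
    amp * v / max(sd(v), 1e-9)
  }
  pose_mat <- vapply(1:6, function(k) {
    amp <- if (k <= 3) rot_amp else trans_amp
    smooth_walk(n_frames, amp)
  }, numeric(n_frames))
  corners <- board$corners

  det <- list(); pts <- list()
  for (f in seq_len(n_frames)) {
    rv <- pose_mat[f, 1:3]; tv <- pose_mat[f, 4:6]
    R <- rotvec_to_matrix(rv)
    Pw <- as.matrix(corners[, c("x", "y", "z")]) %*% t(R) +
      matrix(tv, nrow(corners), 3, byrow = TRUE)
    pts[[f]] <- tibble(frame = f, corner_id = corners$corner_id,
                       x = Pw[, 1], y = Pw[, 2], z = Pw[, 3])
    for (cm in rig) {
      uv <- project_points(Pw, cm)
      keep <- is.finite(uv[, 1]) &
        uv[, 1] >= 0 & uv[, 1] <= cm$image_size[1] &
        uv[, 2] >= 0 & uv[, 2] <= cm$image_size[2]
      if (!any(keep)) next
      det[[length(det) + 1L]] <- tibble(
        camera = cm$name, frame = f,
        corner_id = corners$corner_id[keep],
        x = uv[keep, 1], y = uv[keep, 2]
      )
    }
  }
  detections <- dplyr::bind_rows(det)
  n <- nrow(detections)
  if (noise_px > 0) {
    detections$x <- detections$x + rnorm(n, sd = noise_px)
    detections$y <- detections$y + rnorm(n, sd = noise_px)
  }
  if (outlier_frac > 0) {
    is_out <- runif(n) < outlier_frac
    ang <- runif(n, 0, 2 * pi)
    detections$x[is_out] <- detections$x[is_out] +
      outlier_px * cos(ang[is_out])
    detections$y[is_out] <- detections$y[is_out] +
      outlier_px * sin(ang[is_out])
    detections$outlier <- is_out
  }
  list(detections = detections, points3d = dplyr::bind_rows(pts),
       poses = pose_mat)
}

#' Simulate smooth ground-truth trajectories
#'
#' White noise passed through a zero-phase low-pass filter with the
#' given cutoff (cycles/sample) and normalized to unit variance -- the
#' standard bench signal for evaluating temporal regularization.
#'
#' @param n Number of trajectories (default 30).
#' @param length Samples per trajectory (default 500).
#' @param cutoff Low-pass cutoff in cycles/sample (default 0.12).
#' @param seed Integer seed.
#' @return Tibble (trajectory, frame, value).
#' @export
simulate_trajectories <- function(n = 30L, length = 500L, cutoff = 0.12,
                                  seed = 1L) {
  stopifnot(cutoff > 0, cutoff < 0.5)
  set.seed(sub_seed(seed, "trajectories"))
  bf <- signal::butter(4, 2 * cutoff)
  purrr::map_dfr(seq_len(n), function(i) {
    pad <- 100L
    w <- rnorm(length + 2 * pad)
    v <- signal::filtfilt(bf, w)[(pad + 1):(pad + length)]
    v <- (v - mean(v)) / sd(v)
    tibble(trajectory = i, frame = seq_len(length), value = v)
  })
}

#' Corrupt trajectories with noise and missing samples
#'
#' Additive white Gaussian noise plus uniformly random removal of a
#' fraction of the samples, emulating noisy triangulated points with
#' dropped detections.
#'
#' @param traj Tibble from [simulate_trajectories()].
#' @param noise_sd Noise standard deviation; default 0.3 x the signal's
#'   standard deviation.
#' @param missing_frac Fraction of samples masked (default 0.10).
#' @param seed Integer seed.
#' @return Same tibble with a corrupted `value` (NA where removed).
#' @export
corrupt_trajectories <- function(traj, noise_sd = NULL, missing_frac = 0.10,
                                 seed = 1L) {
  set.seed(sub_seed(seed, "corrupt"))
  if (is.null(noise_sd)) noise_sd <- 0.3 * sd(traj$value, na.rm = TRUE)
  out <- traj
  if (noise_sd > 0) out$value <- out$value + rnorm(nrow(out), sd = noise_sd)
  if (missing_frac > 0) {
    out$value[runif(nrow(out)) < missing_frac] <- NA_real_
  }
  out
}

#' A small articulated example skeleton
#'
#' Two 4-joint legs hanging from a rigid body axis, plus three body
#' reference keypoints (origin, anterior, dorsal) for the body frame.
#'
#' @param n_legs Number of legs (1-6).
#' @return A [skeleton()].
#' @export
example_skeleton <- function(n_legs = 2L) {
  legs <- lapply(seq_len(n_legs), function(l) {
    paste0("leg", l, "_", c("hip", "knee", "ankle", "tip"))
  })
  joints <- c("origin", "head", "dorsum", unlist(legs))
  limbs <- purrr::map_dfr(legs, function(ch) {
    tibble(joint_a = ch[-length(ch)], joint_b = ch[-1],
           weight = c(1, 1, 0.5)) # distal-most segment more flexible
  })
  skeleton(joints, limbs, chains = legs)
}

#' Simulate a rigid articulated walker
#'
#' Joint angles follow sinusoidal gait patterns (per-joint amplitude,
#' phase and a shared stride frequency); positions come from forward
#' kinematics, so limb lengths are exactly constant over time. Body
#' reference keypoints are fixed in the world frame.
#'
#' @param skel A [skeleton()] whose chains are the legs.
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param stride_hz Gait frequency (Hz).
#' @param lengths Segment lengths for each chain (recycled).
#' @param seed Seed for amplitude/phase draws.
#' @return Trajectory tibble (frame, joint, x, y, z) with attributes
#'   `frame_rate` and `limb_lengths`.
#' @export
simulate_articulated_walker <- function(skel, n_frames = 200L,
                                        frame_rate = 300,
                                        stride_hz = 10,
                                        lengths = c(1.2, 1.0, 0.8),
                                        seed = 1L) {
  if (!length(skel$chains)) abort("skeleton has no chains")
  set.seed(sub_seed(seed, "walker"))
  t_s <- (seq_len(n_frames) - 1) / frame_rate
  body <- list(origin = c(0, 0, 0), head = c(2, 0, 0), dorsum = c(0, 0, 2))
  rows <- list()
  for (nm in intersect(names(body), skel$joints)) {
    rows[[length(rows) + 1L]] <- tibble(
      frame = seq_len(n_frames), joint = nm,
      x = body[[nm]][1], y = body[[nm]][2], z = body[[nm]][3]
    )
  }
  for (ci in seq_along(skel$chains)) {
    ch <- skel$chains[[ci]]
    n_seg <- length(ch) - 1L
    Ls <- rep_len(lengths, n_seg)
    side <- if (ci %% 2 == 0) -1 else 1
    base <- c(0.5 * ci, side * 0.8, 0)
    rot_mean <- runif(n_seg, -30, 30)
    rot_amp <- runif(n_seg, 5, 20)
    flex_mean <- runif(n_seg, 70, 120)
    flex_amp <- runif(n_seg, 10, 25)
    phase <- runif(n_seg, 0, 2 * pi)
    Pall <- array(NA_real_, c(n_frames, n_seg + 1, 3))
    for (f in seq_len(n_frames)) {
      wt <- 2 * pi * stride_hz * t_s[f]
      rot <- rot_mean + rot_amp * sin(wt + phase)
      flex <- clamp(flex_mean + flex_amp * sin(wt + phase + pi / 3), 5, 175)
      Pall[f, , ] <- forward_kinematics_chain(rot, flex, Ls, base = base)
    }
    for (j in seq_len(n_seg + 1)) {
      rows[[length(rows) + 1L]] <- tibble(
        frame = seq_len(n_frames), joint = ch[j],
        x = Pall[, j, 1], y = Pall[, j, 2], z = Pall[, j, 3]
      )
    }
  }
  traj <- dplyr::bind_rows(rows)
  ll <- skel$limbs
  if (nrow(ll)) {
    ll$length <- vapply(seq_len(nrow(ll)), function(l) {
      a <- traj[traj$joint == ll$joint_a[l], c("x", "y", "z")]
      b <- traj[traj$joint == ll$joint_b[l], c("x", "y", "z")]
      median(sqrt(rowSums((as.matrix(a) - as.matrix(b))^2)))
    }, numeric(1))
  }
  attr(traj, "frame_rate") <- frame_rate
  attr(traj, "limb_lengths") <- ll
  traj
}

#' Project a 3D trajectory into a rig and corrupt the detections
#'
#' Produces multi-candidate keypoint detections the way a 2D detector
#' would: the true projection jittered with Gaussian noise (rank-1
#' candidate with a high score), occasional teleporting outliers that
#' replace the top candidate, missing detections, and spurious
#' low-score duplicate candidates.
#'
#' @param traj Trajectory tibble (frame, joint, x, y, z).
#' @param rig A `camera_rig`.
#' @param noise_px Gaussian jitter (pixels).
#' @param outlier_frac Fraction of top candidates teleported.
#' @param outlier_px Outlier displacement (pixels).
#' @param missing_frac Fraction of detections dropped.
#' @param n_spurious Spurious extra candidates per detection (mean of a
#'   Poisson draw).
#' @param seed Integer seed.
#' @return Candidates tibble (camera, frame, joint, rank, x, y, score).
#' @export
simulate_detections <- function(traj, rig, noise_px = 2, outlier_frac = 0.05,
                                outlier_px = 80, missing_frac = 0.02,
                                n_spurious = 0.5, seed = 1L) {
  set.seed(sub_seed(seed, "detections"))
  joints <- unique(traj$joint)
  out <- list()
  for (cm in rig) {
    uv <- project_points(as.matrix(traj[, c("x", "y", "z")]), cm)
    n <- nrow(uv)
    keep <- is.finite(uv[, 1]) & runif(n) >= missing_frac
    x <- uv[, 1] + rnorm(n, sd = noise_px)
    y <- uv[, 2] + rnorm(n, sd = noise_px)
    tele <- runif(n) < outlier_frac
    ang <- runif(n, 0, 2 * pi)
    x[tele] <- x[tele] + outlier_px * cos(ang[tele])
    y[tele] <- y[tele] + outlier_px * sin(ang[tele])
    score <- clamp(rnorm(n, 0.95, 0.05), 0, 1)
    main <- tibble(camera = cm$name, frame = traj$frame, joint = traj$joint,
                   rank = 1L, x = x, y = y, score = score)[keep, ]
    n_sp <- stats::rpois(1, n_spurious * n)
    if (n_sp > 0) {
      pick <- sample(which(keep), n_sp, replace = TRUE)
      spur <- tibble(
        camera = cm$name, frame = traj$frame[pick], joint = traj$joint[pick],
        rank = 2L,
        x = uv[pick, 1] + runif(n_sp, -150, 150),
        y = uv[pick, 2] + runif(n_sp, -150, 150),
        score = clamp(rnorm(n_sp, 0.3, 0.15), 0, 1)
      )
      main <- dplyr::bind_rows(main, spur)
    }
    out[[length(out) + 1L]] <- main
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$camera, .data$frame,
                   match(.data$joint, joints), .data$rank)
}

#' RMSE and averaged Welch spectra of a reconstruction
#'
#' @param truth,recon Tibbles (trajectory, frame, value) on the same
#'   grid.
#' @param fs Sampling rate for the spectra (cycles/sample by default).
#' @return List with `rmse` and `psd` (tibble: freq, truth, recon).
#' @export
evaluate_reconstruction <- function(truth, recon, fs = 1) {
  j <- dplyr::inner_join(truth, recon, by = c("trajectory", "frame"),
                         suffix = c("_t", "_r"))
  ok <- is.finite(j$value_t) & is.finite(j$value_r)
  rmse <- sqrt(mean((j$value_t[ok] - j$value_r[ok])^2))
  psd_of <- function(col) {
    j |>
      dplyr::group_by(.data$trajectory) |>
      dplyr::group_map(function(df, key) {
        v <- df[[col]]
        v[!is.finite(v)] <- mean(v, na.rm = TRUE)
        welch_psd(v, fs = fs)
      }) |>
      dplyr::bind_rows() |>
      dplyr::group_by(.data$freq) |>
      dplyr::summarise(power = mean(.data$power), .groups = "drop")
  }
  pt <- psd_of("value_t"); pr <- psd_of("value_r")
  list(rmse = rmse,
       psd = tibble(freq = pt$freq, truth = pt$power, recon = pr$power))
}
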