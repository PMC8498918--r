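test_that("linear triangulation recovers noiseless points exactly", {
  rig <- simulate_rig(2, radius = 8, elevation = 2, focal = 500, k1 = -0.05)
  set.seed(51)
  P <- matrix(rnorm(30, sd = 0.5), 10, 3)
  det <- project_scene(P, rig, joints = rep("j", 10), frames = 1:10)
  tri <- triangulate_points(det, rig)
  expect_lt(max(abs(as.matrix(tri[, c("x", "y", "z")]) - P)), 1e-9)
  expect_lt(max(tri$error), 1e-6)
})

test_that("two orthogonal cameras triangulate to the hand-computed ray intersection", {
  # cam A looks down +z from z=-5, cam B looks along -x from x=5 (axes 90 deg)
  camA <- camera("A", rotation = c(0, 0, 0), translation = c(0, 0, 5),
                 focal = 400, image_size = c(800, 600))
  RB <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0)) # optical axis along -x
  camB <- camera("B", rotation = matrix_to_rotvec(RB),
                 translation = as.numeric(-RB %*% c(5, 0, 0)),
                 focal = 400, image_size = c(800, 600))
  rig <- camera_rig(list(camA, camB))
  p <- c(0.7, -0.4, 1.2)
  det <- project_scene(matrix(p, 1), rig, joints = "j")
  tri <- triangulate_points(det, rig)
  expect_equal(as.numeric(tri[1, c("x", "y", "z")]), p, tolerance = 1e-9)
})

test_that("a single camera yields a missing point", {
  rig <- simulate_rig(3, focal = 500)
  det <- tibble::tibble(camera = "cam01", frame = 1L, joint = "j",
                        x = 400, y = 300)
  tri <- triangulate_points(det, rig)
  expect_true(is.na(tri$x))
  expect_equal(tri$n_cams, 1L)
})

test_that("RANSAC equals linear triangulation with exactly two cameras", {
  rig <- simulate_rig(2, focal = 500)
  set.seed(52)
  P <- matrix(rnorm(15, sd = 0.4), 5, 3)
  det <- project_scene(P, rig, joints = rep("j", 5), frames = 1:5)
  a <- triangulate_points(det, rig, method = "linear")
  b <- triangulate_points(det, rig, method = "ransac")
  expect_equal(as.matrix(a[, c("x", "y", "z")]),
               as.matrix(b[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("RANSAC excludes a corrupted view and beats all-view linear", {
  rig <- simulate_rig(4, focal = 600)
  set.seed(53)
  P <- matrix(rnorm(60, sd = 0.4), 20, 3)
  det <- project_scene(P, rig, joints = rep("j", 20), frames = 1:20)
  det$x[det$camera == "cam02"] <- det$x[det$camera == "cam02"] + 50
  lin <- triangulate_points(det, rig, method = "linear")
  ran <- triangulate_points(det, rig, method = "ransac")
  err <- function(tr) sqrt(rowSums((as.matrix(tr[, c("x", "y", "z")]) - P)^2))
  expect_lt(mean(err(ran)), mean(err(lin)))
  expect_lt(max(err(ran)), 1e-6) # selected pair avoids the corrupted view
})

test_that("RANSAC agrees with an independent exhaustive pair enumeration", {
  rig <- simulate_rig(5, focal = 600)
  set.seed(54)
  P <- matrix(rnorm(24, sd = 0.4), 8, 3)
  det <- project_scene(P, rig, joints = rep("j", 8), frames = 1:8,
                       noise_px = 3)
  got <- triangulate_points(det, rig, method = "ransac")
  for (f in 1:8) {
    d <- det[det$frame == f, ]
    best <- Inf; best_p <- NULL
    cams <- unique(d$camera)
    for (a in seq_along(cams)) for (b in seq_len(a - 1)) {
      sub <- d[d$camera %in% cams[c(a, b)], ]
      p_ab <- triangulate_points(sub, rig)
      obj <- 0
      for (cc in cams[c(a, b)]) {
        pr <- project_points(as.matrix(p_ab[, c("x", "y", "z")]), rig[[cc]])
        o <- sub[sub$camera == cc, ]
        obj <- obj + sum((pr[1, ] - c(o$x, o$y))^2)
      }
      if (obj < best) { best <- obj; best_p <- p_ab }
    }
    expect_equal(as.numeric(got[got$frame == f, c("x", "y", "z")]),
                 as.numeric(best_p[, c("x", "y", "z")]), tolerance = 1e-9)
  }
})

test_that("3D median filter removes spikes and respects missing data", {
  traj <- tibble::tibble(frame = 1:21, joint = "j", x = 1, y = 2, z = 3)
  expect_equal(median_filter_3d(traj, 5)$x, rep(1, 21))
  traj$z[11] <- 13
  out <- median_filter_3d(traj, 5)
  expect_equal(out$z, rep(3, 21))
  all_na <- tibble::tibble(frame = 1:10, joint = "k", x = NA_real_,
                           y = NA_real_, z = NA_real_)
  expect_true(all(is.na(median_filter_3d(all_na, 3)$x)))
})

test_that("regularizers off reduces to per-frame reprojection-minimizing triangulation", {
  sc <- rigid_chain_scene(n_frames = 12, noise_px = 1.5, seed = 55)
  skel_nolimb <- skeleton(sc$skel$joints, NULL, sc$skel$chains)
  fit <- triangulate_regularized(sc$det, sc$rig, skel_nolimb,
                                 beta_time = 0, alpha_limb = 0,
                                 robust_norm = "linear", max_iter = 60)
  ref <- mocap3d:::triangulate_nonlinear(sc$det, sc$rig)
  j <- dplyr::inner_join(fit$traj, ref, by = c("frame", "joint"),
                         suffix = c("_a", "_b"))
  d <- sqrt((j$x_a - j$x_b)^2 + (j$y_a - j$y_b)^2 + (j$z_a - j$z_b)^2)
  expect_lt(max(d, na.rm = TRUE), 1e-4)
})

test_that("gamma is the reciprocal mean frame-to-frame displacement", {
  # constant displacement of 0.5 units/frame -> gamma = 2
  rig <- simulate_rig(4, focal = 600, k1 = 0)
  n <- 10
  traj <- tibble::tibble(frame = 1:n, joint = "j",
                         x = 0.5 * (1:n) - 2.5, y = 0, z = 0)
  det <- purrr::map_dfr(seq_along(rig), function(i) {
    uv <- project_points(as.matrix(traj[, c("x", "y", "z")]), rig[[i]])
    tibble::tibble(camera = names(rig)[i], frame = traj$frame, joint = "j",
                   x = uv[, 1], y = uv[, 2])
  })
  skel1 <- skeleton("j", NULL, list())
  fit <- triangulate_regularized(det, rig, skel1, max_iter = 3)
  expect_equal(fit$gamma, 2, tolerance = 1e-6)
  expect_equal(fit$alpha_time, 4, tolerance = 1e-6)
})

test_that("spatiotemporal regularization stabilizes limb lengths and lowers RMSE", {
  sc <- rigid_chain_scene(n_frames = 60, noise_px = 2, seed = 56)
  fit <- triangulate_regularized(sc$det, sc$rig, sc$skel, max_iter = 30)
  lin <- triangulate_points(sc$det, sc$rig)
  limb_sd <- function(tr, a, b) {
    A <- tr[tr$joint == a, ]; B <- tr[tr$joint == b, ]
    sd(sqrt((A$x - B$x)^2 + (A$y - B$y)^2 + (A$z - B$z)^2), na.rm = TRUE)
  }
  expect_lt(limb_sd(fit$traj, "j1", "j2"), limb_sd(lin, "j1", "j2"))
  expect_lt(limb_sd(fit$traj, "j2", "j3"), limb_sd(lin, "j2", "j3"))
  e_reg <- position_errors(fit$traj, sc$traj)$summary$mean_error
  e_lin <- position_errors(lin, sc$traj)$summary$mean_error
  expect_lt(e_reg, e_lin)
  # recovered limb-length parameters within 2% of ground truth
  expect_lt(max(abs(fit$limb_lengths$length - sc$limb_truth) / sc$limb_truth),
            0.02)
  # temporal term reduces mean squared acceleration vs the initialization
  acc <- function(tr) {
    tr |>
      dplyr::group_by(joint) |>
      dplyr::arrange(frame, .by_group = TRUE) |>
      dplyr::summarise(a = mean(diff(x, differences = 2)^2 +
                                  diff(y, differences = 2)^2 +
                                  diff(z, differences = 2)^2,
                                na.rm = TRUE)) |>
      dplyr::pull(a) |> mean()
  }
  expect_lt(acc(fit$traj), acc(lin))
})

test_that("raising the reprojection drop threshold never loses points", {
  sc <- rigid_chain_scene(n_frames = 20, noise_px = 2, seed = 57)
  det <- sc$det
  # corrupt some observations so some reprojection errors are large
  set.seed(58)
  bad <- sample(nrow(det), 30)
  det$x[bad] <- det$x[bad] + 60
  kept <- vapply(c(5, 10, 20, 40), function(thr) {
    fit <- triangulate_regularized(det, sc$rig, sc$skel, reproj_drop = thr,
                                   max_iter = 10)
    sum(is.finite(fit$traj$x))
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("finite-difference velocities follow the frame rate", {
  traj <- tibble::tibble(frame = 1:10, joint = "j",
                         x = (1:10), y = 0, z = 5)
  v <- estimate_derivative(traj, frame_rate = 300)
  expect_equal(v$vx[1:9], rep(300, 9))
  expect_equal(v$vz[1:9], rep(0, 9))
  expect_true(is.na(v$vx[10]))
  traj$x[4] <- NA
  v2 <- estimate_derivative(traj, frame_rate = 300)
  expect_true(all(is.na(v2$vx[3:4])))
})

test_that("angle errors are absolute and circular for rotations", {
  ref <- tibble::tibble(frame = 1:4, joint = "j",
                        kind = c("flexion", "flexion", "rotation", "rotation"),
                        value_deg = c(90, 120, 179, -179))
  pred <- ref
  pred$value_deg <- c(92, 117, -179, 179) # rotation wraps across +-180
  ae <- angle_errors(pred, ref)
  expect_equal(ae$errors$error, c(2, 3, 2, 2))
  expect_equal(angle_errors(ref, ref)$summary$mean_error, 0)
})

test_that("position errors and paired comparisons match a direct computation", {
  ref <- tibble::tibble(frame = 1:50, joint = "j", x = 0, y = 0, z = 0)
  pred <- ref; pred$x <- 2
  pe <- position_errors(pred, ref)
  expect_equal(pe$summary$mean_error, 2)
  expect_equal(position_errors(ref, ref)$summary$mean_error, 0)
  set.seed(59)
  p1 <- ref; p1$x <- rnorm(50); p2 <- ref; p2$x <- rnorm(50)
  cmp <- position_errors(p1, ref, pred2 = p2)
  d <- abs(p1$x) - abs(p2$x)
  tt <- t.test(d)
  expect_equal(cmp$summary$mean_diff, mean(d))
  expect_equal(cmp$summary$ci_low, tt$conf.int[1], tolerance = 1e-9)
  expect_equal(cmp$summary$ci_high, tt$conf.int[2], tolerance = 1e-9)
  expect_error(position_errors(pred, ref[0, ]), "overlap")
})
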