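test_that("greedy covisibility graph follows the hand-traced rule", {
  # shared-frame counts AB=50, BC=40, AC=30 -> edges {AB, BC}, AC skipped
  mk <- function(cam, frames) {
    tidyr::expand_grid(camera = cam, frame = frames, corner_id = 0:3) |>
      dplyr::mutate(x = 50, y = 50)
  }
  det <- dplyr::bind_rows(
    mk("A", 1:50), mk("B", 1:50),          # AB share 1..50
    mk("B", 101:140), mk("C", 101:140),    # BC share 40
    mk("A", 201:230), mk("C", 201:230)     # AC share 30
  )
  g <- build_camera_graph(det)
  sel <- g$edges
  expect_equal(nrow(sel), 2)
  expect_setequal(paste(sel$cam_a, sel$cam_b),
                  c("A B", "B C"))
  # two cameras sharing one frame -> single edge
  g2 <- build_camera_graph(dplyr::bind_rows(mk("A", 1), mk("B", 1)))
  expect_equal(nrow(g2$edges), 1)
})

test_that("a disconnected camera graph is an error naming the components", {
  mk <- function(cam, frames) {
    tidyr::expand_grid(camera = cam, frame = frames, corner_id = 0:3) |>
      dplyr::mutate(x = 50, y = 50)
  }
  det <- dplyr::bind_rows(mk("A", 1:5), mk("B", 1:5),
                          mk("C", 101:105), mk("D", 101:105))
  expect_error(build_camera_graph(det), "disconnected")
  expect_error(build_camera_graph(det), "A,B")
  expect_error(build_camera_graph(det), "C,D")
})

test_that("focal initialization recovers the true focal from board views", {
  rig <- simulate_rig(1, radius = 10, elevation = 3, focal = 600, k1 = 0)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = 20, noise_px = 0,
                                seed = 4)
  f <- initialize_intrinsics(bs$detections, board, image_sizes_for(rig))
  expect_lt(abs(f[["cam01"]] - 600) / 600, 0.01)
})

test_that("fronto-parallel-only views trigger the FOV-prior fallback", {
  # a board parallel to the image plane at fixed depths is degenerate
  # for focal estimation from homographies
  cm <- camera("cam01", focal = 600, image_size = c(832, 632))
  board <- board_geometry()
  det <- purrr::map_dfr(1:10, function(f) {
    P <- as.matrix(board$corners[, c("x", "y", "z")])
    P[, 3] <- 5 + 0.2 * f
    uv <- project_points(P, cm)
    tibble::tibble(camera = "cam01", frame = f,
                   corner_id = board$corners$corner_id,
                   x = uv[, 1], y = uv[, 2])
  })
  expect_warning(
    f <- initialize_intrinsics(det, board, list(cam01 = c(832, 632))),
    "FOV prior")
  expect_equal(unname(f[["cam01"]]), 1.2 * 832)
})

test_that("extrinsics initialization recovers relative poses exactly", {
  rig <- simulate_rig(6, radius = 10, elevation = 3, focal = 600, k1 = 0)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = 40, noise_px = 0,
                                seed = 6)
  g <- build_camera_graph(bs$detections)
  f <- initialize_intrinsics(bs$detections, board, image_sizes_for(rig))
  rig0 <- initialize_extrinsics(g, bs$detections, board, f,
                                image_sizes_for(rig))
  # up to a global rigid transform, camera centers must match
  al <- align_similarity(camera_centers(rig0), camera_centers(rig))
  expect_lt(al$rmsd, 1e-3)
  pts <- mocap3d:::triangulate_board(rig0, bs$detections)
  e <- reprojection_errors(rig0, bs$detections, pts)
  expect_lt(mean(e$error, na.rm = TRUE), 0.2)
})

test_that("reprojection errors are the per-observation residual norms", {
  rig <- simulate_rig(3, focal = 600, k1 = 0)
  set.seed(8)
  P <- matrix(rnorm(15, sd = 0.5), 5, 3)
  det <- project_scene(P, rig, joints = as.character(0:4))
  det$corner_id <- as.integer(det$joint)
  pts <- tibble::tibble(frame = 1L, corner_id = 0:4,
                        x = P[, 1], y = P[, 2], z = P[, 3])
  e0 <- reprojection_errors(rig, det, pts)
  expect_lt(max(e0$error), 1e-9)
  det_shift <- det; det_shift$x <- det_shift$x + 3
  e3 <- reprojection_errors(rig, det_shift, pts)
  expect_equal(e3$error, rep(3, nrow(det_shift)), tolerance = 1e-9)
})

test_that("bundle adjustment refines a perturbed rig to machine precision", {
  rig <- simulate_rig(4, radius = 10, elevation = 3, focal = 600, k1 = 0)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = 25, noise_px = 0,
                                seed = 9)
  det <- bs$detections
  # start at truth: parameters should not move
  fit0 <- bundle_adjust(rig, det, loss = "linear", max_iter = 5)
  expect_lt(fit0$summary$final_mean_error, 1e-7)
  # perturb extrinsics by ~5 degrees / 5% translation
  rig_p <- rig
  set.seed(10)
  for (i in seq_along(rig_p)) {
    rig_p[[i]]$rotation <- rig_p[[i]]$rotation + rnorm(3, sd = 0.04)
    rig_p[[i]]$translation <- rig_p[[i]]$translation * (1 + rnorm(3, sd = 0.03))
  }
  fit <- bundle_adjust(rig_p, det, loss = "linear", max_iter = 40)
  expect_lt(fit$summary$final_mean_error, 1e-5)
  expect_lte(fit$summary$final_mean_error, fit$summary$initial_mean_error)
  al <- align_similarity(camera_centers(fit$rig), camera_centers(rig))
  expect_lt(al$rmsd, 1e-5)
})

test_that("all three losses are accepted and never increase the cost", {
  rig <- simulate_rig(3, focal = 600, k1 = 0)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = 15, noise_px = 1,
                                seed = 12)
  for (loss in c("linear", "huber", "soft_l1")) {
    fit <- bundle_adjust(rig, bs$detections, loss = loss, max_iter = 8)
    expect_lte(fit$summary$final_mean_error,
               fit$summary$initial_mean_error + 1e-9)
  }
})

test_that("iterative bundle adjustment uses a geometric threshold decay", {
  mu <- 15 * (1 / 15)^((0:11) / 11)
  expect_equal(mu[1], 15)
  expect_equal(mu[12], 1)
  expect_true(all(diff(log(mu)) < 0))
  expect_equal(diff(log(mu)), rep(diff(log(mu))[1], 11))
})

test_that("iterative bundle adjustment beats plain linear-loss BA on outliers", {
  rig <- simulate_rig(6, radius = 10, elevation = 3, focal = 600, k1 = 0)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = 60, noise_px = 0.5,
                                outlier_frac = 0.05, outlier_px = 30,
                                seed = 13)
  det <- bs$detections[, c("camera", "frame", "corner_id", "x", "y")]
  sizes <- image_sizes_for(rig)
  g <- build_camera_graph(det)
  f <- initialize_intrinsics(det, board, sizes)
  rig0 <- initialize_extrinsics(g, det, board, f, sizes)

  it <- iterative_bundle_adjust(rig0, det, max_frames = 60, seed = 1,
                                max_iter_inner = 8, board = board)
  ba <- bundle_adjust(rig0, det, loss = "linear", max_iter = 25)
  pts_ba <- mocap3d:::triangulate_board(ba$rig, det)
  err_ba <- reprojection_errors(ba$rig, det, pts_ba)

  inlier <- !bs$detections$outlier
  mean_it <- mean(it$errors$error[inlier], na.rm = TRUE)
  mean_ba <- mean(err_ba$error[inlier], na.rm = TRUE)
  expect_lt(mean_it, mean_ba)
  # field rule of thumb: a usable calibration stays under 3 px
  expect_lt(mean_it, 3)
  # rig accuracy after similarity alignment at least as good
  al_it <- align_similarity(camera_centers(it$rig), camera_centers(rig))
  al_ba <- align_similarity(camera_centers(ba$rig), camera_centers(rig))
  expect_lte(al_it$rmsd, al_ba$rmsd + 1e-6)
})
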