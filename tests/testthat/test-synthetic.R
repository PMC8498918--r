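test_that("simulated rigs are evenly spaced rings aimed at the origin", {
  rig <- simulate_rig(6, radius = 10, elevation = 3)
  centers <- camera_centers(rig)
  expect_equal(unname(sqrt(rowSums(centers[, 1:2]^2))), rep(10, 6))
  # adjacent optical axes separated by 360/6 degrees in azimuth
  az <- atan2(centers[, 2], centers[, 1])
  expect_equal(unname(sort(diff(sort(az))) * 180 / pi), rep(60, 5),
               tolerance = 1e-9)
  # the origin projects to the image center in every camera
  for (cm in rig) {
    uv <- project_points(matrix(c(0, 0, 0), 1), cm)
    expect_equal(as.numeric(uv), cm$principal_point, tolerance = 1e-9)
  }
  expect_identical(tidy(simulate_rig(4, seed = 2)),
                   tidy(simulate_rig(4, seed = 2)))
})

test_that("noiseless board detections reproject exactly and the board is 2 mm wide", {
  board <- board_geometry()
  expect_equal(board$square_size, 0.5)
  expect_equal(board$marker_size, 0.375)
  expect_equal(max(board$corners$x) - min(board$corners$x), 2)
  expect_error(board_geometry(marker_size = 0.6, square_size = 0.5),
               "marker_size")
  rig <- simulate_rig(4, focal = 600)
  bs <- simulate_board_sequence(rig, board, n_frames = 10, noise_px = 0,
                                seed = 71)
  e <- reprojection_errors(rig, bs$detections, bs$points3d)
  expect_lt(max(e$error), 1e-9)
})

test_that("board corruption statistics are recoverable", {
  board <- board_geometry()
  rig <- simulate_rig(4, focal = 600)
  bs <- simulate_board_sequence(rig, board, n_frames = 40, noise_px = 1,
                                outlier_frac = 0.07, outlier_px = 40,
                                seed = 72)
  n <- nrow(bs$detections)
  expect_gt(n, 3000)
  rate <- mean(bs$detections$outlier)
  expect_lt(abs(rate - 0.07), 3 * sqrt(0.07 * 0.93 / n))
  e <- reprojection_errors(rig, bs$detections[!bs$detections$outlier, ],
                           bs$points3d)
  # per-axis noise of 1 px -> residual norm ~ Rayleigh, mean sqrt(pi/2)
  expect_equal(mean(e$error), sqrt(pi / 2), tolerance = 0.05)
})

test_that("synthetic trajectories are band-limited unit-variance and seeded", {
  tr <- simulate_trajectories(n = 30, length = 500, cutoff = 0.12, seed = 73)
  expect_equal(dplyr::n_distinct(tr$trajectory), 30)
  expect_equal(max(tr$frame), 500)
  sds <- tr |> dplyr::group_by(trajectory) |>
    dplyr::summarise(s = sd(value)) |> dplyr::pull(s)
  expect_equal(sds, rep(1, 30), tolerance = 1e-9)
  # spectral content above 1.5x cutoff is < 1% of that below the cutoff
  ps <- tr |> dplyr::group_by(trajectory) |>
    dplyr::group_map(~ welch_psd(.x$value)) |> dplyr::bind_rows() |>
    dplyr::group_by(freq) |> dplyr::summarise(p = mean(power))
  hi <- mean(ps$p[ps$freq > 0.18]); lo <- mean(ps$p[ps$freq < 0.12])
  expect_lt(hi / lo, 0.01)
  expect_identical(tr, simulate_trajectories(30, 500, 0.12, seed = 73))
})

test_that("trajectory corruption has the stated missing rate and noise", {
  tr <- simulate_trajectories(n = 20, length = 500, seed = 74)
  co <- corrupt_trajectories(tr, noise_sd = 0.25, missing_frac = 0.10,
                             seed = 75)
  n <- nrow(co)
  expect_lt(abs(mean(is.na(co$value)) - 0.10), 0.01)
  resid <- co$value - tr$value
  expect_equal(sd(resid, na.rm = TRUE), 0.25, tolerance = 0.02)
  # identity case
  id <- corrupt_trajectories(tr, noise_sd = 0, missing_frac = 0, seed = 76)
  expect_identical(id$value, tr$value)
})

test_that("the articulated walker is rigid and triangulates back exactly", {
  skel <- example_skeleton(2)
  traj <- simulate_articulated_walker(skel, n_frames = 40, seed = 77)
  ll <- attr(traj, "limb_lengths")
  for (l in seq_len(nrow(ll))) {
    a <- traj[traj$joint == ll$joint_a[l], ]
    b <- traj[traj$joint == ll$joint_b[l], ]
    lens <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    expect_lt(sd(lens), 1e-12)
  }
  rig <- simulate_rig(6, radius = 10, elevation = 3, focal = 600)
  det <- purrr::map_dfr(seq_along(rig), function(i) {
    uv <- project_points(as.matrix(traj[, c("x", "y", "z")]), rig[[i]])
    tibble::tibble(camera = names(rig)[i], frame = traj$frame,
                   joint = traj$joint, x = uv[, 1], y = uv[, 2])
  })
  tri <- triangulate_points(det, rig)
  j <- dplyr::inner_join(tri, traj, by = c("frame", "joint"),
                         suffix = c("_h", ""))
  expect_lt(max(abs(j$x_h - j$x)), 1e-8)
  expect_identical(traj,
                   simulate_articulated_walker(skel, n_frames = 40, seed = 77))
})

test_that("simulated detections have the requested corruption statistics", {
  skel <- example_skeleton(1)
  traj <- simulate_articulated_walker(skel, n_frames = 100, seed = 78)
  rig <- simulate_rig(3, focal = 600)
  cand <- simulate_detections(traj, rig, noise_px = 2, outlier_frac = 0.05,
                              missing_frac = 0.1, n_spurious = 0.5, seed = 79)
  top <- cand[cand$rank == 1L, ]
  n_expected <- nrow(traj) * length(rig)
  expect_lt(abs(nrow(top) / n_expected - 0.9), 0.02)
  expect_gt(nrow(cand[cand$rank > 1L, ]), 0)
  expect_true(all(cand$score >= 0 & cand$score <= 1))
})

test_that("reconstruction evaluation reports zero RMSE for identical signals", {
  tr <- simulate_trajectories(n = 3, length = 200, seed = 80)
  ev <- evaluate_reconstruction(tr, tr)
  expect_equal(ev$rmse, 0)
  # white noise has a flat spectrum: max/min band power within ~3 dB
  set.seed(81)
  wn <- tidyr::expand_grid(trajectory = 1:20, frame = 1:512)
  wn$value <- rnorm(nrow(wn))
  ps <- evaluate_reconstruction(wn, wn)$psd
  band <- ps$truth[ps$freq > 0.05 & ps$freq < 0.45]
  expect_lt(max(band) / min(band), 2)
})

test_that("temporal regularization reconstructs corrupted trajectories", {
  tr <- simulate_trajectories(n = 10, length = 500, seed = 82)
  co <- corrupt_trajectories(tr, seed = 83) # noise_sd = 0.3 x signal sd
  rec <- co |>
    dplyr::group_by(trajectory) |>
    dplyr::mutate(value = smooth_temporal(value, beta = 2, order = 2)) |>
    dplyr::ungroup()
  ev_c <- evaluate_reconstruction(tr, co)
  ev_r <- evaluate_reconstruction(tr, rec)
  expect_lt(ev_r$rmse, ev_c$rmse)
})
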