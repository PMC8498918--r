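test_that("flexion angle matches hand-computed and law-of-cosines values", {
  expect_equal(flexion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(flexion_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_true(is.na(flexion_angle(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))))
  set.seed(61)
  for (i in 1:30) {
    p <- matrix(rnorm(9), 3)
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    b <- sqrt(sum((p[3, ] - p[2, ])^2))
    cc <- sqrt(sum((p[1, ] - p[3, ])^2))
    oracle <- acos(mocap3d:::clamp((a^2 + b^2 - cc^2) / (2 * a * b), -1, 1)) *
      180 / pi
    expect_equal(flexion_angle(p[1, ], p[2, ], p[3, ]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("a planar convex chain has zero rotation and flexion equal to the vertex angles", {
  # arc in the world x-z plane, all bends the same way
  P <- rbind(c(0, 0, 0), c(1, 0, 1), c(2, 0, 1.6), c(3, 0, 1.9))
  traj <- tibble::tibble(frame = 1, joint = c("a", "b", "c", "d"),
                         x = P[, 1], y = P[, 2], z = P[, 3])
  ang <- chain_angles(traj, c("a", "b", "c", "d"))
  rot <- ang$value_deg[ang$kind == "rotation"]
  expect_equal(rot, rep(0, 3), tolerance = 1e-9)
  expect_equal(ang$value_deg[ang$kind == "abduction"], 0)
  fb <- ang$value_deg[ang$joint == "b" & ang$kind == "flexion"]
  fc <- ang$value_deg[ang$joint == "c" & ang$kind == "flexion"]
  expect_equal(fb, flexion_angle(P[1, ], P[2, ], P[3, ]), tolerance = 1e-9)
  expect_equal(fc, flexion_angle(P[2, ], P[3, ], P[4, ]), tolerance = 1e-9)
})

test_that("forward kinematics and chain angles are mutual inverses", {
  set.seed(62)
  for (i in 1:10) {
    n_seg <- sample(2:4, 1)
    rot <- runif(n_seg, -170, 170)
    flex <- runif(n_seg, 15, 165)
    L <- runif(n_seg, 0.5, 2)
    P <- forward_kinematics_chain(rot, flex, L, base = rnorm(3))
    joints <- paste0("j", seq_len(n_seg + 1))
    traj <- tibble::tibble(frame = 1, joint = joints,
                           x = P[, 1], y = P[, 2], z = P[, 3])
    ang <- chain_angles(traj, joints)
    rot_hat <- ang$value_deg[ang$kind == "rotation"]
    flex_hat <- ang$value_deg[ang$kind == "flexion"]
    expect_equal(rot_hat, rot, tolerance = 1e-6)
    expect_equal(flex_hat, flex, tolerance = 1e-6)
    # and back: positions reproduced
    P2 <- forward_kinematics_chain(rot_hat, flex_hat, L, base = P[1, ])
    expect_lt(max(abs(P2 - P)), 1e-9)
  }
})

test_that("chain angles are invariant to global rigid motion with the body frame", {
  skel <- example_skeleton(1)
  traj <- simulate_articulated_walker(skel, n_frames = 15, seed = 63)
  bf <- c("origin", "head", "dorsum")
  a1 <- chain_angles(traj, skel$chains[[1]], body_frame = bf)
  # rotate + translate everything rigidly
  R <- rotvec_to_matrix(c(0.3, -0.5, 0.8)); tr <- c(5, -2, 3)
  P <- as.matrix(traj[, c("x", "y", "z")]) %*% t(R) +
    matrix(tr, nrow(traj), 3, byrow = TRUE)
  traj2 <- traj; traj2$x <- P[, 1]; traj2$y <- P[, 2]; traj2$z <- P[, 3]
  a2 <- chain_angles(traj2, skel$chains[[1]], body_frame = bf)
  expect_equal(a1$value_deg, a2$value_deg, tolerance = 1e-8)
})

test_that("degenerate straight segments report missing rotation", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 1))
  traj <- tibble::tibble(frame = 1, joint = c("a", "b", "c", "d"),
                         x = P[, 1], y = P[, 2], z = P[, 3])
  ang <- chain_angles(traj, c("a", "b", "c", "d"))
  # collinear a-b-c: flexion at b is 180, rotation at b undefined
  expect_equal(ang$value_deg[ang$joint == "b" & ang$kind == "flexion"], 180)
  expect_true(is.na(ang$value_deg[ang$joint == "b" & ang$kind == "rotation"]))
})

test_that("angle derivatives unwrap circular angles", {
  ang <- tibble::tibble(frame = 1:3, joint = "j", kind = "rotation",
                        value_deg = c(359, 1, 3))
  d <- angle_derivatives(ang, frame_rate = 1)
  expect_equal(d$deg_per_s[1:2], c(2, 2))
  const <- tibble::tibble(frame = 1:5, joint = "j", kind = "flexion",
                          value_deg = 90)
  expect_equal(angle_derivatives(const, 100)$deg_per_s[1:4], rep(0, 4))
  # smooth series: derivative matches direct differentiation
  set.seed(64)
  v <- cumsum(rnorm(50))
  sm <- tibble::tibble(frame = 1:50, joint = "j", kind = "flexion",
                       value_deg = v)
  expect_equal(angle_derivatives(sm, 10)$deg_per_s[1:49], diff(v) * 10)
})

test_that("feature matrices have the documented closed-form shape", {
  # 6 legs x 3 angles (+ derivatives), 32-sample windows -> 1152 columns
  TT <- 200
  A6 <- matrix(rnorm(TT * 18), TT, 18)
  f6 <- build_feature_vectors(A6, window = 32, stride = 8)
  expect_equal(ncol(f6), 1152)
  expect_equal(nrow(f6), floor((TT - 32) / 8) + 1)
  # 2 legs x 3 angles, 24-sample windows -> 288 columns
  A2 <- matrix(rnorm(TT * 6), TT, 6)
  f2 <- build_feature_vectors(A2, window = 24, stride = 8)
  expect_equal(ncol(f2), 288)
  # series shorter than the window: zero rows
  expect_equal(nrow(build_feature_vectors(A2[1:10, ], window = 24)), 0)
  # standardization: column means ~0, sds ~1
  cm <- colMeans(f6, na.rm = TRUE)
  expect_lt(max(abs(cm)), 1e-8)
  # zero-variance column handling
  Az <- cbind(A2[, 1:2], 5)
  expect_warning(fz <- build_feature_vectors(Az, window = 24, stride = 8),
                 "zero-variance")
  expect_true(all(is.finite(fz[, !apply(is.na(fz), 2, any)])))
})

test_that("phase estimation tracks a pure sinusoid and stays in range", {
  fs <- 300
  t <- seq_len(900)
  x <- sin(2 * pi * 10 * t / fs)
  ph <- estimate_phase(x, frame_rate = fs)
  expect_true(all(ph >= -pi & ph < pi))
  inner <- 100:800
  dp <- diff(unwrap_angle(ph[inner]))
  expect_equal(median(dp), 2 * pi * 10 / fs, tolerance = 1e-3)
  # constant signal: all phases missing
  expect_true(all(is.na(estimate_phase(rep(3, 100), frame_rate = fs))))
})

test_that("phase is consistent at successive flexion maxima of a gait angle", {
  fs <- 300
  t <- seq_len(1500)
  x0 <- 30 * sin(2 * pi * 8 * t / fs)
  set.seed(65)
  x <- 90 + x0 + rnorm(1500, sd = 0.5)
  ph <- estimate_phase(x, frame_rate = fs)
  # interior maxima located on the clean oscillation
  peaks <- which(diff(sign(diff(x0))) == -2) + 1
  peaks <- peaks[peaks > 150 & peaks < 1350]
  spread <- diff(range(ph[peaks]))
  expect_lt(spread, 0.2)
})
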