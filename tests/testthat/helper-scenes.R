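# Shared fixture builders. Everything is generated in code with fixed
# seeds; no data files.

# project a set of 3D points into every camera of a rig as a detections
# tibble (one joint per row of P when joints not given)
project_scene <- function(P, rig, joints = NULL, frames = NULL,
                          noise_px = 0, seed = 1L) {
  set.seed(seed)
  n <- nrow(P)
  joints <- joints %||% paste0("j", seq_len(n))
  frames <- frames %||% rep(1L, n)
  purrr::map_dfr(seq_along(rig), function(i) {
    uv <- project_points(P, rig[[i]])
    tibble::tibble(camera = names(rig)[i], frame = frames, joint = joints,
                   x = uv[, 1] + rnorm(n, sd = noise_px),
                   y = uv[, 2] + rnorm(n, sd = noise_px))
  })
}

# small rigid 3-joint chain moving smoothly, for triangulation tests
rigid_chain_scene <- function(n_frames = 60, noise_px = 2, seed = 2) {
  skel <- skeleton(c("j1", "j2", "j3"),
                   tibble::tibble(joint_a = c("j1", "j2"),
                                  joint_b = c("j2", "j3")),
                   chains = list(c("j1", "j2", "j3")))
  rig <- simulate_rig(6, radius = 10, elevation = 3, focal = 600, k1 = 0)
  set.seed(seed)
  tt <- seq_len(n_frames)
  base <- cbind(0.3 * sin(tt / 8), 0.3 * cos(tt / 10), 0.2 * sin(tt / 13))
  traj <- dplyr::bind_rows(
    tibble::tibble(frame = tt, joint = "j1", x = base[, 1], y = base[, 2],
                   z = base[, 3]),
    tibble::tibble(frame = tt, joint = "j2", x = base[, 1] + 1, y = base[, 2],
                   z = base[, 3] + 0.3),
    tibble::tibble(frame = tt, joint = "j3", x = base[, 1] + 1.8,
                   y = base[, 2] + 0.4, z = base[, 3]))
  det <- purrr::map_dfr(seq_along(rig), function(i) {
    uv <- project_points(as.matrix(traj[, c("x", "y", "z")]), rig[[i]])
    tibble::tibble(camera = names(rig)[i], frame = traj$frame,
                   joint = traj$joint,
                   x = uv[, 1] + rnorm(nrow(uv), sd = noise_px),
                   y = uv[, 2] + rnorm(nrow(uv), sd = noise_px))
  })
  list(skel = skel, rig = rig, traj = traj, det = det,
       limb_truth = c(sqrt(1 + 0.09), sqrt(0.64 + 0.16 + 0.09)))
}

image_sizes_for <- function(rig) {
  lapply(setNames(names(rig), names(rig)), function(cm) rig[[cm]]$image_size)
}

camera_centers <- function(rig) {
  t(vapply(rig, function(cm) {
    R <- rotvec_to_matrix(cm$rotation)
    as.numeric(-t(R) %*% cm$translation)
  }, numeric(3)))
}
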