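# Reduced pinhole camera model: 8 free parameters per camera
# (3 rotation, 3 translation, 1 focal length, 1 radial distortion k1).
# The principal point is fixed at the image center and fx = fy, skew = 0.

#' Construct a camera
#'
#' A camera is parameterized by an axis-angle rotation and translation
#' (world -> camera), a single focal length in pixels, and one radial
#' distortion coefficient `k1` acting on normalized image coordinates.
#' The principal point is fixed at the image center, so each camera has
#' exactly 8 free parameters.
#'
#' @param name Camera identifier.
#' @param rotation Length-3 axis-angle rotation vector (radians).
#' @param translation Length-3 translation (world units).
#' @param focal Focal length in pixels (> 0).
#' @param k1 Radial distortion coefficient (dimensionless).
#' @param image_size Integer `(width, height)` in pixels.
#' @return An object of class `camera`.
#' @export
camera <- function(name, rotation = c(0, 0, 0), translation = c(0, 0, 0),
                   focal, k1 = 0, image_size = c(832L, 632L)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  if (length(rotation) != 3 || length(translation) != 3) {
    abort("rotation and translation must have length 3")
  }
  if (!is.finite(focal) || focal <= 0) abort("focal must be a positive number")
  if (!all(is.finite(c(rotation, translation, k1, image_size)))) {
    abort("camera parameters must be finite")
  }
  structure(list(
    name = as.character(name),
    rotation = rotation,
    translation = translation,
    focal = as.numeric(focal),
    principal_point = as.numeric(image_size) / 2,
    k1 = as.numeric(k1),
    image_size = as.integer(image_size)
  ), class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("<camera '%s'> f=%.1f px, k1=%.4g, image %dx%d\n",
              x$name, x$focal, x$k1, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Bundle cameras into a rig
#'
#' @param cameras A list of [camera()] objects.
#' @return An object of class `camera_rig` (a named list of cameras).
#' @export
camera_rig <- function(cameras) {
  stopifnot(length(cameras) >= 1, all(vapply(cameras, inherits, TRUE, "camera")))
  names(cameras) <- vapply(cameras, `[[`, "", "name")
  if (anyDuplicated(names(cameras))) abort("camera names must be unique")
  structure(cameras, class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig> %d cameras: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Summarize a rig as a tibble
#'
#' @param x A `camera_rig`.
#' @param ... Unused.
#' @return One row per camera with rotation, translation, focal and k1.
#' @export
tidy.camera_rig <- function(x, ...) {
  purrr::map_dfr(x, function(cm) {
    tibble(
      camera = cm$name,
      rx = cm$rotation[1], ry = cm$rotation[2], rz = cm$rotation[3],
      tx = cm$translation[1], ty = cm$translation[2], tz = cm$translation[3],
      focal = cm$focal, k1 = cm$k1,
      width = cm$image_size[1], height = cm$image_size[2]
    )
  })
}

#' Apply radial distortion in normalized image coordinates
#'
#' `x' = x (1 + k1 r^2)` with `r^2 = x^2 + y^2` (higher-order coefficients
#' fixed to zero).
#'
#' @param xy Nx2 matrix of normalized (unitless) coordinates.
#' @param k1 Radial distortion coefficient.
#' @return Nx2 matrix of distorted coordinates.
#' @export
distort_points <- function(xy, k1) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  r2 <- rowSums(xy^2)
  xy * (1 + k1 * r2)
}

#' Invert the radial distortion by fixed-point iteration
#'
#' @param xy Nx2 matrix of distorted normalized coordinates.
#' @param k1 Radial distortion coefficient.
#' @param max_iter,tol Iteration controls.
#' @return Nx2 matrix of undistorted coordinates; rows that fail to
#'   converge are set to `NA` with a warning.
#' @export
undistort_points <- function(xy, k1, max_iter = 20L, tol = 1e-10) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (k1 == 0) return(xy)
  u <- xy
  for (i in seq_len(max_iter)) {
    r2 <- rowSums(u^2)
    u_new <- xy / (1 + k1 * r2)
    delta <- sqrt(rowSums((u_new - u)^2))
    u <- u_new
    if (all(is.na(delta) | delta < tol)) break
  }
  r2 <- rowSums(u^2)
  resid <- sqrt(rowSums((u * (1 + k1 * r2) - xy)^2))
  bad <- !is.finite(resid) | resid > 1e-8
  if (any(bad)) {
    warn(sprintf("undistort_points: %d point(s) did not converge; set missing",
                 sum(bad)))
    u[bad, ] <- NA_real_
  }
  u
}

#' Project 3D world points into a camera
#'
#' Composition: rigid extrinsics, perspective divide, radial distortion in
#' normalized coordinates, then focal/principal-point scaling. Points at
#' or behind the camera plane are returned as missing.
#'
#' @param points Nx3 matrix (or data frame with columns x, y, z) of world
#'   coordinates.
#' @param cam A [camera()].
#' @param eps Depth below which a point counts as behind the camera.
#' @return Nx2 matrix of pixel coordinates (NA rows for unprojectable
#'   points).
#' @export
project_points <- function(points, cam, eps = 1e-8) {
  if (!inherits(cam, "camera")) abort("cam must be a camera object")
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  R <- rotvec_to_matrix(cam$rotation)
  Xc <- points %*% t(R) + matrix(cam$translation, nrow(points), 3, byrow = TRUE)
  z <- Xc[, 3]
  behind <- !is.finite(z) | z <= eps
  xn <- Xc[, 1] / z
  yn <- Xc[, 2] / z
  d <- distort_points(cbind(xn, yn), cam$k1)
  px <- cbind(cam$focal * d[, 1] + cam$principal_point[1],
              cam$focal * d[, 2] + cam$principal_point[2])
  px[behind, ] <- NA_real_
  colnames(px) <- c("x", "y")
  px
}

# pixel -> normalized undistorted coordinates
pixels_to_normalized <- function(xy, cam) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- cbind((xy[, 1] - cam$principal_point[1]) / cam$focal,
             (xy[, 2] - cam$principal_point[2]) / cam$focal)
  undistort_points(n, cam$k1)
}

# camera center in world coordinates
camera_center <- function(cam) {
  R <- rotvec_to_matrix(cam$rotation)
  as.numeric(-t(R) %*% cam$translation)
}

#' Write a rig to a calibration file
#'
#' JSON with one section per camera plus a metadata block. Numeric values
#' are written with 17 significant digits so that a read/write round trip
#' is bit-exact.
#'
#' @param rig A `camera_rig`.
#' @param path Output file path.
#' @param units Length unit of the translations (metadata only).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(rig, path, units = "mm") {
  stopifnot(inherits(rig, "camera_rig"))
  payload <- list(
    metadata = list(
      format = "mocap3d-calibration-v1",
      units = units,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_cameras = length(rig)
    ),
    cameras = lapply(unclass(rig), function(cm) {
      list(name = cm$name,
           image_size = cm$image_size,
           rotation = cm$rotation,
           translation = cm$translation,
           focal = cm$focal,
           principal_point = cm$principal_point,
           k1 = cm$k1)
    })
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a rig from a calibration file
#'
#' @param path Path written by [write_calibration()].
#' @return A `camera_rig`.
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cams <- payload$cameras
  if (is.data.frame(cams)) cams <- split(cams, seq_len(nrow(cams)))
  rig <- lapply(cams, function(cm) {
    cm <- as.list(cm)
    camera(name = cm$name,
           rotation = unlist(cm$rotation),
           translation = unlist(cm$translation),
           focal = unlist(cm$focal),
           k1 = unlist(cm$k1),
           image_size = unlist(cm$image_size))
  })
  camera_rig(rig)
}
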