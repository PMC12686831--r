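#' @useDynLib sinusnav, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# Camera convention used throughout: right-handed, +z forward along the
# optical axis, +x right, +y down. Poses are stored camera-to-world: the
# rotation's columns are the camera axes expressed in the world frame and
# the translation is the camera center.

## ---- intrinsics ------------------------------------------------------------

#' Pinhole camera intrinsics with Brown-Conrady distortion
#'
#' Focal lengths and principal point are in pixels; `dist` holds the
#' radial-tangential coefficients `(k1, k2, p1, p2)` applied after
#' perspective division. Higher-order radial terms are not modelled.
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels, inside the image.
#' @param width,height Image size in pixels.
#' @param dist Numeric length-4 vector `(k1, k2, p1, p2)`; defaults to zeros.
#' @return An object of class `sn_intrinsics`.
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height, dist = c(0, 0, 0, 0)) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  dist <- as.numeric(dist)
  if (length(dist) != 4 || any(!is.finite(dist)))
    stop("dist must be 4 finite coefficients (k1, k2, p1, p2)")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 dist = dist),
            class = "sn_intrinsics")
}

#' @export
print.sn_intrinsics <- function(x, ...) {
  cat(sprintf("intrinsics %dx%d px, f=(%.2f, %.2f), c=(%.2f, %.2f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  if (any(x$dist != 0))
    cat("  distortion (k1,k2,p1,p2):", paste(signif(x$dist, 6), collapse = " "), "\n")
  invisible(x)
}

#' Read / write camera intrinsics as YAML
#'
#' The file stores `fx, fy, cx, cy, width, height` (pixels) and a `dist`
#' list of the four Brown-Conrady coefficients.
#'
#' @param path File path.
#' @return `read_intrinsics` returns an `sn_intrinsics` object.
#' @export
read_intrinsics <- function(path) {
  y <- yaml::read_yaml(path)
  intrinsics(y$fx, y$fy, y$cx, y$cy, y$width, y$height,
             dist = if (is.null(y$dist)) c(0, 0, 0, 0) else unlist(y$dist))
}

#' @rdname read_intrinsics
#' @param intr An `sn_intrinsics` object.
#' @export
write_intrinsics <- function(intr, path) {
  yaml::write_yaml(list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
                        width = intr$width, height = intr$height,
                        units = "pixel", dist = as.list(intr$dist)), path,
                   precision = 17)
  invisible(path)
}

## ---- rigid poses -----------------------------------------------------------

nearest_rotation <- function(R) {
  s <- svd(R)
  U <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  U %*% t(s$v)
}

check_rotation <- function(R, tol_accept = 1e-9, tol_repair = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || any(!is.finite(R)))
    stop("rotation must be a finite 3x3 matrix")
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > tol_accept) {
    if (err > tol_repair) stop("matrix is not orthonormal (error ", signif(err, 3), ")")
    R <- nearest_rotation(R)
  }
  if (abs(det(R) - 1) > tol_repair) stop("rotation must have determinant +1")
  R
}

#' Rigid camera pose (camera-to-world)
#'
#' `rotation` columns are the camera x/y/z axes in the target frame;
#' `translation` is the camera center (mm in the CT frame, arbitrary units
#' in the SLAM frame). Orthonormality violations below 1e-6 are repaired by
#' projection to the nearest rotation; larger violations are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 camera center.
#' @param frame Label for the reference frame (e.g. `"ct"`, `"slam"`).
#' @return An object of class `sn_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                       frame = "world") {
  rotation <- check_rotation(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3, all(is.finite(translation)))
  structure(list(R = rotation, t = translation, frame = frame),
            class = "sn_pose")
}

#' @export
print.sn_pose <- function(x, ...) {
  q <- rot_to_quat(x$R)
  cat(sprintf("pose [%s]: center (%.4g, %.4g, %.4g), quat xyzw (%.4f %.4f %.4f %.4f)\n",
              x$frame, x$t[1], x$t[2], x$t[3], q[1], q[2], q[3], q[4]))
  invisible(x)
}

#' Compose and invert rigid poses
#'
#' Poses act as transforms from their camera frame to the world frame;
#' `pose_compose(a, b)` is the transform `a` followed after `b`
#' (apply `b`, then `a`), and `pose_invert(a)` satisfies
#' `pose_compose(a, pose_invert(a)) = identity`.
#'
#' @param a,b `sn_pose` objects.
#' @return An `sn_pose`.
#' @export
pose_compose <- function(a, b) {
  rigid_pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, frame = a$frame)
}

#' @rdname pose_compose
#' @export
pose_invert <- function(a) {
  rigid_pose(t(a$R), as.numeric(-t(a$R) %*% a$t), frame = paste0(a$frame, "^-1"))
}

#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `p` to `scale * rotation %*% p + translation`. Used for the
#' SLAM-to-CT registration, where `scale` is CT millimetres per SLAM unit.
#'
#' @param scale Positive scalar.
#' @param rotation 3x3 rotation.
#' @param translation Length-3 vector (mm).
#' @return An object of class `sn_similarity`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1, is.finite(scale), scale > 0)
  rotation <- check_rotation(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3, all(is.finite(translation)))
  structure(list(s = scale, R = rotation, t = translation),
            class = "sn_similarity")
}

#' @export
print.sn_similarity <- function(x, ...) {
  cat(sprintf("similarity: scale %.6g, translation (%.4g, %.4g, %.4g)\n",
              x$s, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a similarity transform to points or to a pose
#'
#' For a pose the rotation becomes `T$R %*% pose$R` and the camera center
#' maps as a point, so projecting transformed points with the transformed
#' pose reproduces the original image geometry.
#'
#' @param T An `sn_similarity`.
#' @param points n x 3 matrix of points.
#' @param pose An `sn_pose`.
#' @param frame Frame label for the transformed pose.
#' @return Transformed points (n x 3) or pose.
#' @export
apply_similarity_points <- function(T, points) {
  points <- as_points(points)
  sweep(T$s * points %*% t(T$R), 2, T$t, `+`)
}

#' @rdname apply_similarity_points
#' @export
apply_similarity_pose <- function(T, pose, frame = pose$frame) {
  rigid_pose(T$R %*% pose$R, T$s * as.numeric(T$R %*% pose$t) + T$t,
             frame = frame)
}

#' @rdname apply_similarity_points
#' @export
similarity_invert <- function(T) {
  Rinv <- t(T$R)
  similarity_transform(1 / T$s, Rinv, as.numeric(-Rinv %*% T$t) / T$s)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  points
}

## ---- projection ------------------------------------------------------------

# Brown-Conrady forward model on normalized (ideal) coordinates.
distort_normalized <- function(intr, xy) {
  k1 <- intr$dist[1]; k2 <- intr$dist[2]; p1 <- intr$dist[3]; p2 <- intr$dist[4]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd)
}

#' Project 3D points into a camera
#'
#' Points are expressed in the pose's frame; they are brought into the
#' camera frame via the inverse of the camera-to-world pose, divided by
#' depth, distorted with the Brown-Conrady model, and mapped to pixels.
#'
#' @param intr `sn_intrinsics`.
#' @param pose `sn_pose` (camera-to-world).
#' @param points n x 3 matrix (or length-3 vector).
#' @return List with `pixels` (n x 2) and `valid` (logical): a projection is
#'   valid when the camera-frame depth is positive and the pixel falls in
#'   `[0, width) x [0, height)`. Pixels of invalid points are still returned
#'   (possibly `NaN` for points at zero depth).
#' @export
project_points <- function(intr, pose, points) {
  points <- as_points(points)
  stopifnot(all(is.finite(points)))
  cam <- sweep(points, 2, pose$t) %*% pose$R  # rows are camera-frame coords
  z <- cam[, 3]
  xy <- cbind(cam[, 1] / z, cam[, 2] / z)
  xyd <- distort_normalized(intr, xy)
  px <- cbind(intr$fx * xyd[, 1] + intr$cx, intr$fy * xyd[, 2] + intr$cy)
  valid <- z > 1e-12 & is.finite(px[, 1]) & is.finite(px[, 2]) &
    px[, 1] >= 0 & px[, 1] < intr$width & px[, 2] >= 0 & px[, 2] < intr$height
  list(pixels = px, valid = valid)
}

#' Backproject pixels at known depth
#'
#' Inverse of the ideal (distortion-free) pinhole projection: pixels are
#' treated as undistorted coordinates (apply [undistort_points()] first when
#' the camera has distortion). Depth is the camera-frame z coordinate, not
#' the ray length.
#'
#' @param intr `sn_intrinsics`.
#' @param pose `sn_pose` whose frame the returned points live in.
#' @param pixels n x 2 matrix (or length-2 vector).
#' @param depth Positive depth(s), recycled to the number of pixels.
#' @return n x 3 matrix of points in the pose's frame.
#' @export
backproject_pixels <- function(intr, pose, pixels, depth) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  pixels <- as.matrix(pixels)
  depth <- rep_len(as.numeric(depth), nrow(pixels))
  if (any(!is.finite(depth)) || any(depth <= 0)) stop("depth must be positive")
  xn <- (pixels[, 1] - intr$cx) / intr$fx
  yn <- (pixels[, 2] - intr$cy) / intr$fy
  cam <- cbind(xn * depth, yn * depth, depth)
  sweep(cam %*% t(pose$R), 2, pose$t, `+`)
}

#' Undistort pixel coordinates
#'
#' Inverts the Brown-Conrady forward model by fixed-point iteration on
#' normalized coordinates; returns ideal (zero-distortion) pixel
#' coordinates. With all-zero coefficients the input is returned exactly.
#'
#' @param intr `sn_intrinsics`.
#' @param pixels n x 2 matrix (or length-2 vector).
#' @param max_iter,tol Iteration controls; residual is measured in pixels.
#' @return n x 2 matrix of ideal pixel coordinates.
#' @export
undistort_points <- function(intr, pixels, max_iter = 50, tol = 1e-8) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  pixels <- as.matrix(pixels)
  if (all(intr$dist == 0)) return(pixels)
  xd <- (pixels[, 1] - intr$cx) / intr$fx
  yd <- (pixels[, 2] - intr$cy) / intr$fy
  x <- xd; y <- yd
  k1 <- intr$dist[1]; k2 <- intr$dist[2]; p1 <- intr$dist[3]; p2 <- intr$dist[4]
  fscale <- max(intr$fx, intr$fy)
  for (it in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    rad <- 1 + k1 * r2 + k2 * r2^2
    x_new <- (xd - (2 * p1 * x * y + p2 * (r2 + 2 * x^2))) / rad
    y_new <- (yd - (p1 * (r2 + 2 * y^2) + 2 * p2 * x * y)) / rad
    delta <- max(abs(x_new - x), abs(y_new - y)) * fscale
    x <- x_new; y <- y_new
    if (!is.finite(delta)) stop("undistortion diverged: invalid coefficients")
    if (delta < tol) break
    if (it == max_iter) stop("undistortion did not converge: invalid coefficients")
  }
  cbind(intr$fx * x + intr$cx, intr$fy * y + intr$cy)
}

#' Distort ideal pixel coordinates (forward Brown-Conrady model)
#'
#' @inheritParams undistort_points
#' @return n x 2 matrix of distorted pixel coordinates.
#' @export
distort_points <- function(intr, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  pixels <- as.matrix(pixels)
  xy <- cbind((pixels[, 1] - intr$cx) / intr$fx,
              (pixels[, 2] - intr$cy) / intr$fy)
  xyd <- distort_normalized(intr, xy)
  cbind(intr$fx * xyd[, 1] + intr$cx, intr$fy * xyd[, 2] + intr$cy)
}

## ---- quaternions and axis-angle -------------------------------------------

#' Rotation matrix / quaternion conversions
#'
#' Quaternions are unit, ordered `(qx, qy, qz, qw)` as in TUM trajectory
#' files; `rot_to_quat` returns the representative with `qw >= 0`.
#'
#' @param q Length-4 quaternion `(qx, qy, qz, qw)`.
#' @param R 3x3 rotation matrix.
#' @return A rotation matrix, or a quaternion.
#' @export
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' @rdname quat_to_rot
#' @export
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, 0.25 * s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c(0.25 * s, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[3, 2] - R[2, 3]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 2] + R[2, 1]) / s, 0.25 * s, (R[2, 3] + R[3, 2]) / s,
           (R[1, 3] - R[3, 1]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, 0.25 * s,
           (R[2, 1] - R[1, 2]) / s)
  }
  if (q[4] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Axis-angle (rotation vector) exponential and logarithm
#'
#' @param w Length-3 rotation vector (axis times angle in radians).
#' @param R 3x3 rotation matrix.
#' @return `rotvec_to_rot` returns a rotation matrix; `rot_to_rotvec` a
#'   length-3 vector with angle in `[0, pi]`.
#' @export
rotvec_to_rot <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew3(w)
  if (th < 1e-12) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

#' @rdname rotvec_to_rot
#' @export
rot_to_rotvec <- function(R) {
  q <- rot_to_quat(R)
  v <- q[1:3]; w <- q[4]
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(2 * v)  # small-angle limit
  2 * atan2(n, w) * v / n
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

## ---- TUM trajectory I/O ----------------------------------------------------

#' Read / write trajectories in TUM format
#'
#' One pose per line: `timestamp tx ty tz qx qy qz qw`, whitespace
#' separated; `#` lines are comments. Translations are camera centers in
#' the trajectory's frame; quaternions rotate camera to world.
#'
#' @param path File path.
#' @param frame Frame label attached to the poses on reading.
#' @return `read_tum` returns a list with `timestamps` (numeric) and
#'   `poses` (list of `sn_pose`).
#' @export
read_tum <- function(path, frame = "world") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  m <- do.call(rbind, lapply(strsplit(lines, "[[:space:]]+"), as.numeric))
  if (ncol(m) != 8) stop("TUM lines must have 8 fields")
  poses <- lapply(seq_len(nrow(m)), function(i)
    rigid_pose(quat_to_rot(m[i, 5:8]), m[i, 2:4], frame = frame))
  list(timestamps = m[, 1], poses = poses)
}

#' @rdname read_tum
#' @param traj List with `timestamps` and `poses` as returned by `read_tum`.
#' @export
write_tum <- function(traj, path) {
  stopifnot(length(traj$timestamps) == length(traj$poses))
  lines <- vapply(seq_along(traj$poses), function(i) {
    p <- traj$poses[[i]]
    q <- rot_to_quat(p$R)
    paste(format(c(traj$timestamps[i], p$t, q), digits = 17, trim = TRUE,
                 scientific = FALSE), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

trajectory_centers <- function(poses) {
  do.call(rbind, lapply(poses, `[[`, "t"))
}
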