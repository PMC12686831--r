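## Trajectory evaluation: translation / rotation error metrics against a
## reference (tracker) trajectory, retrospective similarity alignment,
## half-split target registration error, and fiducial point-to-mesh
## distances.

#' Translation error between two poses
#'
#' Euclidean (L2) distance between the camera centers, in the shared frame.
#'
#' @param est,ref `sn_pose` objects in the same frame.
#' @return Distance (mm when poses are in the CT frame).
#' @export
translation_error <- function(est, ref) {
  sqrt(sum((est$t - ref$t)^2))
}

#' General rotation error (residual-rotation angle)
#'
#' Angle of the residual rotation `R %*% t(R_ref)`, computed as
#' `acos((trace - 1) / 2)` with the argument clamped to `[-1, 1]` to absorb
#' floating-point excursions. The rotation-matrix inverse is taken as the
#' transpose (orthonormality is enforced at pose construction).
#'
#' @param R,R_ref 3x3 rotation matrices (or `sn_pose` objects).
#' @return Angle in degrees.
#' @export
rotation_error_general <- function(R, R_ref) {
  if (inherits(R, "sn_pose")) R <- R$R
  if (inherits(R_ref, "sn_pose")) R_ref <- R_ref$R
  R <- check_rotation(R); R_ref <- check_rotation(R_ref)
  delta <- R %*% t(R_ref)
  arg <- (sum(diag(delta)) - 1) / 2
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' Per-axis rotation errors
#'
#' Angle between corresponding camera axes (columns of the rotation
#' matrices) of the estimated and reference poses; translations play no
#' role.
#'
#' @param est,ref `sn_pose` objects (or rotation matrices).
#' @return Named vector `(x, y, z)` of angles in degrees.
#' @export
rotation_error_per_axis <- function(est, ref) {
  R <- if (inherits(est, "sn_pose")) est$R else est
  Rr <- if (inherits(ref, "sn_pose")) ref$R else ref
  ang <- vapply(1:3, function(a) {
    d <- sum(R[, a] * Rr[, a])
    acos(min(1, max(-1, d))) * 180 / pi
  }, numeric(1))
  setNames(ang, c("x", "y", "z"))
}

#' Closed-form similarity alignment of paired point sets (Umeyama)
#'
#' Least-squares `scale * R %*% x + t` fit mapping `source` points onto
#' `target` points. Used for retrospective trajectory alignment (on camera
#' centers) and for the half-split TRE registration.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3).
#' @param with_scale Estimate the scale (default) or fix it at 1.
#' @return An `sn_similarity`.
#' @export
umeyama_alignment <- function(source, target, with_scale = TRUE) {
  X <- as_points(source); Y <- as_points(target)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  Sigma <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(Sigma)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: points are collinear or coincident")
  S <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
  R <- sv$u %*% S %*% t(sv$v)
  var_x <- sum(Xc^2) / nrow(X)
  s <- if (with_scale) sum(diag(diag(sv$d) %*% S)) / var_x else 1
  if (s <= 0) stop("degenerate geometry: non-positive scale")
  similarity_transform(s, R, my - s * as.numeric(R %*% mx))
}

#' Align an estimated trajectory to a reference by a similarity transform
#'
#' Fits the closed-form similarity on camera centers of timestamp-paired
#' poses (the retrospective evaluation mode: scale and registration are
#' recovered from the reference trajectory itself).
#'
#' @param est,ref Trajectories: lists with `timestamps` and `poses`.
#' @param with_scale Estimate scale (default `TRUE`).
#' @return An `sn_similarity` mapping estimated coordinates onto reference
#'   coordinates.
#' @export
align_similarity <- function(est, ref, with_scale = TRUE) {
  p <- pair_by_timestamp(est, ref)
  umeyama_alignment(trajectory_centers(p$est$poses),
                    trajectory_centers(p$ref$poses),
                    with_scale = with_scale)
}

pair_by_timestamp <- function(est, ref, tol = NULL) {
  te <- est$timestamps; tr <- ref$timestamps
  if (is.null(tol)) {
    step <- if (length(tr) > 1) median(diff(sort(tr))) else 1
    tol <- step / 2
  }
  idx <- vapply(te, function(t0) {
    j <- which.min(abs(tr - t0))
    if (abs(tr[j] - t0) <= tol) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  if (!any(keep)) stop("no timestamp overlap between trajectories")
  list(est = list(timestamps = te[keep], poses = est$poses[keep]),
       ref = list(timestamps = tr[idx[keep]], poses = ref$poses[idx[keep]]),
       dropped = sum(!keep))
}

#' Evaluate an estimated trajectory against a reference
#'
#' Navigation mode compares the estimated (already CT-mapped) poses
#' directly with the reference. Retrospective mode first fits the
#' closed-form similarity from the estimated to the reference centers —
#' the evaluation a tracker-informed post-hoc registration would give —
#' and maps the estimated poses through it before computing errors.
#'
#' @param est,ref Trajectories (lists with `timestamps`, `poses`),
#'   timestamp-matched within half the reference frame interval.
#' @param mode `"navigation"` or `"retrospective"`.
#' @return List with `per_pose` (data frame: timestamp, translation error,
#'   general and per-axis rotation errors) and `summary` (means and sds).
#' @export
evaluate_run <- function(est, ref, mode = c("navigation", "retrospective")) {
  mode <- match.arg(mode)
  p <- pair_by_timestamp(est, ref)
  est_poses <- p$est$poses
  if (mode == "retrospective") {
    Tfit <- umeyama_alignment(trajectory_centers(p$est$poses),
                              trajectory_centers(p$ref$poses))
    est_poses <- lapply(est_poses, function(ps) apply_similarity_pose(Tfit, ps))
  }
  n <- length(est_poses)
  tr_err <- numeric(n); rot_err <- numeric(n); ax <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tr_err[i] <- translation_error(est_poses[[i]], p$ref$poses[[i]])
    rot_err[i] <- rotation_error_general(est_poses[[i]], p$ref$poses[[i]])
    ax[i, ] <- rotation_error_per_axis(est_poses[[i]], p$ref$poses[[i]])
  }
  per_pose <- data.frame(timestamp = p$est$timestamps,
                         translation_mm = tr_err, rotation_deg = rot_err,
                         rot_x_deg = ax[, 1], rot_y_deg = ax[, 2],
                         rot_z_deg = ax[, 3])
  summary <- list(mode = mode, n = n, dropped = p$dropped,
                  translation_mean = mean(tr_err), translation_sd = sd(tr_err),
                  rotation_mean = mean(rot_err), rotation_sd = sd(rot_err),
                  rot_axis_mean = colMeans(ax),
                  ate_rmse = sqrt(mean(tr_err^2)))
  list(per_pose = per_pose, summary = summary)
}

#' Half-split target registration error of the SLAM point cloud
#'
#' Builds 3D-3D correspondences between SLAM landmarks and the CT surface
#' by casting a ray from the reference (tracker) CT pose of the first
#' keyframe observing each landmark through that landmark's observed
#' pixel. A seeded random half of the pairs fits the similarity
#' registration; the residual is the RMS distance on the fitting half and
#' the TRE the RMS distance on the held-out half.
#'
#' @param map `sn_slam_map`.
#' @param ref_poses List of CT-frame reference `sn_pose`, one per keyframe.
#' @param mesh CT `sn_mesh`.
#' @param intr `sn_intrinsics`.
#' @param seed Integer seed for the half split.
#' @return List with `residual_mm`, `tre_mm`, `n_pairs`, and the fitted
#'   `registration`.
#' @export
tre_halfsplit <- function(map, ref_poses, mesh, intr, seed = 1) {
  obs <- map$observations
  nl <- nrow(map$landmarks)
  if (nl < 6) stop("need at least 6 landmarks for the half-split TRE")
  slam_pts <- NULL; ct_pts <- NULL; used <- integer(0)
  ord <- order(obs$landmark, obs$kf)
  obs <- obs[ord, ]
  first_obs <- obs[!duplicated(obs$landmark), ]
  for (i in seq_len(nrow(first_obs))) {
    kf <- first_obs$kf[i]
    pose <- ref_poses[[kf]]
    pix <- undistort_points(intr, c(first_obs$x[i], first_obs$y[i]))
    dir_cam <- c((pix[1] - intr$cx) / intr$fx, (pix[2] - intr$cy) / intr$fy, 1)
    dir_world <- as.numeric(pose$R %*% dir_cam)
    dir_world <- dir_world / sqrt(sum(dir_world^2))
    hit <- raycast(mesh, pose$t, dir_world)
    if (hit$hit[1]) {
      slam_pts <- rbind(slam_pts, map$landmarks[first_obs$landmark[i], ])
      ct_pts <- rbind(ct_pts, hit$point[1, ])
      used <- c(used, first_obs$landmark[i])
    }
  }
  n <- length(used)
  if (n < 6) stop("insufficient ray hits for the half-split TRE")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  fit_idx <- sort(sample.int(n, floor(n / 2)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  hold_idx <- setdiff(seq_len(n), fit_idx)
  Tfit <- umeyama_alignment(slam_pts[fit_idx, , drop = FALSE],
                            ct_pts[fit_idx, , drop = FALSE])
  rms <- function(idx) {
    mapped <- apply_similarity_points(Tfit, slam_pts[idx, , drop = FALSE])
    sqrt(mean(rowSums((mapped - ct_pts[idx, , drop = FALSE])^2)))
  }
  list(residual_mm = rms(fit_idx), tre_mm = rms(hold_idx), n_pairs = n,
       registration = Tfit)
}

#' Distance of guidance intersection points to a fiducial mesh
#'
#' Point-to-mesh distance between estimated viewing-axis intersections and
#' the segmented fiducial marker surface.
#'
#' @param intersections n x 3 matrix of intersection points (mm, CT frame).
#' @param fiducial_mesh `sn_mesh` of the segmented marker.
#' @return List with `distances_mm`, `mean_mm`, `sd_mm`.
#' @export
fiducial_distance <- function(intersections, fiducial_mesh) {
  d <- point_to_mesh_distance(fiducial_mesh, intersections)
  list(distances_mm = d, mean_mm = mean(d),
       sd_mm = if (length(d) > 1) sd(d) else NA_real_)
}
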