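## Semi-automated first-frame registration: user-picked 2D-2D
## correspondences between the CT-rendered reference view and the first
## endoscopic frame are lifted to 3D through the rendered depth map, and a
## robust PnP solve yields the first endoscopic camera pose in CT
## coordinates.

#' Read / write a 2D-2D correspondence file
#'
#' CSV with header `x_ct,y_ct,x_rgb,y_rgb`; 0-based pixel coordinates with
#' origin at the top-left corner.
#'
#' @param path File path.
#' @return A data frame of class `sn_correspondences`.
#' @export
read_correspondences <- function(path) {
  df <- read.csv(path)
  need <- c("x_ct", "y_ct", "x_rgb", "y_rgb")
  if (!all(need %in% names(df))) stop("correspondence file must have columns ",
                                      paste(need, collapse = ","))
  correspondence_set(df[, need])
}

#' @rdname read_correspondences
#' @param corr Correspondence data frame.
#' @export
write_correspondences <- function(corr, path) {
  write.csv(as.data.frame(corr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a correspondence set
#'
#' @param pairs Data frame with columns `x_ct, y_ct, x_rgb, y_rgb`.
#' @return The validated data frame with class `sn_correspondences`.
#' @export
correspondence_set <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 4) stop("at least 4 correspondences are required for PnP")
  if (any(!is.finite(as.matrix(pairs)))) stop("non-finite correspondence coordinates")
  class(pairs) <- c("sn_correspondences", "data.frame")
  pairs
}

#' Lift 2D-2D correspondences to 3D-2D pairs through the reference depth
#'
#' Each reference pixel `x_ct` is looked up in the rendered depth map
#' (bilinear over finite neighbors); pairs falling on miss pixels are
#' dropped with a warning. Surviving pixels are backprojected at their
#' depth and moved into the CT frame by the reference pose. The reference
#' render is an ideal pinhole view, so `x_ct` needs no undistortion; the
#' endoscopic pixels `x_rgb` are kept as given and undistorted later by the
#' PnP solver.
#'
#' @param render `sn_render` of the CT reference view.
#' @param pose_ct Reference camera pose (camera-to-CT).
#' @param intr `sn_intrinsics`.
#' @param corr `sn_correspondences`.
#' @return List with `points_ct` (n x 3), `pixels_rgb` (n x 2) and
#'   `kept` (row indices of surviving pairs).
#' @export
lift_correspondences <- function(render, pose_ct, intr, corr) {
  px_ct <- as.matrix(corr[, c("x_ct", "y_ct")])
  depths <- depth_at(render, px_ct)
  keep <- is.finite(depths) & depths > 0
  if (sum(keep) < nrow(corr))
    warning(sum(!keep), " correspondence(s) fell on depth-map misses and were dropped")
  if (sum(keep) < 4)
    stop("fewer than 4 correspondences survive depth lookup")
  pts <- backproject_pixels(intr, pose_ct, px_ct[keep, , drop = FALSE],
                            depths[keep])
  list(points_ct = pts,
       pixels_rgb = as.matrix(corr[keep, c("x_rgb", "y_rgb")]),
       kept = which(keep))
}

## ---- PnP -------------------------------------------------------------------

# Direct linear transform camera resection on >= 6 normalized 3D-2D pairs.
# Returns a camera-to-world pose, or NULL for degenerate configurations.
dlt_pose <- function(points, ynorm) {
  n <- nrow(points)
  A <- matrix(0, 2 * n, 12)
  Xh <- cbind(points, 1)
  A[seq(1, 2 * n, 2), 1:4] <- Xh
  A[seq(1, 2 * n, 2), 9:12] <- -ynorm[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- Xh
  A[seq(2, 2 * n, 2), 9:12] <- -ynorm[, 2] * Xh
  sv <- tryCatch(svd(A, nu = 0, nv = 12), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  P <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
  M <- P[, 1:3]
  if (det(M) < 0) { P <- -P; M <- -M }
  sm <- svd(M)
  if (sm$d[3] < 1e-10 * sm$d[1]) return(NULL)
  R_wc <- sm$u %*% t(sm$v)
  if (det(R_wc) < 0) return(NULL)
  sigma <- mean(sm$d)
  t_wc <- P[, 4] / sigma
  # cheirality: points must be in front of the camera
  z <- points %*% R_wc[3, ] + t_wc[3]
  if (mean(z > 0) < 0.5) return(NULL)
  rigid_pose(t(R_wc), as.numeric(-t(R_wc) %*% t_wc))
}

# Gauss-Newton refinement of a single camera pose on ideal-pixel
# reprojection error. Observations are undistorted pixels.
refine_pose <- function(pose, points, pixels, intr, max_iter = 25,
                        tol = 1e-14) {
  R_wc <- t(pose$R)
  t_wc <- as.numeric(-R_wc %*% pose$t)
  n <- nrow(points)
  cost <- function(R_wc, t_wc) {
    cam <- points %*% t(R_wc)
    cam <- sweep(cam, 2, t_wc, `+`)
    u <- intr$fx * cam[, 1] / cam[, 3] + intr$cx
    v <- intr$fy * cam[, 2] / cam[, 3] + intr$cy
    sum((u - pixels[, 1])^2 + (v - pixels[, 2])^2)
  }
  lambda <- 1e-8
  c0 <- cost(R_wc, t_wc)
  for (it in seq_len(max_iter)) {
    cam <- sweep(points %*% t(R_wc), 2, t_wc, `+`)
    z <- cam[, 3]
    u <- intr$fx * cam[, 1] / z + intr$cx
    v <- intr$fy * cam[, 2] / z + intr$cy
    r <- as.numeric(rbind(u - pixels[, 1], v - pixels[, 2]))
    J <- matrix(0, 2 * n, 6)
    for (i in seq_len(n)) {
      xc <- cam[i, ]
      dpix_dxc <- rbind(c(intr$fx / xc[3], 0, -intr$fx * xc[1] / xc[3]^2),
                        c(0, intr$fy / xc[3], -intr$fy * xc[2] / xc[3]^2))
      dxc <- cbind(-skew3(xc - t_wc), diag(3))  # d xc / d(rot increment, dt)
      J[c(2 * i - 1, 2 * i), ] <- dpix_dxc %*% dxc
    }
    H <- crossprod(J)
    g <- crossprod(J, r)
    ok <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(solve(H + lambda * diag(6), -g), error = function(e) NULL)
      if (!is.null(step)) {
        R_new <- rotvec_to_rot(step[1:3]) %*% R_wc
        t_new <- t_wc + step[4:6]
        c1 <- cost(R_new, t_new)
        if (is.finite(c1) && c1 <= c0) {
          R_wc <- R_new; t_wc <- as.numeric(t_new)
          improved <- c0 - c1
          c0 <- c1
          lambda <- max(lambda / 4, 1e-12)
          ok <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!ok || improved < tol * (c0 + 1e-300)) break
  }
  list(pose = rigid_pose(t(R_wc), as.numeric(-t(R_wc) %*% t_wc),
                         frame = pose$frame),
       cost = c0, rms_px = sqrt(c0 / n))
}

# Huber-robust (IRLS) Levenberg-Marquardt pose refinement from an initial
# pose guess; used inside incremental SLAM where an adjacent frame
# provides a motion prior. Returns NULL when too few observations remain
# within threshold_px.
refine_pose_robust <- function(init, points, pixels, intr, huber_px = 4,
                               threshold_px = 6, max_iter = 30) {
  R_wc <- t(init$R)
  t_wc <- as.numeric(-R_wc %*% init$t)
  n <- nrow(points)
  resid <- function(R_wc, t_wc) {
    cam <- sweep(points %*% t(R_wc), 2, t_wc, `+`)
    z <- cam[, 3]
    u <- intr$fx * cam[, 1] / z + intr$cx
    v <- intr$fy * cam[, 2] / z + intr$cy
    e <- sqrt((u - pixels[, 1])^2 + (v - pixels[, 2])^2)
    e[z <= 0] <- Inf
    e
  }
  rob_cost <- function(e) sum(huber_rho(pmin(e, 1e6), huber_px))
  c0 <- rob_cost(resid(R_wc, t_wc))
  lambda <- 1e-4
  for (it in seq_len(max_iter)) {
    cam <- sweep(points %*% t(R_wc), 2, t_wc, `+`)
    z <- cam[, 3]
    bad <- z <= 1e-9
    u <- intr$fx * cam[, 1] / z + intr$cx
    v <- intr$fy * cam[, 2] / z + intr$cy
    r <- rbind(u - pixels[, 1], v - pixels[, 2])
    en <- sqrt(colSums(r^2))
    w <- ifelse(en <= huber_px, 1, huber_px / pmax(en, 1e-300))
    w[bad] <- 0
    J <- matrix(0, 2 * n, 6)
    rv <- numeric(2 * n)
    for (i in seq_len(n)) {
      if (bad[i]) next
      xc <- cam[i, ]
      dpix <- rbind(c(intr$fx / xc[3], 0, -intr$fx * xc[1] / xc[3]^2),
                    c(0, intr$fy / xc[3], -intr$fy * xc[2] / xc[3]^2))
      sw <- sqrt(w[i])
      J[c(2 * i - 1, 2 * i), ] <- sw * dpix %*%
        cbind(-skew3(xc - t_wc), diag(3))
      rv[c(2 * i - 1, 2 * i)] <- sw * r[, i]
    }
    H <- crossprod(J)
    g <- crossprod(J, rv)
    accepted <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(solve(H + lambda * diag(6), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        R_new <- rotvec_to_rot(step[1:3]) %*% R_wc
        t_new <- as.numeric(t_wc + step[4:6])
        c1 <- rob_cost(resid(R_new, t_new))
        if (is.finite(c1) && c1 <= c0) {
          R_wc <- R_new; t_wc <- t_new
          improved <- c0 - c1
          c0 <- c1
          lambda <- max(lambda / 4, 1e-10)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || improved < 1e-12 * (c0 + 1e-300)) break
  }
  err <- resid(R_wc, t_wc)
  inl <- err <= threshold_px
  if (sum(inl) < 4) return(NULL)
  list(pose = rigid_pose(t(R_wc), as.numeric(-t(R_wc) %*% t_wc),
                         frame = init$frame),
       inliers = inl, reproj_px = err)
}

#' Robust PnP registration (RANSAC + refinement)
#'
#' Estimates the camera-to-world pose from 3D-2D correspondences with
#' known intrinsics. Hypotheses are generated by DLT camera resection on
#' minimal 6-point samples inside RANSAC; the final pose is refined by
#' Gauss-Newton on the inlier set only. Observed pixels are undistorted
#' before solving, and inlier reprojection errors are measured in ideal
#' pixel coordinates. Deterministic given `seed`.
#'
#' @param points n x 3 matrix of 3D points (frame of the desired pose).
#' @param pixels n x 2 matrix of observed pixels.
#' @param intr `sn_intrinsics`.
#' @param threshold_px RANSAC inlier reprojection threshold (default 2 px).
#' @param confidence RANSAC stopping confidence (default 0.999).
#' @param max_iter Maximum RANSAC iterations (default 1000).
#' @param seed Integer RNG seed.
#' @param frame Frame label of the returned pose.
#' @return List with `pose` (`sn_pose`), `inliers` (logical mask),
#'   `reproj_px` (per-point errors) and `rms_px` over inliers.
#' @export
pnp_register <- function(points, pixels, intr, threshold_px = 2,
                         confidence = 0.999, max_iter = 1000, seed = 1,
                         frame = "ct") {
  points <- as_points(points)
  pixels <- as.matrix(pixels)
  n <- nrow(points)
  if (n < 4) stop("PnP requires at least 4 correspondences")
  ideal <- undistort_points(intr, pixels)
  ynorm <- cbind((ideal[, 1] - intr$cx) / intr$fx,
                 (ideal[, 2] - intr$cy) / intr$fy)
  reproj_errors <- function(pose) {
    cam <- sweep(points, 2, pose$t) %*% pose$R
    z <- cam[, 3]
    u <- intr$fx * cam[, 1] / z + intr$cx
    v <- intr$fy * cam[, 2] / z + intr$cy
    err <- sqrt((u - ideal[, 1])^2 + (v - ideal[, 2])^2)
    err[z <= 0] <- Inf
    err
  }
  m <- min(6, n)
  if (n < 6) stop("DLT hypothesis generation requires at least 6 points")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best_inl <- NULL; best_count <- -1; best_err <- Inf
  needed <- max_iter
  it <- 0
  while (it < needed && it < max_iter) {
    it <- it + 1
    idx <- sample.int(n, m)
    hyp <- dlt_pose(points[idx, , drop = FALSE], ynorm[idx, , drop = FALSE])
    if (is.null(hyp)) next
    err <- reproj_errors(hyp)
    inl <- err <= threshold_px
    cnt <- sum(inl)
    if (cnt > best_count || (cnt == best_count && sum(err[inl]) < best_err)) {
      best_count <- cnt; best_inl <- inl; best_err <- sum(err[inl])
      w <- max(cnt / n, 1e-9)
      denom <- log1p(-min(w^m, 1 - 1e-12))
      needed <- if (denom < 0)
        min(max_iter, max(it, ceiling(log(1 - confidence) / denom)))
      else max_iter
    }
  }
  if (is.null(best_inl) || best_count < 4)
    stop("RANSAC PnP failed to find a 4-point consensus")
  # final refinement on the inlier set only
  inl <- best_inl
  init <- dlt_pose(points[inl, , drop = FALSE], ynorm[inl, , drop = FALSE])
  if (is.null(init)) init <- rigid_pose(frame = frame)
  ref <- refine_pose(init, points[inl, , drop = FALSE],
                     ideal[inl, , drop = FALSE], intr)
  pose <- rigid_pose(ref$pose$R, ref$pose$t, frame = frame)
  err <- reproj_errors(pose)
  inl_final <- err <= threshold_px
  list(pose = pose, inliers = inl_final, reproj_px = err,
       rms_px = sqrt(mean(err[inl_final]^2)))
}

#' Registration transform from the PnP-registered first frame
#'
#' Builds the SLAM-to-CT similarity (scale initialized to 1) that maps the
#' first SLAM keyframe pose exactly onto its PnP-registered CT pose.
#'
#' @param pose_rgb_in_ct First endoscopic frame pose in CT coordinates.
#' @param first_slam_pose The same frame's pose in the SLAM frame
#'   (identity under the SLAM gauge).
#' @return An `sn_similarity` with scale 1.
#' @export
registration_from_first_frame <- function(pose_rgb_in_ct, first_slam_pose) {
  R_T <- pose_rgb_in_ct$R %*% t(first_slam_pose$R)
  t_T <- pose_rgb_in_ct$t - as.numeric(R_T %*% first_slam_pose$t)
  similarity_transform(1, R_T, t_T)
}

#' Read / write a registration (similarity transform) as YAML
#'
#' Stores the scale, rotation as a unit quaternion `(qx, qy, qz, qw)` and
#' the translation in mm.
#'
#' @param path File path.
#' @return `read_registration` returns an `sn_similarity`.
#' @export
read_registration <- function(path) {
  y <- yaml::read_yaml(path)
  similarity_transform(y$scale, quat_to_rot(unlist(y$quaternion_xyzw)),
                       unlist(y$translation_mm))
}

#' @rdname read_registration
#' @param reg An `sn_similarity`.
#' @export
write_registration <- function(reg, path) {
  yaml::write_yaml(list(scale = reg$s,
                        quaternion_xyzw = as.list(rot_to_quat(reg$R)),
                        translation_mm = as.list(reg$t)), path,
                   precision = 17)
  invisible(path)
}
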