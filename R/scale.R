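## Monocular scale recovery against the CT surface. 3D points visible from
## the first keyframe are paired with CT surface points obtained by
## casting rays from the PnP-registered first-frame pose through the same
## image positions; the scale is the ratio of the longest lines (maximum
## pairwise distances) of the two point clouds, re-estimated at every
## keyframe event as the reconstruction densifies. The registration's
## rotation and translation stay anchored to the first frame: only the
## scale changes, and the translation is recomputed so the first
## keyframe's CT pose never drifts.

#' Scale state: current SLAM-to-CT scale and its history
#'
#' @param current Positive scale (CT mm per SLAM unit).
#' @param history Data frame `keyframe, scale` (keyframe = number of
#'   keyframes in the map when the estimate was made).
#' @return An object of class `sn_scale_state`.
#' @export
scale_state <- function(current, history = NULL) {
  stopifnot(is.numeric(current), length(current) == 1, is.finite(current),
            current > 0)
  if (is.null(history))
    history <- data.frame(keyframe = integer(0), scale = numeric(0))
  structure(list(current = current, history = history),
            class = "sn_scale_state")
}

#' @rdname scale_state
#' @param state An `sn_scale_state`.
#' @param path CSV output path (`keyframe,scale`).
#' @export
write_scale_history <- function(state, path) {
  write.csv(state$history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Landmarks visible from the first keyframe
#'
#' Returns exactly the landmarks that carry an observation in the map's
#' first keyframe, with those observed image positions.
#'
#' @param map `sn_slam_map`.
#' @return List with `points` (k x 3, SLAM frame), `pixels` (k x 2) and
#'   `landmark` indices.
#' @export
first_keyframe_points <- function(map) {
  obs <- map$observations
  sel <- obs[obs$kf == 1, , drop = FALSE]
  if (nrow(sel) < 2)
    stop("fewer than 2 landmarks observed in the first keyframe; ",
         "scale cannot be estimated")
  sel <- sel[order(sel$landmark), ]
  list(points = map$landmarks[sel$landmark, , drop = FALSE],
       pixels = as.matrix(sel[, c("x", "y")]),
       landmark = sel$landmark)
}

#' Ray-cast image points onto the CT surface
#'
#' Casts a ray from the registered first-frame CT pose through each pixel;
#' pixels whose ray misses the mesh are dropped, preserving pairing by
#' index.
#'
#' @param mesh CT `sn_mesh`.
#' @param pose_rgb_in_ct First endoscopic frame pose in CT coordinates.
#' @param intr `sn_intrinsics`.
#' @param pixels n x 2 matrix of image points.
#' @return List with `index` (of the surviving pixels), `points` (k x 3 CT
#'   points) and `ray_length` (mm from the camera center).
#' @export
raycast_correspondences <- function(mesh, pose_rgb_in_ct, intr, pixels) {
  pixels <- as.matrix(pixels)
  ideal <- undistort_points(intr, pixels)
  dirs_cam <- cbind((ideal[, 1] - intr$cx) / intr$fx,
                    (ideal[, 2] - intr$cy) / intr$fy, 1)
  dirs_cam <- dirs_cam / sqrt(rowSums(dirs_cam^2))
  dirs <- dirs_cam %*% t(pose_rgb_in_ct$R)
  res <- raycast(mesh, pose_rgb_in_ct$t, dirs)
  if (sum(res$hit) < 2)
    stop("fewer than 2 rays hit the CT surface; scale cannot be estimated")
  list(index = which(res$hit),
       points = res$point[res$hit, , drop = FALSE],
       ray_length = res$distance[res$hit])
}

#' Longest-line scale ratio between two paired point clouds
#'
#' Scale = (maximum pairwise distance among the CT points) /
#' (maximum pairwise distance among the SLAM points). Only lengths enter;
#' the two maxima are taken independently in each cloud.
#'
#' @param slam_points,ct_points k x 3 matrices (k >= 2).
#' @return Positive scalar (CT mm per SLAM unit).
#' @export
longest_line_scale <- function(slam_points, ct_points) {
  slam_points <- as_points(slam_points); ct_points <- as_points(ct_points)
  stopifnot(nrow(slam_points) >= 2, nrow(ct_points) >= 2)
  d_slam <- max(dist(slam_points))
  if (d_slam < 1e-12) stop("zero diameter of the SLAM point cloud")
  max(dist(ct_points)) / d_slam
}

# Robust alternative: ratio of RMS distances from the centroid.
rms_radius_scale <- function(slam_points, ct_points) {
  r <- function(p) sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
  rs <- r(as_points(slam_points))
  if (rs < 1e-12) stop("zero diameter of the SLAM point cloud")
  r(as_points(ct_points)) / rs
}

# Shared estimation step: first-keyframe landmarks -> ray-cast CT partners
# -> scale ratio, with an outlier guard dropping pairs whose distance from
# the first camera exceeds 3x the median in either cloud. Distant points
# (badly triangulated low-parallax landmarks on the SLAM side, long
# grazing rays on the CT side) would otherwise dominate the max-based
# estimator.
estimate_scale_once <- function(map, mesh, pose_rgb_in_ct, intr,
                                method = c("longest_line", "rms"),
                                guard = TRUE) {
  method <- match.arg(method)
  fk <- first_keyframe_points(map)
  rc <- raycast_correspondences(mesh, pose_rgb_in_ct, intr, fk$pixels)
  slam_pts <- fk$points[rc$index, , drop = FALSE]
  ct_pts <- rc$points
  if (guard && nrow(ct_pts) >= 4) {
    d_slam <- sqrt(rowSums(sweep(slam_pts, 2, map$poses[[1]]$t)^2))
    keep <- rc$ray_length <= 3 * median(rc$ray_length) &
      d_slam <= 3 * median(d_slam)
    if (sum(keep) >= 2) {
      slam_pts <- slam_pts[keep, , drop = FALSE]
      ct_pts <- ct_pts[keep, , drop = FALSE]
    }
  }
  if (method == "longest_line") longest_line_scale(slam_pts, ct_pts)
  else rms_radius_scale(slam_pts, ct_pts)
}

#' Initial scale estimate from the map after the second keyframe
#'
#' @param map `sn_slam_map` with at least two keyframes.
#' @param mesh CT `sn_mesh`.
#' @param pose_rgb_in_ct PnP-registered first-frame CT pose.
#' @param intr `sn_intrinsics`.
#' @param method `"longest_line"` (default) or `"rms"` (ratio of RMS
#'   centroid distances).
#' @param guard Drop ray-cast partners beyond 3x the median ray length
#'   before the ratio (default `TRUE`).
#' @return An `sn_scale_state` with one history entry.
#' @export
initialize_scale <- function(map, mesh, pose_rgb_in_ct, intr,
                             method = "longest_line", guard = TRUE) {
  if (length(map$poses) < 2) stop("scale initialization needs >= 2 keyframes")
  s <- estimate_scale_once(map, mesh, pose_rgb_in_ct, intr, method, guard)
  scale_state(s, data.frame(keyframe = length(map$poses), scale = s))
}

#' Update the scale after a new keyframe
#'
#' Re-runs the same estimator over all landmarks currently visible from
#' the first keyframe (denser and refined after bundle adjustment). If the
#' estimation fails the previous scale is retained with a warning.
#'
#' @param state `sn_scale_state`.
#' @inheritParams initialize_scale
#' @param keyframe Keyframe count to record in the history (defaults to
#'   the map's current keyframe count).
#' @return The updated `sn_scale_state`.
#' @export
update_scale <- function(state, map, mesh, pose_rgb_in_ct, intr,
                         keyframe = length(map$poses),
                         method = "longest_line", guard = TRUE) {
  s <- tryCatch(estimate_scale_once(map, mesh, pose_rgb_in_ct, intr,
                                    method, guard),
                error = function(e) {
                  warning("scale update failed (", conditionMessage(e),
                          "); retaining previous scale")
                  state$current
                })
  scale_state(s, rbind(state$history,
                       data.frame(keyframe = keyframe, scale = s)))
}

## ---- navigation state ------------------------------------------------------

#' Navigation state: registration, scale, latest CT pose and intersection
#'
#' The registration rotation is fixed by the first-frame PnP solve; on
#' every scale change the translation is recomputed so the first SLAM
#' keyframe still maps exactly onto its PnP-registered CT pose (anchor
#' preservation).
#'
#' @param pose_rgb_in_ct PnP-registered first-frame CT pose.
#' @param first_slam_pose First keyframe pose in the SLAM frame.
#' @param scale_state `sn_scale_state`.
#' @return An object of class `sn_navigation_state`.
#' @export
navigation_state <- function(pose_rgb_in_ct, first_slam_pose, scale_state) {
  base <- registration_from_first_frame(pose_rgb_in_ct, first_slam_pose)
  st <- structure(list(anchor_ct = pose_rgb_in_ct,
                       anchor_slam = first_slam_pose,
                       rotation = base$R,
                       scale_state = scale_state,
                       registration = NULL,
                       latest_ct_pose = NULL,
                       latest_intersection = NULL),
                  class = "sn_navigation_state")
  refresh_registration(st)
}

refresh_registration <- function(state) {
  s <- state$scale_state$current
  t_T <- state$anchor_ct$t -
    s * as.numeric(state$rotation %*% state$anchor_slam$t)
  state$registration <- similarity_transform(s, state$rotation, t_T)
  state
}

#' Update the navigation state's scale (atomically with the registration)
#'
#' @param state `sn_navigation_state`.
#' @param map,mesh,intr See [update_scale()].
#' @param ... Passed to [update_scale()].
#' @return The updated state.
#' @export
navigation_update_scale <- function(state, map, mesh, intr, ...) {
  state$scale_state <- update_scale(state$scale_state, map, mesh,
                                    state$anchor_ct, intr, ...)
  refresh_registration(state)
}

#' Map a SLAM-frame pose into CT coordinates
#'
#' Applies the current similarity registration. The first SLAM keyframe
#' maps exactly onto the PnP-registered pose for any scale.
#'
#' @param state `sn_navigation_state` (initialized).
#' @param slam_pose `sn_pose` in the SLAM frame.
#' @return `sn_pose` in the CT frame.
#' @export
map_pose_to_ct <- function(state, slam_pose) {
  if (is.null(state$registration)) stop("navigation state not initialized")
  apply_similarity_pose(state$registration, slam_pose, frame = "ct")
}
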