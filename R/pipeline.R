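## End-to-end navigation driver: first-frame registration, incremental
## SLAM, continuous scale recovery, CT mapping and guidance records.

#' Run the full navigation pipeline
#'
#' Renders the CT reference view, lifts the first-frame correspondences
#' and solves robust PnP for the first endoscopic pose in CT coordinates,
#' runs incremental SLAM over the track table, initializes the
#' SLAM-to-CT scale from the first available map and updates it at every
#' section event, and maps each newly emitted keyframe pose into CT
#' coordinates with the registration current at emission time (the
#' prospective, in-navigation behaviour). Guidance records are computed
#' for the latest pose of each event.
#'
#' @param mesh CT `sn_mesh`.
#' @param ref_pose Reference camera `sn_pose` (CT frame).
#' @param intr `sn_intrinsics`.
#' @param corr `sn_correspondences` (first endoscopic frame vs reference
#'   view).
#' @param tracks `sn_track_table`.
#' @param n_frames Stream length (default from tracks).
#' @param lm Section buffer length for SLAM.
#' @param seed Integer seed (RANSAC draws).
#' @param constant_scale Ablation: keep the registration scale fixed at 1
#'   instead of recovering it (default `FALSE`).
#' @param scale_method,scale_guard Passed to the scale estimator.
#' @param geom Optional `sn_volume_geometry` for triplane indices.
#' @param guidance_mesh Mesh used for tissue intersections (defaults to
#'   `mesh`; pass a merge with fiducial geometry to include markers).
#' @param ref_render Optional precomputed reference render.
#' @param slam Optional precomputed `sn_slam_result` for these tracks
#'   (reused, e.g., when comparing scaling modes on one SLAM run).
#' @return List of class `sn_navigation_run`: `trajectory_ct` (timestamps
#'   are keyframe frame indices; poses mapped at emission time, as a
#'   live navigation consumer would have seen them),
#'   `final_trajectory_ct` (the completed map's keyframes mapped with the
#'   final registration), `pose0_ct`, `pnp` (full PnP result), `slam`
#'   (`sn_slam_result`), `nav_state` (final), `scale_state`, `guidance`
#'   (one record per event).
#' @export
run_navigation <- function(mesh, ref_pose, intr, corr, tracks,
                           n_frames = NULL, lm = 12, seed = 1,
                           constant_scale = FALSE,
                           scale_method = "longest_line",
                           scale_guard = TRUE, geom = NULL,
                           guidance_mesh = mesh, ref_render = NULL,
                           slam = NULL) {
  if (is.null(ref_render)) ref_render <- render_reference(mesh, ref_pose, intr)
  lifted <- lift_correspondences(ref_render, ref_pose, intr, corr)
  pnp <- pnp_register(lifted$points_ct, lifted$pixels_rgb, intr, seed = seed)
  if (is.null(slam))
    slam <- run_slam(tracks, intr, n_frames = n_frames, lm = lm, seed = seed)
  nav <- NULL
  timestamps <- numeric(0); poses_ct <- list(); guidance <- list()
  for (ev in slam$events) {
    map <- ev$map
    if (is.null(nav)) {
      init_state <- if (constant_scale) scale_state(1) else
        initialize_scale(map, mesh, pnp$pose, intr,
                         method = scale_method, guard = scale_guard)
      nav <- navigation_state(pnp$pose, map$poses[[1]], init_state)
    } else if (!constant_scale) {
      nav <- navigation_update_scale(nav, map, mesh, intr,
                                     method = scale_method,
                                     guard = scale_guard)
    }
    for (k in ev$new_kf) {
      ct_pose <- map_pose_to_ct(nav, map$poses[[k]])
      timestamps <- c(timestamps, map$frames[k])
      poses_ct <- c(poses_ct, list(ct_pose))
    }
    last_ct <- poses_ct[[length(poses_ct)]]
    nav$latest_ct_pose <- last_ct
    rec <- guidance_record(last_ct, guidance_mesh, geom,
                           frame = timestamps[length(timestamps)])
    nav$latest_intersection <- rec$intersection_mm
    guidance[[length(guidance) + 1]] <- rec
  }
  final_map <- slam$map
  final_traj <- list(timestamps = as.numeric(final_map$frames),
                     poses = lapply(final_map$poses, function(p)
                       map_pose_to_ct(nav, p)))
  structure(list(trajectory_ct = list(timestamps = timestamps,
                                      poses = poses_ct),
                 final_trajectory_ct = final_traj,
                 pose0_ct = pnp$pose, pnp = pnp, slam = slam,
                 nav_state = nav, scale_state = nav$scale_state,
                 guidance = guidance),
            class = "sn_navigation_run")
}

#' Run the pipeline on a synthetic scene
#'
#' Convenience wrapper binding [run_navigation()] to a scene's mesh,
#' reference render, correspondences and tracks.
#'
#' @param scene `sn_scene` (with a reference render and correspondences).
#' @param ... Passed to [run_navigation()].
#' @return An `sn_navigation_run`.
#' @export
navigate_scene <- function(scene, ...) {
  if (is.null(scene$ref_render))
    scene$ref_render <- render_reference(scene$mesh, scene$ref_pose,
                                         scene$intr)
  if (is.null(scene$corr))
    scene$corr <- make_reference_correspondences(scene$cfg, scene$mesh,
                                                 scene$ref_render,
                                                 scene$ref_pose,
                                                 scene$poses_ct[[1]],
                                                 scene$intr)
  run_navigation(scene$mesh, scene$ref_pose, scene$intr, scene$corr,
                 scene$tracks, n_frames = scene$cfg$n_frames,
                 ref_render = scene$ref_render, ...)
}

#' Ground-truth CT trajectory of a scene restricted to keyframes
#'
#' @param scene `sn_scene`.
#' @param timestamps Frame indices (0-based) to extract.
#' @return Trajectory list (`timestamps`, `poses`).
#' @export
scene_reference_trajectory <- function(scene, timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- 0:(scene$cfg$n_frames - 1)
  list(timestamps = as.numeric(timestamps),
       poses = scene$poses_ct[timestamps + 1])
}
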